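# Self-supervised ranking losses over a g x m slice-score matrix:
# g volumes per batch, m equidistantly sampled slices per volume, ordered
# inferior -> superior within each row.

# log(sigmoid(x)) computed without overflow for large |x|.
log_sigmoid <- function(x) {
  ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
}

# Smooth L1 (Huber-style, bounded gradient): quadratic below the transition
# point beta, absolute beyond it. f(0) = 0, f is C1 at |x| = beta.
smooth_l1 <- function(x, beta = 1) {
  ax <- abs(x)
  ifelse(ax < beta, 0.5 * x^2 / beta, ax - 0.5 * beta)
}

smooth_l1_grad <- function(x, beta = 1) {
  pmax(pmin(x / beta, 1), -1)
}

check_score_matrix <- function(scores, min_m) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  assert_that(is.numeric(scores) && length(dim(scores)) == 2L,
              "scores must be a numeric g x m matrix")
  assert_that(all(is.finite(scores)), "scores must be finite")
  assert_that(ncol(scores) >= min_m,
              "need at least m = %d slices per volume, got %d", min_m, ncol(scores))
  scores
}

#' Order loss: penalize non-increasing slice scores
#'
#' For a `g x m` score matrix `S` (one row per volume, columns in axial
#' inferior-to-superior order) the order loss is
#' `-sum_i sum_{j=1}^{m-1} log sigmoid(S[i, j+1] - S[i, j])`.
#' It is minimized (towards 0) when every consecutive score difference is
#' large and positive, i.e. when scores increase towards the head.
#'
#' @param scores numeric matrix (`g x m`, `m >= 2`) or a length-`m` vector
#'   treated as a single volume.
#' @return nonnegative scalar.
#' @seealso [distance_loss()], [total_loss()]
#' @examples
#' order_loss(0:7)               # 7 * -log(sigmoid(1))
#' order_loss(rep(1, 8))         # 7 * log(2)
#' @export
order_loss <- function(scores) {
  scores <- check_score_matrix(scores, 2L)
  d <- scores[, -1L, drop = FALSE] - scores[, -ncol(scores), drop = FALSE]
  -sum(log_sigmoid(d))
}

# Gradient of order_loss w.r.t. the score matrix.
order_loss_grad <- function(scores) {
  scores <- check_score_matrix(scores, 2L)
  m <- ncol(scores)
  d <- scores[, -1L, drop = FALSE] - scores[, -m, drop = FALSE]
  # dL/dd = sigmoid(d) - 1
  dd <- stats::plogis(d) - 1
  g <- matrix(0, nrow(scores), m)
  g[, -1L] <- g[, -1L, drop = FALSE] + dd
  g[, -m] <- g[, -m, drop = FALSE] - dd
  g
}

#' Distance loss: drive slice scores towards equal spacing
#'
#' With consecutive gaps `D[i, j] = S[i, j+1] - S[i, j]`, the distance loss
#' is `sum_i sum_{j=1}^{m-2} f(D[i, j+1] - D[i, j])` where `f` is the smooth
#' L1 function (quadratic below `beta`, absolute above). It is zero exactly
#' when each volume's scores are an arithmetic progression, i.e. when score
#' grows linearly along the (equidistant) slice stack.
#'
#' The sign convention is `+sum f`: the loss is small when consecutive gaps
#' agree and grows with irregular spacing (see the methods vignette for why
#' this orientation is the meaningful one).
#'
#' @param scores numeric matrix (`g x m`, `m >= 3`) or a length-`m` vector.
#' @param beta smooth-L1 transition point (default 1).
#' @return nonnegative scalar.
#' @examples
#' distance_loss(c(0, 1, 3))     # f(1) = 0.5
#' distance_loss(seq(0, 70, 10)) # 0: equally spaced
#' @export
distance_loss <- function(scores, beta = 1) {
  scores <- check_score_matrix(scores, 3L)
  assert_that(is.numeric(beta) && length(beta) == 1L && beta > 0, "beta must be > 0")
  gaps <- scores[, -1L, drop = FALSE] - scores[, -ncol(scores), drop = FALSE]
  dd <- gaps[, -1L, drop = FALSE] - gaps[, -ncol(gaps), drop = FALSE]
  sum(smooth_l1(dd, beta))
}

# Gradient of distance_loss w.r.t. the score matrix.
distance_loss_grad <- function(scores, beta = 1) {
  scores <- check_score_matrix(scores, 3L)
  m <- ncol(scores)
  gaps <- scores[, -1L, drop = FALSE] - scores[, -m, drop = FALSE]
  dd <- gaps[, -1L, drop = FALSE] - gaps[, -ncol(gaps), drop = FALSE]
  fg <- smooth_l1_grad(dd, beta)                     # g x (m-2)
  # dd_j = S[,j+2] - 2 S[,j+1] + S[,j]
  g <- matrix(0, nrow(scores), m)
  idx <- seq_len(m - 2L)
  g[, idx] <- g[, idx, drop = FALSE] + fg
  g[, idx + 1L] <- g[, idx + 1L, drop = FALSE] - 2 * fg
  g[, idx + 2L] <- g[, idx + 2L, drop = FALSE] + fg
  g
}

#' Total self-supervised loss
#'
#' The sum of [order_loss()] and [distance_loss()], weighted 1:1.
#'
#' @inheritParams distance_loss
#' @return scalar `order_loss(scores) + distance_loss(scores, beta)`.
#' @export
total_loss <- function(scores, beta = 1) {
  order_loss(scores) + distance_loss(scores, beta)
}

total_loss_grad <- function(scores, beta = 1) {
  order_loss_grad(scores) + distance_loss_grad(scores, beta)
}
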