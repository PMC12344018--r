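# Backbone-agnostic slice scorer. A registered 2-D backbone maps each
# slice to a feature map; the regression head is a 1 x 1 convolution with
# head_width filters, a ReLU, global average pooling over the spatial
# dimensions, and a final affine map to one scalar. Each slice is scored
# independently (time-distributed), so stacks of any length share one
# network.

.bpr_backbones <- new.env(parent = emptyenv())

#' Register a slice-scorer backbone
#'
#' A backbone is a factory `function(input_size)` returning a list with:
#' `out_channels`; `init()` drawing initial parameters from the current
#' RNG; `forward(params, X, N, keep_cache)` mapping an input matrix
#' (`P * N` rows, 1 column; P = prod(input_size), position fastest) to
#' `list(out, cache)` with `out` a `(P2 * N, out_channels)` feature
#' matrix; `spatial` (P2); and `backward(params, cache, dOut, N)`
#' returning parameter gradients shaped like `params`.
#'
#' @param id backbone name.
#' @param factory factory function as described.
#' @return `id`, invisibly.
#' @export
register_backbone <- function(id, factory) {
  assign(id, factory, envir = .bpr_backbones)
  invisible(id)
}

#' List registered backbone ids
#' @return character vector.
#' @export
list_backbones <- function() ls(.bpr_backbones)

get_backbone <- function(id, input_size) {
  assert_that(exists(id, envir = .bpr_backbones),
              "unknown backbone '%s'; registered: %s", id,
              paste(list_backbones(), collapse = ", "))
  get(id, envir = .bpr_backbones)(input_size)
}

# Small trainable encoders: a chain of stride-2 3x3 convolutions with
# ReLU, plus a parallel average-pooling branch (an Inception-style
# pooling pathway) carrying the raw slice and three soft threshold maps
# as four extra feature channels aligned with the final conv grid. The
# pooled branch exposes plain intensity/area statistics to the head from
# the first update, which is what makes these backbones trainable from
# scratch in few epochs on a CPU; the convolutional chain contributes
# learned local structure, and with depth 4 a receptive field wide
# enough to relate neighbouring structures.
#
# Structured initialization: the first layer starts as a bank of
# classical image-analysis filters (averaging, Sobel edges, Laplacian,
# and soft intensity thresholds), deeper layers as per-channel smoothing
# / local-contrast selectors, all perturbed with a little noise. Global
# pooling of such channels immediately yields discriminative slice
# statistics (areas above thresholds, edge densities), which is what a
# pretrained encoder would provide; training then refines every filter.
tinyconv_factory <- function(input_size, depth) {
  stride_total <- as.integer(2^depth)
  assert_that(all(input_size %% stride_total == 0L),
              "this backbone needs input dimensions divisible by %d", stride_total)
  widths <- c(1L, 8L, 16L, 24L, 32L)[seq_len(depth + 1L)]
  plans <- vector("list", depth)
  H <- input_size[1]; W <- input_size[2]
  for (l in seq_len(depth)) {
    plans[[l]] <- conv_plan(H, W, kernel = 3L, stride = 2L, pad = 1L)
    H <- plans[[l]]$H2; W <- plans[[l]]$W2
  }
  # average pooling to the final conv grid as a sparse row-gather
  k <- stride_total
  pool_idx <- {
    H0 <- input_size[1]; W0 <- input_size[2]
    H2 <- H0 %/% k; W2 <- W0 %/% k
    oy <- rep(seq_len(H2), times = W2); ox <- rep(seq_len(W2), each = H2)
    idx <- matrix(0L, H2 * W2, k * k)
    o <- 0L
    for (kx in seq_len(k) - 1L) for (ky in seq_len(k) - 1L) {
      o <- o + 1L
      idx[, o] <- ((oy - 1L) * k + ky + 1L) + ((ox - 1L) * k + kx) * H0
    }
    idx
  }
  pool_forward <- function(X, N) {
    Xm <- matrix(X, prod(input_size), N)
    chans <- list(Xm, pmax(Xm - 0.25, 0), pmax(Xm - 0.5, 0), pmax(Xm - 0.75, 0))
    res <- vapply(chans, function(ch) {
      out <- matrix(0, nrow(pool_idx), N)
      for (o in seq_len(ncol(pool_idx))) out <- out + ch[pool_idx[, o], , drop = FALSE]
      as.numeric(out / ncol(pool_idx))
    }, numeric(nrow(pool_idx) * N))
    matrix(res, nrow = nrow(pool_idx) * N, ncol = length(chans))
  }
  structured_init <- function() {
    avg <- rep(1 / 9, 9)
    sy <- as.numeric(outer(c(-1, 0, 1), c(1, 2, 1)) / 4)
    sx <- as.numeric(outer(c(1, 2, 1), c(-1, 0, 1)) / 4)
    lap <- avg * -1; lap[5] <- 8 / 9
    thresholds <- c(0.15, 0.35, 0.55, 0.75)
    jitter <- function(w, sd) w + matrix(stats::rnorm(length(w), sd = sd),
                                         nrow(w), ncol(w))
    params <- list(W1 = unname(jitter(cbind(avg, sy, sx, lap, avg, avg, avg, avg),
                                      0.02)),
                   b1 = c(0, 0, 0, 0, -thresholds))
    for (l in 2:depth) {
      cin <- widths[l]; cout <- widths[l + 1L]
      Wl <- matrix(0, 9 * cin, cout)
      for (ch in seq_len(min(cin, cout))) {
        pos <- (ch - 1L) * 9L + 1:9
        Wl[pos, ch] <- avg                       # smoothed pass-through
        if (ch + cin <= cout) Wl[pos, ch + cin] <- lap   # local contrast
      }
      params[[paste0("W", l)]] <- jitter(Wl, 0.02)
      params[[paste0("b", l)]] <- numeric(cout)
    }
    params
  }
  list(
    out_channels = widths[depth + 1L] + 4L,
    spatial = plans[[depth]]$P2,
    init = structured_init,
    forward = function(params, X, N, keep_cache = FALSE) {
      act <- X
      caches <- masks <- vector("list", depth)
      for (l in seq_len(depth)) {
        f <- conv_forward(act, N, params[[paste0("W", l)]],
                          params[[paste0("b", l)]], plans[[l]], keep_cache)
        act <- relu(f$out)
        if (keep_cache) { caches[[l]] <- f$cache; masks[[l]] <- f$out > 0 }
      }
      out <- cbind(act, pool_forward(X, N))
      cache <- if (keep_cache) list(caches = caches, masks = masks) else NULL
      list(out = out, cache = cache)
    },
    backward = function(params, cache, dOut, N) {
      # the pooling branch has no parameters; drop its channels
      d <- dOut[, seq_len(widths[depth + 1L]), drop = FALSE] * cache$masks[[depth]]
      grads <- list()
      for (l in rev(seq_len(depth))) {
        bg <- conv_backward(d, N, params[[paste0("W", l)]], plans[[l]],
                            cache$caches[[l]], need_dx = l > 1L)
        grads[[paste0("W", l)]] <- bg$dW
        grads[[paste0("b", l)]] <- bg$db
        if (l > 1L) d <- bg$dX * cache$masks[[l - 1L]]
      }
      grads
    })
}

tiny2conv_factory <- function(input_size) tinyconv_factory(input_size, depth = 2L)
tiny4conv_factory <- function(input_size) tinyconv_factory(input_size, depth = 4L)

# Parameter-free backbone: the raw slice is its own one-channel feature
# map. Useful for exercising the registry and head contracts.
identity_backbone_factory <- function(input_size) {
  P <- prod(input_size)
  list(out_channels = 1L,
       spatial = P,
       init = function() list(),
       forward = function(params, X, N, keep_cache = FALSE)
         list(out = X, cache = NULL),
       backward = function(params, cache, dOut, N) list())
}

register_backbone("tiny2conv", tiny2conv_factory)
register_backbone("tiny4conv", tiny4conv_factory)
register_backbone("identity", identity_backbone_factory)

#' Scorer configuration
#'
#' @param backbone_id a registered backbone name (default `"tiny2conv"`).
#' @param head_width number of 1 x 1 filters in the regression head
#'   (default 512; small values such as 32 are adequate for desk-scale
#'   models).
#' @param input_size slice size `c(rows, cols)` expected by the network
#'   (default `c(128, 128)`).
#' @return an object of class `bpr_scorer_config`.
#' @export
scorer_config <- function(backbone_id = "tiny2conv", head_width = 512L,
                          input_size = c(128L, 128L)) {
  assert_that(is_count(head_width), "head_width must be >= 1")
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  structure(list(backbone_id = backbone_id,
                 head_width = as.integer(head_width),
                 input_size = as.integer(input_size)),
            class = "bpr_scorer_config")
}

#' Initialize a slice-scoring model
#'
#' @param config a [scorer_config()].
#' @param seed integer seed for the parameter initialization.
#' @return an object of class `bpr_scorer`.
#' @export
scorer_init <- function(config = scorer_config(), seed = 0L) {
  backbone <- get_backbone(config$backbone_id, config$input_size)
  params <- with_seed(seed, {
    bp <- backbone$init()
    C <- backbone$out_channels
    hw <- config$head_width
    list(backbone = bp,
         head = list(Wh = init_weight(C, hw), bh = numeric(hw),
                     w = init_weight(hw, 1L), b = 0))
  })
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "bpr_scorer")
}

#' @export
print.bpr_scorer <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("Slice scorer: backbone '%s', head width %d, input %d x %d, %d parameters\n",
              x$config$backbone_id, x$config$head_width,
              x$config$input_size[1], x$config$input_size[2], np))
  invisible(x)
}

# Forward pass over a batch of N slices given as an input matrix
# (P * N, 1). Returns scores (length N) and, optionally, the caches
# needed for the backward pass.
scorer_forward <- function(model, X, N, keep_cache = FALSE) {
  backbone <- get_backbone(model$config$backbone_id, model$config$input_size)
  bb <- backbone$forward(model$params$backbone, X, N, keep_cache)
  hp <- model$params$head
  P2 <- backbone$spatial
  Hpre <- sweep(bb$out %*% hp$Wh, 2, hp$bh, `+`)
  Hact <- relu(Hpre)
  groups <- rep(seq_len(N), each = P2)
  G <- rowsum(Hact, groups) / P2                 # (N, head_width) pooled
  scores <- as.numeric(G %*% hp$w + hp$b)
  cache <- if (keep_cache) list(backbone = bb$cache, F = bb$out,
                                mask = Hpre > 0, G = G, P2 = P2,
                                groups = groups, bb = backbone) else NULL
  list(scores = scores, cache = cache)
}

# Backward pass: dscores (length N) -> gradients shaped like model$params.
scorer_backward <- function(model, cache, dscores, N) {
  hp <- model$params$head
  dG <- matrix(dscores, ncol = 1) %*% t(hp$w)    # (N, hw)
  dw <- crossprod(cache$G, matrix(dscores, ncol = 1))
  db <- sum(dscores)
  dH <- (dG / cache$P2)[cache$groups, , drop = FALSE] * cache$mask
  dWh <- crossprod(cache$F, dH)
  dbh <- colSums(dH)
  dF <- dH %*% t(hp$Wh)
  bbg <- cache$bb$backward(model$params$backbone, cache$backbone, dF, N)
  list(backbone = bbg, head = list(Wh = dWh, bh = dbh, w = dw, b = db))
}

# Assemble a batch input matrix from a list of H x W slices.
slices_to_input <- function(slices, input_size) {
  P <- prod(input_size)
  X <- matrix(0, P * length(slices), 1L)
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    assert_that(all(dim(s) == input_size),
                "slice %d is %d x %d but the model expects %d x %d",
                i, nrow(s), ncol(s), input_size[1], input_size[2])
    X[(i - 1L) * P + seq_len(P), 1L] <- as.numeric(s)
  }
  X
}

#' Score a stack of preprocessed slices
#'
#' Applies the scorer independently to each slice (time-distributed): the
#' score of a slice depends only on its own pixels and the model state.
#'
#' @param model a `bpr_scorer`.
#' @param pixels list of `input_size` matrices, or a 3-D array
#'   `(m, rows, cols)`.
#' @return numeric vector of `m` raw (unbounded) slice scores.
#' @export
score_stack <- function(model, pixels) {
  assert_that(inherits(model, "bpr_scorer"), "model must be a bpr_scorer")
  if (is.array(pixels) && length(dim(pixels)) == 3L)
    pixels <- lapply(seq_len(dim(pixels)[1]), function(i) pixels[i, , ])
  X <- slices_to_input(pixels, model$config$input_size)
  scorer_forward(model, X, length(pixels))$scores
}

#' Score every slice of a volume
#'
#' Each slice is preprocessed exactly as at inference time (min-max
#' normalization to `[0, 1]` and resizing to the model's input size; no
#' random augmentation) and scored independently.
#'
#' @param model a `bpr_scorer`.
#' @param volume a `bpr_volume`.
#' @param batch_size slices per forward pass (default 128).
#' @return numeric raw score curve of length `n_slices(volume)`.
#' @export
score_volume <- function(model, volume, batch_size = 128L) {
  assert_that(inherits(model, "bpr_scorer"), "model must be a bpr_scorer")
  t <- n_slices(volume)
  assert_that(t >= 1, "empty volume")
  size <- model$config$input_size
  out <- numeric(t)
  for (start in seq(1L, t, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, t)
    slices <- lapply(idx, function(z) preprocess_slice(volume$voxels[z, , ], size))
    out[idx] <- score_stack(model, slices)
  }
  out
}

#' Save / load a scorer checkpoint
#'
#' Checkpoints are JSON files holding the configuration, the
#' initialization seed, and all weights at full precision.
#'
#' @param model a `bpr_scorer`.
#' @param path output path.
#' @return `path` invisibly (`save_scorer`); a `bpr_scorer`
#'   (`load_scorer`).
#' @export
save_scorer <- function(model, path) {
  assert_that(inherits(model, "bpr_scorer"), "model must be a bpr_scorer")
  flat <- function(group) lapply(group, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.numeric(p)))
  payload <- list(schema = "bpregress-scorer-1",
                  config = unclass(model$config), seed = model$seed,
                  backbone = flat(model$params$backbone),
                  head = flat(model$params$head))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(payload$schema, "bpregress-scorer-1"),
              "not a scorer checkpoint: %s", path, class = "bpr_schema_error")
  unflat <- function(group) lapply(group, function(p) {
    d <- unlist(p$dim)
    if (length(d) > 1) array(unlist(p$data), d) else
      if (d == 1) unlist(p$data) else unlist(p$data)
  })
  cfg <- scorer_config(payload$config$backbone_id,
                       payload$config$head_width, payload$config$input_size)
  params <- list(backbone = unflat(payload$backbone), head = unflat(payload$head))
  # restore matrix shapes dropped by JSON for the head
  structure(list(config = cfg, params = params, seed = payload$seed),
            class = "bpr_scorer")
}
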