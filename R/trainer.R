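# Self-supervised training loop: each epoch draws one fresh random
# equidistant slice stack per training volume, augments each stack with
# one shared set of augmentation parameters, scores all slices
# time-distributed, and minimizes order_loss + distance_loss over the
# g x m score matrix with RMSprop.

#' Training configuration
#'
#' @param epochs training epochs (default 400).
#' @param batch_volumes volumes per batch, the `g` of the loss (default
#'   16; each volume contributes one `m`-slice stack).
#' @param m slices per stack (default 8).
#' @param k_range candidate stack spacings (default `1:4`).
#' @param learning_rate RMSprop learning rate (default `1e-4`, the
#'   fine-tuning rate used with large pretrained backbones; short
#'   from-scratch runs of the tiny registry backbones train better
#'   around `1e-3`--`2e-3` with `batch_volumes = 1` — see the methods
#'   vignette).
#' @param rmsprop_alpha,rmsprop_eps RMSprop smoothing constant and
#'   denominator floor.
#' @param momentum RMSprop momentum (default 0, plain RMSprop; desk-scale
#'   runs of the small from-scratch backbone benefit from 0.9).
#' @param beta smooth-L1 transition point of the distance loss.
#' @param seed master seed; per-epoch sampling/augmentation streams and
#'   the parameter initialization are derived from it.
#' @param augment an [augment_config()]; its `output_size` must equal the
#'   scorer's `input_size`.
#' @param scorer a [scorer_config()].
#' @return an object of class `bpr_train_config`.
#' @export
train_config <- function(epochs = 400L, batch_volumes = 16L, m = 8L,
                         k_range = 1:4, learning_rate = 1e-4,
                         rmsprop_alpha = 0.99, rmsprop_eps = 1e-8,
                         momentum = 0, beta = 1, seed = 0L,
                         augment = augment_config(),
                         scorer = scorer_config()) {
  assert_that(is_count(epochs), "epochs must be >= 1")
  assert_that(is_count(batch_volumes), "batch_volumes must be >= 1")
  assert_that(is_count(m, 3), "m must be >= 3 (distance loss needs 3 slices)")
  assert_that(learning_rate > 0, "learning_rate must be > 0")
  assert_that(all(augment$output_size == scorer$input_size),
              "augment output_size (%s) must equal scorer input_size (%s)",
              paste(augment$output_size, collapse = "x"),
              paste(scorer$input_size, collapse = "x"))
  structure(list(epochs = as.integer(epochs),
                 batch_volumes = as.integer(batch_volumes),
                 m = as.integer(m), k_range = as.integer(k_range),
                 learning_rate = learning_rate,
                 rmsprop_alpha = rmsprop_alpha, rmsprop_eps = rmsprop_eps,
                 momentum = momentum, beta = beta, seed = as.integer(seed),
                 augment = augment, scorer = scorer),
            class = "bpr_train_config")
}

# Draw and augment one stack per volume; returns the input matrix rows for
# each volume plus the stack bookkeeping. Consumes the global RNG.
draw_epoch_stacks <- function(volumes, config) {
  lapply(volumes, function(vol) {
    st <- sample_stack(n_slices(vol), config$m, config$k_range)
    aug <- draw_augment_params(config$augment)
    pixels <- lapply(st$indices, function(z)
      apply_augment(vol$voxels[z, , ], aug, config$augment))
    list(stack = st, pixels = pixels)
  })
}

#' Train the self-supervised slice scorer
#'
#' @param x a `bpr_cohort` (its train split is used) or a list of
#'   `bpr_volume`s.
#' @param config a [train_config()].
#' @param eval_volumes optional list of volumes monitored each epoch with
#'   [evaluate_monotonicity()]; when given and `out_dir` is set, the
#'   checkpoint with the best mean monotonic fraction is kept as
#'   `best.json`.
#' @param out_dir optional checkpoint directory; the final model is
#'   written to `checkpoint.json` and the history to `history.csv`.
#' @param verbose print one line per epoch.
#' @return list with `model` (`bpr_scorer`) and `history` (data.frame
#'   with per-epoch mean per-volume losses and, if monitored, the eval
#'   monotonic fraction).
#' @export
train <- function(x, config = train_config(), eval_volumes = NULL,
                  out_dir = NULL, verbose = FALSE) {
  volumes <- if (inherits(x, "bpr_cohort")) x$volumes[x$split$train] else x
  assert_that(length(volumes) >= 1, "train split is empty")
  for (vol in volumes) {
    t <- n_slices(vol)
    if (t < config$m + 1)
      stop_bpr("volume '%s' has t = %d slices; need at least m + 1 = %d",
               vol$subject_id, t, config$m + 1, class = "bpr_validation_error")
    admissible_k(t, config$m, config$k_range)  # errors if k_range invalid
  }
  model <- scorer_init(config$scorer, seed = derive_seed(config$seed, "init"))
  opt <- rmsprop_init(model$params)
  history <- vector("list", config$epochs)
  best_metric <- -Inf
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (epoch in seq_len(config$epochs)) {
    ep <- with_seed(derive_seed(config$seed, paste0("epoch", epoch)), {
      order_v <- sample(seq_along(volumes))
      stacks <- draw_epoch_stacks(volumes[order_v], config)
      batches <- split(seq_along(stacks),
                       ceiling(seq_along(stacks) / config$batch_volumes))
      tot <- ord <- dst <- 0
      for (b in batches) {
        g <- length(b)
        pixels <- unlist(lapply(stacks[b], `[[`, "pixels"), recursive = FALSE)
        X <- slices_to_input(pixels, config$scorer$input_size)
        fw <- scorer_forward(model, X, g * config$m, keep_cache = TRUE)
        S <- matrix(fw$scores, nrow = config$m)       # m x g, column per volume
        S <- t(S)
        lo <- order_loss(S)
        ld <- distance_loss(S, config$beta)
        dS <- total_loss_grad(S, config$beta)
        dscores <- as.numeric(t(dS))                  # back to slice order
        grads <- scorer_backward(model, fw$cache, dscores, g * config$m)
        step <- rmsprop_step(model$params, grads, opt, config$learning_rate,
                             config$rmsprop_alpha, config$rmsprop_eps,
                             config$momentum)
        model$params <- step$params
        opt <- step$state
        tot <- tot + lo + ld; ord <- ord + lo; dst <- dst + ld
      }
      nv <- length(stacks)
      c(total = tot / nv, order = ord / nv, distance = dst / nv)
    })
    row <- data.frame(epoch = epoch, total = ep[["total"]],
                      order = ep[["order"]], distance = ep[["distance"]])
    if (!is.null(eval_volumes)) {
      mono <- evaluate_monotonicity(model, eval_volumes)
      row$eval_monotonic_fraction <- mono$mean_fraction
      if (!is.null(out_dir) && mono$mean_fraction > best_metric) {
        best_metric <- mono$mean_fraction
        save_scorer(model, file.path(out_dir, "best.json"))
      }
    }
    history[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %d/%d: loss %.4f (order %.4f, distance %.4f)",
                      epoch, config$epochs, row$total, row$order, row$distance))
  }
  history <- do.call(rbind, history)
  if (!is.null(out_dir)) {
    save_scorer(model, file.path(out_dir, "checkpoint.json"))
    utils::write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  list(model = model, history = history)
}

#' Monotonicity of raw score curves
#'
#' For each volume, the fraction of adjacent slice pairs whose raw score
#' strictly increases, plus the Spearman correlation between slice index
#' and raw score. Computed on raw (unsmoothed) curves.
#'
#' @param model a `bpr_scorer`.
#' @param volumes list of `bpr_volume`s.
#' @return list with `fractions`, `spearman` (per volume),
#'   `mean_fraction`, `mean_spearman`.
#' @export
evaluate_monotonicity <- function(model, volumes) {
  assert_that(length(volumes) >= 1, "volumes must be non-empty")
  fractions <- numeric(length(volumes))
  rho <- numeric(length(volumes))
  for (i in seq_along(volumes)) {
    curve <- score_volume(model, volumes[[i]])
    d <- diff(curve)
    fractions[i] <- mean(d > 0)
    rho[i] <- stats::cor(seq_along(curve), curve, method = "spearman")
  }
  list(fractions = fractions, spearman = rho,
       mean_fraction = mean(fractions), mean_spearman = mean(rho))
}
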