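# Training loop: determinism, validation, history bookkeeping,
# monotonicity metrics. Deeper end-to-end recovery lives in
# test-acceptance.R; these runs are deliberately tiny.

tiny_train_setup <- function(n = 4) {
  spec <- phantom_spec(slice_count_range = c(40, 50), in_plane_size = c(32, 32),
                       seed = 7)
  vols <- lapply(seq_len(n), function(i) generate_phantom(spec, i)$volume)
  cfg <- train_config(epochs = 2, batch_volumes = 2, learning_rate = 1e-2,
                      seed = 11,
                      augment = augment_config(output_size = c(32, 32)),
                      scorer = scorer_config("tiny2conv", head_width = 8,
                                             input_size = c(32, 32)))
  list(vols = vols, cfg = cfg)
}

test_that("training is reproducible under a fixed seed", {
  s <- tiny_train_setup()
  a <- train(s$vols, s$cfg)
  b <- train(s$vols, s$cfg)
  expect_equal(a$history, b$history, tolerance = 1e-12)
  expect_equal(a$model$params, b$model$params, tolerance = 1e-12)
  # and sensitive to the seed
  cfg2 <- s$cfg; cfg2$seed <- 12L
  c2 <- train(s$vols, cfg2)
  expect_false(isTRUE(all.equal(a$history$total, c2$history$total)))
})

test_that("training records one finite history row per epoch", {
  s <- tiny_train_setup()
  fit <- train(s$vols, s$cfg)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(unlist(fit$history))))
  expect_equal(fit$history$total, fit$history$order + fit$history$distance,
               tolerance = 1e-9)
})

test_that("training does not mutate the input volumes", {
  s <- tiny_train_setup()
  before <- lapply(s$vols, function(v) v$voxels)
  invisible(train(s$vols, s$cfg))
  after <- lapply(s$vols, function(v) v$voxels)
  expect_identical(before, after)
})

test_that("configuration and volumes are validated before training", {
  s <- tiny_train_setup()
  expect_error(train_config(epochs = 0), "epochs")
  # a volume too short for the stack length is rejected by name
  small <- as_volume(array(stats::runif(8 * 32 * 32), c(8, 32, 32)),
                     subject_id = "shorty")
  err <- tryCatch(train(c(s$vols, list(small)), s$cfg), error = identity)
  expect_s3_class(err, "bpr_validation_error")
  expect_match(conditionMessage(err), "shorty")
})

test_that("checkpoints and history are written to the output directory", {
  s <- tiny_train_setup()
  dir <- withr::local_tempdir()
  fit <- train(s$vols, s$cfg, eval_volumes = s$vols[1], out_dir = dir)
  expect_true(file.exists(file.path(dir, "checkpoint.json")))
  expect_true(file.exists(file.path(dir, "best.json")))
  h <- utils::read.csv(file.path(dir, "history.csv"))
  expect_equal(nrow(h), 2)
  expect_true("eval_monotonic_fraction" %in% names(h))
  # checkpointed model reproduces in-memory scores
  back <- load_scorer(file.path(dir, "checkpoint.json"))
  curve_a <- score_volume(fit$model, s$vols[[1]])
  curve_b <- score_volume(back, s$vols[[1]])
  expect_equal(curve_b, curve_a, tolerance = 1e-12)
})

test_that("monotonicity fractions match their definitions", {
  # synthetic model-free check through a fake scorer is overkill: use
  # direct curves via a trivial identity-backbone model on crafted input
  up <- c(1, 2, 3, 4, 5)
  expect_equal(mean(diff(up) > 0), 1)
  down <- rev(up)
  expect_equal(mean(diff(down) > 0), 0)
  # evaluate_monotonicity agrees with a brute-force recomputation
  s <- tiny_train_setup(2)
  model <- scorer_init(s$cfg$scorer, seed = 1)
  mono <- evaluate_monotonicity(model, s$vols[1:2])
  for (i in 1:2) {
    cv <- score_volume(model, s$vols[[i]])
    expect_equal(mono$fractions[i], mean(diff(cv) > 0))
    expect_equal(mono$spearman[i],
                 stats::cor(seq_along(cv), cv, method = "spearman"))
  }
  expect_equal(mono$mean_fraction, mean(mono$fractions))
})

test_that("a replayed epoch reproduces the recorded loss", {
  # with a single volume and one epoch, the recorded loss equals the
  # loss of the (seeded) stack evaluated at the pre-update parameters
  spec <- phantom_spec(slice_count_range = c(40, 40), in_plane_size = c(32, 32),
                       seed = 3)
  vol <- generate_phantom(spec, 1)$volume
  cfg <- train_config(epochs = 1, batch_volumes = 1, learning_rate = 1e-3,
                      seed = 21,
                      augment = augment_config(output_size = c(32, 32)),
                      scorer = scorer_config("tiny2conv", head_width = 8,
                                             input_size = c(32, 32)))
  fit <- train(list(vol), cfg)
  # replay: rebuild the initial model and the epoch's stack from the seeds
  model0 <- scorer_init(cfg$scorer, seed = bpregress:::derive_seed(cfg$seed, "init"))
  replay <- with_seed(bpregress:::derive_seed(cfg$seed, "epoch1"), {
    invisible(sample(1L))   # the volume-order shuffle
    stacks <- bpregress:::draw_epoch_stacks(list(vol), cfg)
    X <- bpregress:::slices_to_input(stacks[[1]]$pixels, cfg$scorer$input_size)
    fw <- bpregress:::scorer_forward(model0, X, cfg$m)
    total_loss(matrix(fw$scores, nrow = 1))
  })
  expect_equal(fit$history$total[1], replay, tolerance = 1e-10)
})
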