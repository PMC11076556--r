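test_that("classifier outputs normalised probabilities and seeded init is exact", {
  m1 <- build_classifier(100, 1, 5, seed = 3)
  m2 <- build_classifier(100, 1, 5, seed = 3)
  expect_identical(flatten_params(m1), flatten_params(m2))
  X <- array(rnorm(4 * 100), c(4, 100, 1))
  p <- predict_proba(m1, X)
  expect_equal(dim(p), c(4, 5))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("shared-section extraction and injection round-trip exactly", {
  m1 <- build_classifier(100, 1, 5, seed = 1)
  m2 <- build_classifier(100, 1, 5, seed = 2)
  sh <- extract_shared(m1)
  m2b <- inject_shared(m2, sh)
  expect_identical(extract_shared(m2b), sh)
  expect_identical(flatten_params(m2b, "shared"), flatten_params(m1, "shared"))
  # private sections untouched
  expect_identical(flatten_params(m2b, "private_front"),
                   flatten_params(m2, "private_front"))
  bad <- sh; names(bad)[1] <- "nope_W"
  expect_error(inject_shared(m2, bad), "names do not match")
})

test_that("flatten order partitions the parameter vector consistently", {
  m <- build_classifier(100, 1, 5, seed = 4)
  n_all <- length(flatten_params(m, "all"))
  n_parts <- length(flatten_params(m, "shared")) +
    length(flatten_params(m, "private_front")) +
    length(flatten_params(m, "private_back"))
  expect_equal(n_all, n_parts)
  # perturbing one tensor changes exactly its slice
  v0 <- flatten_params(m)
  nm <- m$flatten_order[3]
  m$params[[nm]] <- m$params[[nm]] + 1
  v1 <- flatten_params(m)
  sizes <- vapply(m$flatten_order, function(n) length(m$params[[n]]), numeric(1))
  offs <- cumsum(c(0, sizes))
  idx <- (offs[3] + 1):offs[4]
  expect_true(all(v1[idx] != v0[idx]))
  expect_identical(v1[-idx], v0[-idx])
})

test_that("class weights are inverse frequencies normalised to mean one", {
  expect_equal(class_weights(rep(0:4, each = 100)), rep(1, 5))
  w <- class_weights(c(rep(0L, 10), rep(1L, 40)))
  expect_equal(w[1] / w[2], 4)
  expect_equal(mean(w[1:2]), 1)
  expect_equal(w[3:5], rep(0, 3))   # absent classes
})

test_that("local training reduces loss and obeys the simulated clock", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  m <- build_classifier(100, 1, 5, seed = 5)
  rec <- training_recipe(local_epochs = 6)
  tl <- train_local(m, sc$clients[[1]], rec, seed = 21)
  expect_false(tl$flagged)
  expect_lte(tl$last_loss, tl$first_loss)
  expect_equal(tl$duration, rec$base_duration)
  tl3 <- train_local(m, sc$clients[[1]], rec, seed = 21, duration_multiplier = 3)
  expect_equal(tl3$duration, 3 * rec$base_duration)
  # same seed, same data: training is bitwise reproducible
  expect_identical(flatten_params(tl$model),
                   flatten_params(train_local(m, sc$clients[[1]], rec, seed = 21)$model))
})

test_that("autoencoder respects shapes and the bottleneck constraint", {
  expect_error(build_autoencoder(50, latent_dim = 50), "bottleneck")
  ae <- build_autoencoder(100, latent_dim = 16, seed = 2)
  x <- matrix(rnorm(300), 3, 100)
  r <- ae_reconstruct(ae, x)
  expect_equal(dim(r), dim(x))
  expect_gt(sum((r - x)^2), 0)   # untrained reconstruction differs
})

test_that("trained autoencoder scores benchmark-like signals below tampered ones", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  ae <- build_autoencoder(100, latent_dim = 16, seed = 3)
  ae <- train_autoencoder(ae, sc$benchmark$X[sc$benchmark$train_idx, , , drop = FALSE],
                          epochs = 40, seed = 4)
  d <- sc$clients[[1]]
  td <- tamper_noise(d, 0, 0.2, seed = 6)
  # per-signal comparison over >= 100 signals (records x both datasets)
  per_signal <- function(ds) vapply(seq_len(dim(ds$X)[1]), function(i) {
    x <- ds$X[i, , 1]
    dtw_distance(x, as.vector(ae_reconstruct(ae, x)), band = 10)
  }, numeric(1))
  expect_gt(mean(per_signal(td)), mean(per_signal(d)))
  expect_gt(sum(dim(d$X)[1] + dim(td$X)[1]), 80)
})

test_that("multi-channel waveforms flow through generator, model and DTW", {
  w <- generate_waveform(1, 40, seed = 5, sampling_rate = 50, duration = 2,
                         channel_count = 3)
  expect_equal(dim(w$samples), c(100, 3))
  m <- build_classifier(100, 3, 5, seed = 2)
  X <- array(rnorm(2 * 100 * 3), c(2, 100, 3))
  p <- predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})

test_that("backpropagated gradients match finite differences", {
  m <- build_classifier(100, 1, 5, seed = 9)
  set.seed(10)
  X <- array(rnorm(6 * 100), c(6, 100, 1))
  y <- sample(0:4, 6, replace = TRUE)
  cw <- rep(1, 5)
  loss_at <- function(net) {
    fw <- orbitlearn:::net_forward(net, X)
    orbitlearn:::weighted_ce(fw$probs, fw$logits, y, cw)$loss
  }
  fw <- orbitlearn:::net_forward(m, X, cache = TRUE)
  lw <- orbitlearn:::weighted_ce(fw$probs, fw$logits, y, cw)
  grads <- orbitlearn:::net_backward(m, lw$dlogits, fw$caches, 6)
  eps <- 1e-5
  for (nm in c("conv1_W", "conv2_W", "conv3_W", "head_W", "head_b")) {
    set.seed(derive_seed(11, nm))
    for (idx in sample(length(m$params[[nm]]), 3)) {
      mp <- m; mp$params[[nm]][idx] <- mp$params[[nm]][idx] + eps
      mm <- m; mm$params[[nm]][idx] <- mm$params[[nm]][idx] - eps
      num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(grads[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})
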