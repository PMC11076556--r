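test_that("spearman coefficient matches the closed form on canonical cases", {
  x <- c(3.2, 1.5, 9.8, 4.4, 7.7)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)          # exact rank reversal
  expect_equal(spearman_rho(x, max(x) - x)$rho, -1)
  sc <- spearman_rho(x, x)
  expect_equal(sc$n, 5)
  expect_equal(sc$d, rep(0, 5))
  expect_error(spearman_rho(x, x[1:3]), "equal length")
  expect_error(spearman_rho(rep(1, 5), x), "constant vector")
  expect_error(spearman_rho(1, 2), "at least two")
})

test_that("tie handling reduces to the product-moment correlation of ranks", {
  set.seed(41)
  for (i in 1:25) {
    x <- sample(1:6, 12, replace = TRUE)   # heavy ties
    y <- sample(1:6, 12, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    got <- spearman_rho(x, y)
    expect_true(got$tied)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("dtw satisfies identity, symmetry and the single-cell case", {
  set.seed(13)
  for (i in 1:30) {
    a <- rnorm(sample(2:12, 1))
    b <- rnorm(sample(2:12, 1))
    expect_equal(dtw_distance(a, a), 0)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
  expect_equal(dtw_distance(0, 3), 3)
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
})

test_that("dtw equals brute-force path enumeration on short sequences", {
  set.seed(29)
  for (i in 1:40) {
    a <- round(rnorm(sample(1:7, 1)), 2)
    b <- round(rnorm(sample(1:7, 1)), 2)
    expect_equal(dtw_distance(a, b), dtw_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("multi-channel dtw is the sum of per-channel distances", {
  a <- matrix(rnorm(20), 10, 2)
  b <- matrix(rnorm(20), 10, 2)
  expect_equal(dtw_distance(a, b),
               dtw_distance(a[, 1], b[, 1]) + dtw_distance(a[, 2], b[, 2]))
})

test_that("weight similarity is exact for copies and drops under perturbation", {
  m <- build_classifier(100, 1, 5, seed = 6)
  ref <- m
  expect_equal(assess_weight_similarity(m, ref), 1)
  flipped <- m
  sh_names <- names(extract_shared(m))
  flipped$params[[sh_names[1]]] <- -flipped$params[[sh_names[1]]]
  expect_lt(assess_weight_similarity(flipped, ref, "shared"), 1)
  # shared-section restriction: private changes are invisible
  priv <- m
  priv$params[["head_W"]] <- priv$params[["head_W"]] * 5
  expect_equal(assess_weight_similarity(priv, ref, "shared"), 1)
  other <- build_classifier(200, 1, 5, seed = 6, arch = "deep")
  expect_error(assess_weight_similarity(other, ref), "architecture mismatch")
})

test_that("data similarity is invariant to record order and flags tampering", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  ae <- build_autoencoder(100, latent_dim = 16, seed = 3)
  ae <- train_autoencoder(ae, sc$benchmark$X[sc$benchmark$train_idx, , , drop = FALSE],
                          epochs = 40, seed = 4)
  d <- sc$clients[[1]]
  s1 <- assess_data_similarity(d, ae, probe_size = 20, seed = 5, band = 10)
  perm <- sample(length(d$labels))
  dp <- d
  dp$X <- d$X[perm, , , drop = FALSE]
  dp$labels <- d$labels[perm]; dp$ages <- d$ages[perm]
  dp$record_ids <- d$record_ids[perm]
  s2 <- assess_data_similarity(dp, ae, probe_size = 20, seed = 5, band = 10)
  expect_equal(s1, s2)
  td <- tamper_noise(d, 0, 0.2, seed = 8)
  expect_gt(assess_data_similarity(td, ae, probe_size = 20, seed = 5, band = 10), s1)
  untrained <- build_autoencoder(100, latent_dim = 16, seed = 9)
  expect_error(assess_data_similarity(d, untrained), "not been trained")
})

test_that("benchmark scores lowest among untampered datasets", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  ae <- build_autoencoder(100, latent_dim = 16, seed = 3)
  ae <- train_autoencoder(ae, sc$benchmark$X[sc$benchmark$train_idx, , , drop = FALSE],
                          epochs = 40, seed = 4)
  sb <- assess_data_similarity(sc$benchmark, ae, probe_size = 20, seed = 2, band = 10)
  for (d in sc$clients) {
    sc_d <- assess_data_similarity(d, ae, probe_size = 20, seed = 2, band = 10)
    expect_lt(sb, sc_d * 1.5)   # benchmark at or near the minimum
  }
})
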