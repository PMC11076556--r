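test_that("waveform generation is a pure function of label, age and seed", {
  w1 <- generate_waveform(0, 50, seed = 11)
  w2 <- generate_waveform(0, 50, seed = 11)
  expect_identical(w1$samples, w2$samples)
  expect_equal(nrow(w1$samples), 1000)
  w3 <- generate_waveform(0, 50, seed = 12)
  expect_false(identical(w1$samples, w3$samples))
  expect_error(generate_waveform(7, 50), "unknown label")
  expect_error(generate_waveform(0, 150), "age out of")
})

test_that("conduction-disturbance class widens the QRS complex", {
  cfg <- scenario_config(sampling_rate = 100, duration = 4)
  tab <- class_param_table()
  expect_gt(tab$qrs_width_mult[tab$class == "CD"], 1)
  expect_gt(mean_fwhm(cfg, label = 2), mean_fwhm(cfg, label = 0))
})

test_that("hypertrophy raises R amplitude relative to normal", {
  amp <- function(lab) mean(vapply(1:20, function(i) {
    max(generate_waveform(lab, 50, seed = derive_seed(3, lab, i))$samples)
  }, numeric(1)))
  expect_gt(amp(3), 1.2 * amp(0))
})

test_that("classes are learnably separable from summary features", {
  skip_if_not_installed("rpart")
  cfg <- scenario_config(sampling_rate = 100, duration = 5)
  n_per <- 100
  feats <- NULL; labs <- integer(0)
  for (lab in 0:4) {
    for (i in seq_len(n_per)) {
      s <- generate_waveform(lab, runif(1, 20, 85),
                             seed = derive_seed(17, lab, i),
                             sampling_rate = 100, duration = 5)$samples[, 1]
      pk <- which.max(s)
      half <- s[pk] / 2
      lo <- pk; while (lo > 1 && s[lo - 1] > half) lo <- lo - 1
      hi <- pk; while (hi < length(s) && s[hi + 1] > half) hi <- hi + 1
      feats <- rbind(feats, c(rmax = max(s), rmin = min(s),
                              width = hi - lo + 1, sd = sd(s),
                              m = mean(s), absdiff = mean(abs(diff(s)))))
      labs <- c(labs, lab)
    }
  }
  df <- data.frame(feats, y = factor(labs))
  tr <- which(seq_len(nrow(df)) %% 5 != 0)
  fit <- rpart::rpart(y ~ ., df[tr, ], control = rpart::rpart.control(maxdepth = 4))
  pr <- predict(fit, df[-tr, ])
  pool_s <- c(); pool_l <- c()
  yte <- labs[-tr]
  for (c in 0:4) {
    pool_s <- c(pool_s, pr[, as.character(c)])
    pool_l <- c(pool_l, as.integer(yte == c))
  }
  expect_gt(auroc(pool_s, pool_l), 0.6)
})

test_that("Dirichlet partitioning yields pairwise-distinct label mixes", {
  cfg <- scenario_config(n_clients = 4, samples_per_client = 120,
                         sampling_rate = 50, duration = 2, seed = 5)
  sc <- generate_scenario(cfg)
  hists <- lapply(sc$clients, function(d) tabulate(d$labels + 1L, 5) / length(d$labels))
  for (i in 1:3) for (j in (i + 1):4) {
    tv <- sum(abs(hists[[i]] - hists[[j]])) / 2
    expect_gt(tv, 0.05)
  }
})

test_that("infinite Dirichlet concentration recovers near-uniform mixes", {
  cfg <- scenario_config(n_clients = 3, samples_per_client = 200,
                         sampling_rate = 50, duration = 2,
                         noniid_alpha = 1e6, seed = 8)
  sc <- generate_scenario(cfg)
  for (d in sc$clients) {
    h <- tabulate(d$labels + 1L, 5) / length(d$labels)
    expect_lt(max(abs(h - 0.2)), 0.12)   # sampling error only
  }
})

test_that("age partitioning respects the configured bins", {
  cfg <- scenario_config(n_clients = 6, samples_per_client = 30,
                         sampling_rate = 50, duration = 2,
                         scenario = "age_partition", seed = 4)
  sc <- generate_scenario(cfg)
  expect_true(all(sc$clients[[1]]$ages >= 18 & sc$clients[[1]]$ages <= 39))
  for (k in 1:6) {
    b <- cfg$age_bins[[k]]
    expect_true(all(sc$clients[[k]]$ages >= b[1] & sc$clients[[k]]$ages <= b[2]))
  }
})

test_that("each client dataset carries a stratified, exhaustive 80/20 split", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  for (d in sc$clients) {
    expect_length(intersect(d$train_idx, d$test_idx), 0)
    expect_setequal(c(d$train_idx, d$test_idx), seq_along(d$labels))
    expect_equal(length(d$train_idx) / length(d$labels), 0.8, tolerance = 0.1)
  }
})

test_that("noise tampering adds bounded uniform noise to z-scored signals", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  d <- sc$clients[[1]]
  z <- tamper_noise(d, 0, 0, seed = 3)       # zero noise: exactly z-scored
  expect_equal(z$tamper_tag, "noise")
  for (i in 1:3) {
    v <- z$X[i, , 1]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  td <- tamper_noise(d, 0, 0.2, seed = 3)
  shift <- rowMeans(matrix(td$X[, , 1] - z$X[, , 1], nrow = dim(td$X)[1]))
  expect_equal(mean(shift), 0.1, tolerance = 0.01)   # E U(0, 0.2)
  expect_true(all(td$X[, , 1] - z$X[, , 1] >= 0))
  expect_true(all(td$X[, , 1] - z$X[, , 1] <= 0.2))
  expect_identical(td$labels, d$labels)
  expect_error(tamper_noise(d, 0.3, 0.1, seed = 1), "high >= low")
})

test_that("label shuffling permutes the label multiset only", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  d <- sc$clients[[1]]
  td <- tamper_labels(d, seed = 5)
  expect_equal(sort(td$labels), sort(d$labels))
  expect_identical(td$X, d$X)
  expect_equal(td$tamper_tag, "label_shuffle")
  single <- d; single$X <- d$X[1, , , drop = FALSE]
  single$labels <- d$labels[1]; single$record_ids <- d$record_ids[1]
  expect_identical(tamper_labels(single, seed = 2)$labels, single$labels)
})

test_that("expected label-retention fraction matches the combinatorial oracle", {
  labels <- c(rep(0L, 6), rep(1L, 3), rep(2L, 1))
  n <- length(labels)
  expected <- sum((table(labels) / n)^2)
  d <- structure(list(client_id = 1L,
                      X = array(rnorm(n * 10), c(n, 10, 1)),
                      labels = labels, ages = rep(50, n),
                      record_ids = paste0("r", 1:n),
                      train_idx = 1:8, test_idx = 9:10, tamper_tag = "none"),
                 class = "client_dataset")
  keep <- vapply(1:400, function(i) {
    mean(tamper_labels(d, seed = i)$labels == labels)
  }, numeric(1))
  expect_equal(mean(keep), expected, tolerance = 0.03)
})

test_that("the benchmark is balanced, disjoint from clients and reproducible", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  b <- sc$benchmark
  expect_equal(length(unique(tabulate(b$labels + 1L, 5))), 1)  # uniform
  for (d in sc$clients)
    expect_length(intersect(b$record_ids, d$record_ids), 0)
  b2 <- make_benchmark(cfg)
  expect_identical(b$X, b2$X)
  expect_identical(b$labels, b2$labels)
})

test_that("tampering distortion grows with the noise upper bound", {
  cfg <- tiny_config()
  sc <- generate_scenario(cfg)
  d <- sc$clients[[1]]
  z <- tamper_noise(d, 0, 0, seed = 9)
  rms <- vapply(c(0.05, 0.1, 0.2), function(a) {
    td <- tamper_noise(d, 0, a, seed = 9)
    sqrt(mean((td$X - z$X)^2))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})
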