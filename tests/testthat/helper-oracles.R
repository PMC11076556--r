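# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (enumeration, pairwise counting,
# rank-then-correlate) kept separate from the package's own algorithms.

# Brute-force DTW: minimum cost over all monotone warping paths by plain
# recursion (no memoisation), absolute-difference local cost.
dtw_bruteforce <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    cost <- abs(a[i] - b[j])
    if (i == n && j == m) return(cost)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    cost + best
  }
  rec(1, 1)
}

# Brute-force AUROC: concordant-pair counting with half credit for ties.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Rank-then-product-moment Spearman oracle.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Elementwise weighted-mean oracle for FedAvg.
fedavg_oracle <- function(param_list, sizes) {
  w <- sizes / sum(sizes)
  out <- param_list[[1]] * 0
  for (i in seq_along(param_list)) out <- out + param_list[[i]] * w[i]
  out
}

# Full width at half maximum (in samples) of the dominant positive peak,
# averaged over records; used to check class-conditioned QRS widening.
mean_fwhm <- function(config, label, n = 25, seed = 99) {
  widths <- vapply(seq_len(n), function(i) {
    w <- generate_waveform(label, 50, seed = derive_seed(seed, label, i),
                           sampling_rate = config$sampling_rate,
                           duration = config$duration)
    s <- w$samples[, 1]
    pk <- which.max(s)
    half <- s[pk] / 2
    lo <- pk; while (lo > 1 && s[lo - 1] > half) lo <- lo - 1
    hi <- pk; while (hi < length(s) && s[hi + 1] > half) hi <- hi + 1
    hi - lo + 1
  }, numeric(1))
  mean(widths)
}

# Small-signal scenario used throughout the unit tests (cheap to train);
# any scenario_config() argument can be overridden.
tiny_config <- function(...) {
  defaults <- list(n_clients = 3L, samples_per_client = 45L,
                   sampling_rate = 50, duration = 2,
                   benchmark_size = 40L, seed = 7L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

tiny_recipe <- function(...) training_recipe(local_epochs = 2L, ...)
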