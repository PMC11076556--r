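#' Spearman's rank-order correlation coefficient
#'
#' Ranks both vectors (average ranks on ties). For tie-free inputs the
#' coefficient is computed by the classical closed form
#' \deqn{\rho = 1 - \frac{6 \sum d_i^2}{n(n^2 - 1)}}
#' where \eqn{d_i} is the difference of the two ranks of observation
#' \eqn{i}; with ties it falls back to the product-moment correlation of
#' the rank vectors, which reduces to the closed form in the tie-free
#' case. The result is clipped to \eqn{[-1, 1]} only against floating
#' rounding. A value of +1 indicates perfect rank association, e.g.
#' between a reference model's weights and an untouched copy.
#'
#' @param x,y numeric vectors of equal length `n >= 2`
#' @return object of class `spearman_computation`: list with `rho`, `n`,
#'   `d` (rank differences) and `tied` (whether ties were present)
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least two observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("constant vector: rank variance is zero, rho undefined")
  tied <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  d <- rx - ry
  rho <- if (!tied) {
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
  rho <- min(1, max(-1, rho))
  structure(list(rho = rho, n = n, d = d, tied = tied),
            class = "spearman_computation")
}

#' Dynamic time warping distance
#'
#' Classical dynamic-programming DTW with absolute-difference local cost
#' and unit steps (match, insert, delete). Symmetric, non-negative and
#' zero on identical sequences. For long signals an optional Sakoe-Chiba
#' band restricts the warping path to a diagonal corridor, cutting cost
#' from `O(nm)` to `O(n * band)`. Multi-channel inputs (matrices with one
#' channel per column) are scored as the sum of per-channel distances.
#'
#' @param a,b numeric vectors, or matrices with matching channel counts
#' @param band Sakoe-Chiba half-width in samples; `NULL` (default) for
#'   unconstrained warping
#' @return non-negative scalar distance
#' @export
dtw_distance <- function(a, b, band = NULL) {
  bnd <- if (is.null(band)) -1L else as.integer(band)
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, ncol = 1)
    if (!is.matrix(b)) b <- matrix(b, ncol = 1)
    if (ncol(a) != ncol(b)) stop("channel counts differ")
    return(sum(vapply(seq_len(ncol(a)), function(j)
      dtw_cost_cpp(a[, j], b[, j], bnd), numeric(1))))
  }
  if (length(a) == 0 || length(b) == 0) stop("sequences must be non-empty")
  dtw_cost_cpp(as.numeric(a), as.numeric(b), bnd)
}

#' Client-side data-similarity assessment
#'
#' Draws a seeded probe subset of the client's records, reconstructs each
#' probe signal through the benchmark-trained autoencoder, and scores the
#' input-to-reconstruction DTW distance. Probe signals enter the assessor
#' exactly as stored — without renormalisation — so anomalies of scale or
#' texture remain visible. The per-signal distances are aggregated
#' (median by default) into one scalar; only this scalar leaves the
#' client, never the data. Signals close to the benchmark distribution
#' reconstruct well and score low; tampered or out-of-distribution
#' signals score high.
#'
#' @param dataset a `client_dataset`
#' @param ae a trained `autoencoder` (see [train_autoencoder()])
#' @param probe_size number of records probed (default 64, capped at the
#'   dataset size)
#' @param seed integer seed for probe sampling
#' @param aggregate `"mean"` (default) or `"median"`; the mean responds
#'   smoothly to small distributed distortions that the median's sampling
#'   discreteness can mask
#' @param band Sakoe-Chiba half-width passed to [dtw_distance()]
#'   (default 15)
#' @param normalize probe preprocessing: `"none"` (default; signals enter
#'   as stored), `"center"` (subtract each channel's mean) or `"zscore"`
#' @return non-negative scalar data-distance score
#' @export
assess_data_similarity <- function(dataset, ae, probe_size = 64L, seed = 1L,
                                   aggregate = c("mean", "median"),
                                   band = 15L,
                                   normalize = c("none", "center", "zscore")) {
  aggregate <- match.arg(aggregate)
  normalize <- match.arg(normalize)
  if (!isTRUE(ae$trained)) stop("autoencoder has not been trained on the benchmark")
  n <- dim(dataset$X)[1]
  probe_size <- min(probe_size, n)
  # sample on sorted record ids so the probe is invariant to record order
  ord <- order(dataset$record_ids)
  probe <- with_seed(seed, sort(ord[sample(n, probe_size)]))
  C <- dim(dataset$X)[3]
  scores <- vapply(probe, function(i) {
    m <- dataset$X[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = C)
    if (normalize == "center") m <- sweep(m, 2, colMeans(m), "-")
    if (normalize == "zscore") m <- zscore_record(m)$x
    rec <- vapply(seq_len(C), function(j)
      as.vector(ae_reconstruct(ae, m[, j])), numeric(nrow(m)))
    dtw_distance(m, matrix(rec, ncol = C), band = band)
  }, numeric(1))
  if (aggregate == "median") stats::median(scores) else mean(scores)
}

#' Weight-similarity assessment against the reference model
#'
#' Spearman rank-order correlation between the flattened shared sections
#' of a client model and the central reference model. The shared section
#' is what propagates around an orbit, so it is the natural comparison
#' set; the full parameter vector can be compared instead via `section`.
#'
#' @param client_model,reference_model `split_model`s with identical
#'   architecture and flatten order
#' @param section `"shared"` (default) or `"all"`
#' @return scalar rho in `[-1, 1]`
#' @export
assess_weight_similarity <- function(client_model, reference_model,
                                     section = c("shared", "all")) {
  section <- match.arg(section)
  if (!identical(client_model$flatten_order, reference_model$flatten_order) ||
      !identical(client_model$section_map, reference_model$section_map))
    stop("architecture mismatch between client and reference models")
  spearman_rho(flatten_params(client_model, section),
               flatten_params(reference_model, section))$rho
}
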