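# Bagging-ensemble inference within an orbit, rank-based AUROC and the
# per-client evaluation report.

#' Bagging-ensemble prediction with a set of shared-layer packets
#'
#' For each packet, runs the client's private front section, the packet's
#' shared section and the client's private back section, obtaining one
#' probability vector per packet; soft voting (the unweighted mean of the
#' probability vectors, renormalised against rounding) gives the ensemble
#' prediction. With identical packets this is exactly the single-model
#' output, and the result is invariant to packet order.
#'
#' @param model the client's `split_model` (supplies the private sections)
#' @param packets list of shared-layer packets (each with a `tensors` field)
#' @param X input array `(n, len, channels)` or matrix
#' @return matrix `n x n_classes` of ensemble class probabilities
#' @export
ensemble_predict <- function(model, packets, X) {
  if (length(packets) == 0) stop("at least one shared-layer packet required")
  acc <- NULL
  for (pkt in packets) {
    m <- inject_shared(model, pkt$tensors)
    p <- predict_proba(m, X)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / length(packets)
  acc / rowSums(acc)
}

#' Rank-based (Mann-Whitney) AUROC
#'
#' Area under the ROC curve computed from score ranks with average ranks on
#' ties; equal to the probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores numeric prediction scores
#' @param labels binary labels (0/1 or logical)
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Per-class one-vs-rest AUROC plus pooled micro-average for one client's
# test split. Classes absent from the split are reported NA and excluded
# from the micro pooling.
client_auroc_report <- function(probs, labels, n_classes = 5L) {
  per_class <- rep(NA_real_, n_classes)
  pool_scores <- numeric(0); pool_labels <- integer(0)
  for (c in seq_len(n_classes) - 1L) {
    bin <- as.integer(labels == c)
    if (sum(bin) == 0) next                      # class absent: undefined
    if (sum(bin) < length(bin))
      per_class[c + 1L] <- auroc(probs[, c + 1L], bin)
    pool_scores <- c(pool_scores, probs[, c + 1L])
    pool_labels <- c(pool_labels, bin)
  }
  micro <- if (length(unique(pool_labels)) == 2) {
    auroc(pool_scores, pool_labels)
  } else NA_real_
  list(per_class = per_class, micro = micro)
}

#' Evaluate every client of a completed run
#'
#' Scores each client's own held-out test split: in `"orbital"` mode with
#' the bagging ensemble over all shared-layer packets currently held in
#' the client's orbit, in `"baseline"` mode with a single global model.
#' Reports per-class one-vs-rest AUROC for the five classes plus the
#' micro-average over pooled binarised labels. A class absent from a
#' client's test split is reported as `NA` and excluded from that client's
#' micro pooling.
#'
#' @param network a completed `ol_network` (orbital mode) or a list with
#'   fields `clients` and `global_model` (baseline mode, as returned by
#'   [run_fedavg()])
#' @param mode `"orbital"` or `"baseline"`
#' @return object of class `evaluation_report`: list with `per_client`
#'   (one entry per client: `per_class_auroc`, `micro_auroc`,
#'   `orbit_index` where applicable), `mode` and `melioration_index`
#' @export
evaluate_network <- function(network, mode = c("orbital", "baseline")) {
  mode <- match.arg(mode)
  per_client <- list()
  if (mode == "orbital") {
    for (key in names(network$clients)) {
      cl <- network$clients[[key]]
      o <- orbit_of(network, cl$id)
      ring <- network$orbit_config$orbits[[o]]
      packets <- lapply(as.character(ring),
                        function(k) network$clients[[k]]$packet)
      Xte <- cl$dataset$X[cl$dataset$test_idx, , , drop = FALSE]
      yte <- cl$dataset$labels[cl$dataset$test_idx]
      probs <- ensemble_predict(cl$model, packets, Xte)
      rep_c <- client_auroc_report(probs, yte)
      per_client[[key]] <- list(client_id = cl$id,
                                per_class_auroc = rep_c$per_class,
                                micro_auroc = rep_c$micro,
                                orbit_index = o)
    }
    m_idx <- max(vapply(network$clients, function(cl) cl$meliorations,
                        integer(1)))
  } else {
    for (d in network$clients) {
      Xte <- d$X[d$test_idx, , , drop = FALSE]
      yte <- d$labels[d$test_idx]
      probs <- predict_proba(network$global_model, Xte)
      rep_c <- client_auroc_report(probs, yte)
      per_client[[as.character(d$client_id)]] <-
        list(client_id = d$client_id, per_class_auroc = rep_c$per_class,
             micro_auroc = rep_c$micro, orbit_index = NA_integer_)
    }
    m_idx <- network$rounds
  }
  structure(list(per_client = per_client, mode = mode,
                 melioration_index = m_idx),
            class = "evaluation_report")
}

#' Flatten an evaluation report to a data frame
#'
#' @param report an `evaluation_report`
#' @return data.frame with one row per client
#' @export
report_as_df <- function(report) {
  do.call(rbind, lapply(report$per_client, function(pc) {
    row <- data.frame(client_id = pc$client_id, mode = report$mode,
                      micro_auroc = pc$micro_auroc,
                      orbit_index = pc$orbit_index)
    for (c in seq_along(pc$per_class_auroc))
      row[[paste0("auroc_class", c - 1L)]] <- pc$per_class_auroc[c]
    row
  }))
}
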