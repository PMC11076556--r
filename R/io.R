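# Plain-text persistence: per-client signal matrices as CSV plus a single
# manifest, and YAML/JSON scenario configuration files.

#' Write client datasets to a directory
#'
#' One CSV per client and channel (records x samples) plus a manifest CSV
#' (`record_id, client_id, label, age, tamper_tag, split`).
#'
#' @param clients list of `client_dataset`s
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
write_client_data <- function(clients, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  for (d in clients) {
    C <- dim(d$X)[3]
    for (ch in seq_len(C)) {
      M <- d$X[, , ch]
      if (is.null(dim(M))) M <- matrix(M, nrow = dim(d$X)[1])
      utils::write.csv(M, file.path(dir, sprintf("signals_client%d_ch%d.csv",
                                                 d$client_id, ch)),
                       row.names = FALSE)
    }
    split <- rep("train", length(d$labels))
    split[d$test_idx] <- "test"
    manifest <- rbind(manifest, data.frame(
      record_id = d$record_ids, client_id = d$client_id, label = d$labels,
      age = d$ages, tamper_tag = d$tamper_tag, split = split))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read client datasets back from a directory written by [write_client_data()]
#'
#' @param dir directory containing `manifest.csv` and the signal CSVs
#' @return list of `client_dataset`s
#' @export
read_client_data <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(sort(unique(manifest$client_id)), function(cid) {
    mf <- manifest[manifest$client_id == cid, ]
    files <- list.files(dir, sprintf("^signals_client%d_ch[0-9]+\\.csv$", cid))
    C <- length(files)
    mats <- lapply(seq_len(C), function(ch)
      as.matrix(utils::read.csv(file.path(
        dir, sprintf("signals_client%d_ch%d.csv", cid, ch)))))
    X <- array(0, c(nrow(mf), ncol(mats[[1]]), C))
    for (ch in seq_len(C)) X[, , ch] <- mats[[ch]]
    structure(list(client_id = cid, X = X, labels = as.integer(mf$label),
                   ages = mf$age, record_ids = mf$record_id,
                   train_idx = which(mf$split == "train"),
                   test_idx = which(mf$split == "test"),
                   tamper_tag = mf$tamper_tag[1]),
              class = "client_dataset")
  })
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' Keys missing from the file keep the [scenario_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return a `scenario_config`
#' @export
read_scenario_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$age_bins) && !is.list(vals$age_bins))
    vals$age_bins <- apply(vals$age_bins, 1, identity, simplify = FALSE)
  allowed <- names(formals(scenario_config))
  vals <- vals[intersect(names(vals), allowed)]
  do.call(scenario_config, vals)
}

#' Print every scenario default
#'
#' @return the default `scenario_config`, invisibly
#' @export
show_defaults <- function() {
  cfg <- scenario_config()
  flat <- lapply(unclass(cfg), function(v)
    if (is.list(v)) paste(vapply(v, function(b) paste(b, collapse = "-"),
                                 character(1)), collapse = ", ")
    else paste(v, collapse = ", "))
  for (nm in names(flat)) cat(sprintf("%-20s %s\n", nm, flat[[nm]]))
  invisible(cfg)
}
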