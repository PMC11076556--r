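# Weighted federated-averaging baseline on identical client data, the
# experiment runner and the on-disk log formats.

#' One round of weighted federated averaging
#'
#' Parameter-wise average of the client models, weighted by client
#' training-set size and normalised by the total. The aggregate of
#' identical models is that model; each aggregated tensor lies in the
#' convex hull of the client tensors elementwise.
#'
#' @param client_models list of `split_model`s with identical architecture
#' @param client_sizes positive numeric vector of training-set sizes
#' @return named list of aggregated parameter tensors
#' @export
fedavg_round <- function(client_models, client_sizes) {
  if (length(client_models) != length(client_sizes))
    stop("one size per client model required")
  if (any(client_sizes <= 0)) stop("client sizes must be positive")
  ref_names <- names(client_models[[1]]$params)
  for (m in client_models[-1]) {
    if (!identical(names(m$params), ref_names))
      stop("architecture mismatch across client models")
  }
  w <- client_sizes / sum(client_sizes)
  agg <- lapply(ref_names, function(nm) {
    out <- client_models[[1]]$params[[nm]] * w[1]
    for (i in seq_along(client_models)[-1]) {
      p <- client_models[[i]]$params[[nm]]
      if (!identical(dim(p), dim(out)) || length(p) != length(out))
        stop("shape mismatch for tensor ", nm)
      out <- out + p * w[i]
    }
    out
  })
  names(agg) <- ref_names
  agg
}

#' Run the weighted-FedAvg baseline on a set of client datasets
#'
#' The comparator arm: the same clients, data, architecture and optimiser
#' settings as the orbital run, but orchestrated by classical federated
#' averaging — each round every client trains the full model locally and a
#' central server replaces it with the size-weighted parameter mean. There
#' is no assessment, grouping or isolation mechanism.
#'
#' @param clients list of `client_dataset`s (bit-identical to the orbital
#'   arm's input for paired comparisons)
#' @param seed master seed
#' @param recipe a [training_recipe()] (per-round local epochs)
#' @param rounds aggregation rounds (default 15)
#' @param arch classifier architecture
#' @return list of class `fedavg_run` with `global_model`, `clients`,
#'   `rounds` and a per-round `log` data frame
#' @export
run_fedavg <- function(clients, seed = 1L, recipe = training_recipe(),
                       rounds = 15L, arch = "desk") {
  input_len <- dim(clients[[1]]$X)[2]
  n_ch <- dim(clients[[1]]$X)[3]
  global <- build_classifier(input_len, n_ch, 5L,
                             seed = derive_seed(seed, "fedavg_init"),
                             arch = arch)
  sizes <- vapply(clients, function(d) length(d$train_idx), numeric(1))
  log <- NULL
  for (r in seq_len(rounds)) {
    locals <- vector("list", length(clients))
    for (i in seq_along(clients)) {
      m <- global
      m$opt <- list(); m$opt_t <- 0L
      tl <- train_local(m, clients[[i]], recipe,
                        derive_seed(seed, "fedavg", r, clients[[i]]$client_id))
      locals[[i]] <- tl$model
      log <- rbind(log, data.frame(round = r,
                                   client_id = clients[[i]]$client_id,
                                   loss = tl$last_loss))
    }
    global$params <- fedavg_round(locals, sizes)
  }
  structure(list(global_model = global, clients = clients,
                 rounds = rounds, log = log), class = "fedavg_run")
}

#' Experiment configuration
#'
#' Bundles a scenario with the protocol parameters of both arms. Defaults
#' follow the reference schedule: 15 meliorations per client of which the
#' first 5 are initiation, orbit-acceptance threshold 0.015, Adam with
#' learning rate 0.001 on both arms, and a stratified 80/20 split carried
#' by the scenario itself.
#'
#' @param scenario a [scenario_config()]
#' @param protocol `"orbital"`, `"fedavg"` or `"both"`
#' @param rounds total meliorations / aggregation rounds (default 15)
#' @param init_rounds initiation meliorations (default 5; must be < rounds)
#' @param threshold orbit-acceptance half-width (default 0.015)
#' @param local_epochs local epochs per melioration/round
#' @param kmax maximum orbit count at initiation
#' @param seeds integer vector of run seeds
#' @param out_dir output directory (`NULL` = no files written)
#' @param arch classifier architecture
#' @return object of class `experiment_config`
#' @export
experiment_config <- function(scenario = scenario_config(),
                              protocol = c("both", "orbital", "fedavg"),
                              rounds = 15L, init_rounds = 5L,
                              threshold = 0.015, local_epochs = 4L,
                              kmax = 5L, seeds = 1L, out_dir = NULL,
                              arch = "desk") {
  protocol <- match.arg(protocol)
  if (init_rounds >= rounds) stop("init_rounds must be smaller than rounds")
  if (threshold <= 0) stop("threshold must be positive")
  if (length(seeds) < 1) stop("at least one seed required")
  structure(list(scenario = scenario, protocol = protocol,
                 rounds = as.integer(rounds),
                 init_rounds = as.integer(init_rounds),
                 threshold = threshold, local_epochs = as.integer(local_epochs),
                 kmax = as.integer(kmax), seeds = as.integer(seeds),
                 out_dir = out_dir, arch = arch),
            class = "experiment_config")
}

#' Run a configured experiment over its seeds
#'
#' For every seed: generates the scenario, runs the orbital protocol and/or
#' the FedAvg baseline on the identical client datasets, evaluates every
#' client, and (if an output directory is configured) writes the
#' evaluation reports (CSV + JSON), the orbit-membership history (CSV) and
#' the event log (JSON lines).
#'
#' @param config an [experiment_config()]
#' @return named list (one entry per seed) with `orbital`
#'   (`evaluation_report` + network) and/or `fedavg`
#' @export
run_experiment <- function(config) {
  out <- list()
  for (s in config$seeds) {
    sc <- config$scenario
    sc$seed <- as.integer(s)
    data <- generate_scenario(sc)
    recipe <- training_recipe(local_epochs = config$local_epochs)
    res <- list()
    if (config$protocol %in% c("both", "orbital")) {
      net <- build_network(data$clients, data$benchmark, seed = s,
                           recipe = recipe, threshold = config$threshold,
                           kmax = config$kmax, n_init = config$init_rounds,
                           arch = config$arch)
      net <- run_protocol(net, config$rounds)
      res$orbital <- list(report = evaluate_network(net, "orbital"),
                          network = net)
    }
    if (config$protocol %in% c("both", "fedavg")) {
      fa <- run_fedavg(data$clients, seed = s, recipe = recipe,
                       rounds = config$rounds, arch = config$arch)
      res$fedavg <- list(report = evaluate_network(fa, "baseline"),
                         run = fa)
    }
    if (!is.null(config$out_dir))
      write_run_outputs(res, config, s)
    out[[as.character(s)]] <- res
  }
  invisible(out)
}

write_run_outputs <- function(res, config, seed) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste0(config$scenario$scenario, "_seed", seed)
  if (!is.null(res$orbital)) {
    df <- report_as_df(res$orbital$report)
    utils::write.csv(df, file.path(config$out_dir,
                                   paste0("report_orbital_", tag, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(res$orbital$report,
                         file.path(config$out_dir,
                                   paste0("report_orbital_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_event_log(res$orbital$network,
                    file.path(config$out_dir,
                              paste0("events_", tag, ".jsonl")))
    utils::write.csv(res$orbital$network$orbit_history,
                     file.path(config$out_dir,
                               paste0("orbit_history_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(res$orbital$network$assess_log,
                     file.path(config$out_dir,
                               paste0("assessments_", tag, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$fedavg)) {
    df <- report_as_df(res$fedavg$report)
    utils::write.csv(df, file.path(config$out_dir,
                                   paste0("report_fedavg_", tag, ".csv")),
                     row.names = FALSE)
  }
  invisible(NULL)
}

#' Write a network's event log as JSON lines
#'
#' One JSON object per line: `timestamp_sim`, `event_type` (melioration,
#' rotation, regroup, isolate, rejoin, ...) and the event payload.
#'
#' @param network an `ol_network`
#' @param path output file path
#' @export
write_event_log <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ev in network$events)
    writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Extract regroup/isolation events from a completed network
#'
#' @param network an `ol_network`
#' @return data.frame with one row per regroup or isolation event (zero
#'   rows if none occurred)
#' @export
regroup_events <- function(network) {
  rows <- lapply(network$events, function(ev) {
    if (!ev$event_type %in% c("regroup", "isolate")) return(NULL)
    data.frame(timestamp_sim = ev$timestamp_sim,
               event_type = ev$event_type,
               client_id = ev$payload$client_id,
               from_orbit = ev$payload$from_orbit,
               to_orbit = as.character(ev$payload$to_orbit),
               trigger = ev$payload$trigger)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0)
    return(data.frame(timestamp_sim = numeric(0), event_type = character(0),
                      client_id = integer(0), from_orbit = integer(0),
                      to_orbit = character(0), trigger = numeric(0)))
  do.call(rbind, rows)
}
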