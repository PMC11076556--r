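# Memoised protocol runs shared by the acceptance tests: the tamper-
# scenario studies are expensive (full orbital + federated runs over 10
# seeds), so they are computed once per test session and reused by the
# isolation and superiority checks.

.run_cache <- new.env(parent = emptyenv())

acceptance_seeds <- function() 1:10

# TRUE if no orbit mixes tampered and clean clients.
orbits_pure <- function(net, tampered) {
  all(vapply(net$orbit_config$orbits, function(r)
    !(any(r %in% tampered) && any(!(r %in% tampered))), logical(1)))
}

clean_mean_auroc <- function(report, clean_ids) {
  mean(vapply(report$per_client[as.character(clean_ids)],
              function(pc) pc$micro_auroc, numeric(1)), na.rm = TRUE)
}

# One seed of the scaled-down tamper replica: 6 clients x 300 samples,
# 8 meliorations (5 initiation), tampered clients 2 and 4, plus the paired
# weighted-FedAvg arm on bit-identical client data.
run_tamper_seed <- function(scenario, seed) {
  cfg <- scenario_config(scenario = scenario, seed = seed)
  sc <- generate_scenario(cfg)
  net <- build_network(sc$clients, sc$benchmark, seed = seed, ae_epochs = 40L)
  net <- run_protocol(net, 8L)
  ol_report <- evaluate_network(net, "orbital")
  fa <- run_fedavg(sc$clients, seed = seed, rounds = 8L)
  fa_report <- evaluate_network(fa, "baseline")
  clean <- setdiff(seq_len(cfg$n_clients), cfg$tampered_client_ids)
  list(pure = orbits_pure(net, cfg$tampered_client_ids),
       orbits = net$orbit_config$orbits,
       regroups = regroup_events(net),
       ol_clean = clean_mean_auroc(ol_report, clean),
       fa_clean = clean_mean_auroc(fa_report, clean))
}

tamper_study <- function(scenario) {
  key <- paste0("study_", scenario)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- lapply(acceptance_seeds(), function(s)
      run_tamper_seed(scenario, s))
  }
  .run_cache[[key]]
}
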