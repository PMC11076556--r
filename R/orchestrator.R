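# The central node: network construction, initiation (reference training +
# K-means orbit formation), maintenance rounds (melioration, assessment,
# threshold-based regrouping/isolation, ring rotation) and inter-orbit
# access control. All temporal behaviour runs on a simulated clock.

#' Build a network state for the orbital protocol
#'
#' Assembles clients, the central benchmark, the training recipe and the
#' orchestration parameters into one mutable-by-return network object.
#'
#' @param clients list of `client_dataset`s (as from [generate_scenario()])
#' @param benchmark the central benchmark `client_dataset`
#' @param seed master seed for the run
#' @param recipe a [training_recipe()]
#' @param threshold orbit-acceptance half-width on the weight-similarity
#'   coefficient (default 0.015)
#' @param dd_factor multiplicative band on mean orbit data distance for
#'   orbit acceptance: a client joins an orbit only if its data-distance
#'   score is within this factor of the orbit's mean (default 2); together
#'   with `threshold` this requires both assessed characteristics to match
#' @param kmax maximum number of orbits considered at initiation
#' @param n_init meliorations during initiation, before any sharing
#'   (default 5)
#' @param arch classifier architecture, see [build_classifier()]
#' @param ref_epochs reference-model training epochs on the benchmark
#' @param ae_epochs autoencoder training epochs on the benchmark
#' @param probe_size records probed per data-similarity assessment
#' @param dtw_band Sakoe-Chiba half-width for assessment DTW
#' @param probe_normalize probe preprocessing for the data assessor, see
#'   [assess_data_similarity()]
#' @param duration_fn `function(client_id, melioration_index)` returning the
#'   simulated-duration multiplier of that melioration (default: always 1);
#'   use this to model slow clients
#' @param identical_client_seeds if TRUE all clients draw local-training
#'   batches from the same stream (used to construct exactly symmetric
#'   networks); default FALSE gives each client its own stream
#' @param rotation_direction `"clockwise"` or `"anticlockwise"`
#' @param rho_section parameter section compared by the weight assessor:
#'   `"all"` (default) or `"shared"`. The full vector includes the private
#'   head, which never circulates within an orbit and therefore keeps
#'   carrying client-specific signal after shared layers have homogenised
#'   around the ring; the assessment runs client-side, so no parameters
#'   leave the client either way
#' @return object of class `ol_network`
#' @export
build_network <- function(clients, benchmark, seed = 1L,
                          recipe = training_recipe(),
                          threshold = 0.015, dd_factor = 2, kmax = 5L,
                          n_init = 5L,
                          arch = "desk", ref_epochs = 5L, ae_epochs = 80L,
                          probe_size = 64L, dtw_band = 15L,
                          probe_normalize = "none",
                          duration_fn = NULL,
                          identical_client_seeds = FALSE,
                          rotation_direction = c("clockwise", "anticlockwise"),
                          rho_section = c("all", "shared")) {
  rotation_direction <- match.arg(rotation_direction)
  rho_section <- match.arg(rho_section)
  if (is.null(duration_fn)) duration_fn <- function(client_id, melioration_index) 1
  input_len <- dim(clients[[1]]$X)[2]
  n_ch <- dim(clients[[1]]$X)[3]
  cl_states <- lapply(clients, function(d) {
    list(id = d$client_id, dataset = d, model = NULL, packet = NULL,
         clock = 0, meliorations = 0L, last_trained = 0,
         weight_rho = NA_real_, data_distance = NA_real_,
         rate = NA_real_, flagged = FALSE)
  })
  names(cl_states) <- vapply(clients, function(d) as.character(d$client_id),
                             character(1))
  structure(list(
    clients = cl_states, benchmark = benchmark,
    reference_model = NULL, autoencoder = NULL,
    orbit_config = NULL,
    recipe = recipe, threshold = threshold, dd_factor = dd_factor,
    kmax = as.integer(kmax),
    n_init = as.integer(n_init), arch = arch,
    ref_epochs = as.integer(ref_epochs), ae_epochs = as.integer(ae_epochs),
    probe_size = as.integer(probe_size), dtw_band = as.integer(dtw_band),
    probe_normalize = probe_normalize,
    input_len = input_len, n_channels = n_ch,
    duration_fn = duration_fn,
    identical_client_seeds = identical_client_seeds,
    rotation_direction = rotation_direction,
    rho_section = rho_section,
    events = list(), assess_log = NULL, orbit_history = NULL,
    initiated = FALSE, seed = as.integer(seed)
  ), class = "ol_network")
}

log_event <- function(network, t_sim, type, payload = list()) {
  network$events[[length(network$events) + 1L]] <-
    list(timestamp_sim = t_sim, event_type = type, payload = payload)
  network
}

client_train_seed <- function(network, client_id, melioration_index) {
  tag <- if (network$identical_client_seeds) "shared" else client_id
  derive_seed(network$seed, "train", tag, melioration_index)
}

# One melioration of one client, on its currently held model; updates
# clock, counters and logs.
meliorate_client <- function(network, key) {
  cl <- network$clients[[key]]
  m_idx <- cl$meliorations + 1L
  mult <- network$duration_fn(cl$id, m_idx)
  tl <- train_local(cl$model, cl$dataset, network$recipe,
                    client_train_seed(network, cl$id, m_idx),
                    duration_multiplier = mult)
  cl$model <- tl$model
  cl$clock <- cl$clock + tl$duration
  cl$meliorations <- m_idx
  cl$last_trained <- cl$clock
  cl$flagged <- cl$flagged || tl$flagged
  network$clients[[key]] <- cl
  log_event(network, cl$clock, "melioration",
            list(client_id = cl$id, melioration_index = m_idx,
                 duration = tl$duration, loss = tl$last_loss,
                 flagged = tl$flagged))
}

append_assessment <- function(network, key) {
  cl <- network$clients[[key]]
  row <- data.frame(client_id = cl$id, melioration_index = cl$meliorations,
                    weight_rho = cl$weight_rho,
                    data_distance = cl$data_distance,
                    melioration_rate = cl$rate)
  network$assess_log <- rbind(network$assess_log, row)
  network
}

record_orbit_history <- function(network, melioration_index) {
  rows <- do.call(rbind, lapply(seq_along(network$orbit_config$orbits),
    function(o) {
      ring <- network$orbit_config$orbits[[o]]
      data.frame(melioration_index = melioration_index, client_id = ring,
                 orbit_index = o, ring_position = seq_along(ring))
    }))
  network$orbit_history <- rbind(network$orbit_history, rows)
  network
}

#' Group clients into orbits from assessment features
#'
#' Standardises the per-client feature triple (weight similarity, data
#' distance, melioration rate) to zero mean and unit variance, runs seeded
#' K-means for `k = 1..kmax` and picks `k` by maximum mean silhouette width
#' (ties to the smallest `k`; `k = 1` has silhouette `-Inf` unless fewer
#' than 3 clients). Degenerate features (all clients identical) give a
#' single orbit.
#'
#' @param features numeric matrix, one row per client (rownames = client
#'   ids), columns are the assessment features
#' @param kmax maximum cluster count considered
#' @param seed integer seed for the K-means restarts
#' @return list with `assignment` (integer cluster per client), `k`, and
#'   `silhouette` (the selected mean silhouette width, `-Inf` for `k = 1`)
#' @export
form_orbits <- function(features, kmax, seed = 1L) {
  n <- nrow(features)
  sds <- apply(features, 2, stats::sd)
  feats <- scale(features)
  feats[, sds == 0 | !is.finite(sds)] <- 0
  n_distinct <- nrow(unique(round(feats, 12)))
  if (n_distinct <= 1L)
    return(list(assignment = rep(1L, n), k = 1L, silhouette = -Inf))
  kmax_eff <- min(n - 1L, kmax, n_distinct)
  best <- list(k = 1L, sil = if (n < 3) Inf else -Inf,
               assignment = rep(1L, n))
  if (n >= 3) {
    d <- stats::dist(feats)
    for (k in 2:kmax_eff) {
      cl <- with_seed(derive_seed(seed, "kmeans", k),
                      stats::kmeans(feats, centers = k, nstart = 10,
                                    iter.max = 50))
      sil <- mean(cluster::silhouette(cl$cluster, d)[, 3])
      if (sil > best$sil + 1e-12) {
        best <- list(k = k, sil = sil, assignment = as.integer(cl$cluster))
      }
    }
  }
  list(assignment = best$assignment, k = best$k, silhouette = best$sil)
}

orbit_mean_rho <- function(network, ring) {
  mean(vapply(as.character(ring),
              function(k) network$clients[[k]]$weight_rho, numeric(1)))
}

# Order orbits innermost-first by decreasing mean weight similarity.
sort_orbits <- function(network) {
  orbits <- network$orbit_config$orbits
  if (length(orbits) > 1) {
    means <- vapply(orbits, function(r) orbit_mean_rho(network, r), numeric(1))
    network$orbit_config$orbits <- orbits[order(-means)]
  }
  network
}

make_packet <- function(tensors, origin_client, origin_orbit, melioration_index) {
  list(tensors = tensors, origin_client = origin_client,
       origin_orbit = origin_orbit, melioration_index = melioration_index)
}

#' Initiation: reference training, local meliorations, orbit formation
#'
#' Trains the reference model and the assessor autoencoder on the central
#' benchmark, copies the reference model to every client, runs `n_init`
#' meliorations per client with no intelligence sharing, assesses every
#' client (weight similarity, data distance, melioration rate), and groups
#' clients into orbits with [form_orbits()]. Orbits are ordered by
#' decreasing mean weight similarity (innermost = most reference-like) and
#' each client's initial shared-layer packet is its own trained shared
#' section.
#'
#' @param network an `ol_network` from [build_network()]
#' @return the updated network (with `orbit_config` set)
#' @export
initiate <- function(network) {
  if (isTRUE(network$initiated)) return(network)
  ref <- build_classifier(network$input_len, network$n_channels, 5L,
                          seed = derive_seed(network$seed, "refinit"),
                          arch = network$arch)
  ref_recipe <- network$recipe
  ref_recipe$local_epochs <- network$ref_epochs
  ref <- train_local(ref, network$benchmark, ref_recipe,
                     derive_seed(network$seed, "reftrain"))$model
  network$reference_model <- ref
  ae <- build_autoencoder(network$input_len,
                          seed = derive_seed(network$seed, "aeinit"))
  bench_train <- network$benchmark$X[network$benchmark$train_idx, , ,
                                     drop = FALSE]
  network$autoencoder <- train_autoencoder(
    ae, bench_train, epochs = network$ae_epochs,
    seed = derive_seed(network$seed, "aetrain"))
  network <- log_event(network, 0, "reference_trained",
                       list(benchmark_size = dim(network$benchmark$X)[1]))

  for (key in names(network$clients)) {
    cl <- network$clients[[key]]
    cl$model <- ref
    cl$model$opt <- list(); cl$model$opt_t <- 0L
    network$clients[[key]] <- cl
  }
  for (m in seq_len(network$n_init)) {
    for (key in names(network$clients))
      network <- meliorate_client(network, key)
  }
  for (key in names(network$clients)) {
    cl <- network$clients[[key]]
    cl$weight_rho <- assess_weight_similarity(cl$model, network$reference_model,
                                              section = network$rho_section)
    cl$data_distance <- assess_data_similarity(
      cl$dataset, network$autoencoder, network$probe_size,
      seed = derive_seed(network$seed, "probe", cl$id),
      band = network$dtw_band, normalize = network$probe_normalize)
    cl$rate <- cl$meliorations / cl$clock
    network$clients[[key]] <- cl
    network <- append_assessment(network, key)
  }

  feats <- do.call(rbind, lapply(network$clients, function(cl)
    c(weight_rho = cl$weight_rho, data_distance = cl$data_distance,
      melioration_rate = cl$rate)))
  rownames(feats) <- names(network$clients)
  fo <- form_orbits(feats, network$kmax, derive_seed(network$seed, "orbits"))
  orbits <- lapply(sort(unique(fo$assignment)), function(g) {
    ids <- vapply(network$clients[fo$assignment == g],
                  function(cl) cl$id, integer(1))
    unname(sort(ids))
  })
  network$orbit_config <- list(orbits = orbits,
                               rotation_direction = network$rotation_direction,
                               threshold = network$threshold)
  network <- sort_orbits(network)
  for (key in names(network$clients)) {
    cl <- network$clients[[key]]
    cl$packet <- make_packet(extract_shared(cl$model), cl$id,
                             orbit_of(network, cl$id), cl$meliorations)
    network$clients[[key]] <- cl
  }
  t_now <- max(vapply(network$clients, function(cl) cl$clock, numeric(1)))
  network <- log_event(network, t_now, "initiation_complete",
                       list(k = fo$k, silhouette = fo$silhouette,
                            orbits = network$orbit_config$orbits))
  network$initiated <- TRUE
  record_orbit_history(network, network$n_init)
}

#' Orbit index of a client (1 = innermost)
#' @param network an `ol_network`
#' @param client_id client id
#' @return integer orbit index
#' @export
orbit_of <- function(network, client_id) {
  for (o in seq_along(network$orbit_config$orbits))
    if (client_id %in% network$orbit_config$orbits[[o]]) return(o)
  stop("client ", client_id, " is in no orbit")
}

#' Rotate shared-layer packets around an orbit ring
#'
#' Clockwise moves each client's packet to the next client in ring order
#' (a cyclic shift by +1); anticlockwise shifts by -1. A singleton ring is
#' the identity. The reassignment is a bijection on ring members, so
#' exactly one packet per client is conserved.
#'
#' @param ring ordered vector of client ids
#' @param packets list of packets, one per ring member, in ring order
#' @param direction `"clockwise"` or `"anticlockwise"`
#' @return list of packets in ring order after rotation (element `i` is the
#'   packet now held by `ring[i]`)
#' @export
rotate_shared_layers <- function(ring, packets,
                                 direction = c("clockwise", "anticlockwise")) {
  direction <- match.arg(direction)
  n <- length(ring)
  if (length(packets) != n) stop("packet/ring size mismatch")
  if (n == 1) return(packets)
  # clockwise: holder index i receives the packet of predecessor i-1
  shift <- if (direction == "clockwise") -1L else 1L
  idx <- ((seq_len(n) - 1L + shift) %% n) + 1L
  packets[idx]
}

orbit_mean_dd <- function(network, ring) {
  mean(vapply(as.character(ring),
              function(k) network$clients[[k]]$data_distance, numeric(1)))
}

# Which orbit (if any) accepts a client: the orbit with the nearest mean
# weight similarity within the acceptance threshold whose mean data
# distance is also compatible (within a multiplicative factor band), so a
# client cannot slip into an orbit of different data quality on weight
# similarity alone. Orbits listed in `exclude` are never candidates.
# Returns the orbit index or NA.
accepting_orbit <- function(network, rho, dd = NA_real_,
                            exclude = integer(0)) {
  orbits <- network$orbit_config$orbits
  cand <- setdiff(seq_along(orbits), exclude)
  if (length(cand) == 0) return(NA_integer_)
  means <- vapply(cand, function(o) orbit_mean_rho(network, orbits[[o]]),
                  numeric(1))
  dists <- abs(rho - means)
  ok <- dists <= network$threshold
  if (is.finite(dd) && dd > 0) {
    dd_means <- vapply(cand, function(o)
      orbit_mean_dd(network, orbits[[o]]), numeric(1))
    ok <- ok & is.finite(dd_means) &
      abs(log(pmax(dd, 1e-12) / pmax(dd_means, 1e-12))) <=
        log(network$dd_factor)
  }
  ok <- which(ok)
  if (length(ok) == 0) return(NA_integer_)
  cand[ok[which.min(dists[ok])]]
}

#' One maintenance round of the orbital protocol
#'
#' Per orbit, in ring order: every member meliorates on the shared-layer
#' packet it currently holds (plus its private sections), and is assessed
#' *before* its packet is shared onward. A member whose weight similarity
#' deviates from the mean of its orbit's other members by more than the
#' acceptance threshold is removed; it joins the orbit with the nearest
#' mean within the threshold, or becomes a singleton orbit (isolation).
#' Isolated singletons whose similarity re-enters the threshold of some
#' orbit are re-admitted at the start of a later round (appended at ring
#' end). Surviving rings then rotate once; each ring waits for all its own
#' members (per-orbit barrier on the simulated clock) but never for other
#' orbits. All events are logged.
#'
#' @param network an initiated `ol_network`
#' @return the updated network; the round's regroup/isolation events are in
#'   `network$events`
#' @export
maintenance_round <- function(network) {
  if (!isTRUE(network$initiated)) stop("initiation has not been run")

  # re-admission of isolated singletons that fit an orbit again
  orbits <- network$orbit_config$orbits
  if (length(orbits) > 1) {
    rejoined <- FALSE
    # decreasing index order so deletions do not shift the orbits still
    # to be visited; re-sorting happens once afterwards
    for (o in rev(seq_along(orbits))) {
      ring <- network$orbit_config$orbits[[o]]
      if (length(ring) != 1) next
      rho <- network$clients[[as.character(ring)]]$weight_rho
      dd <- network$clients[[as.character(ring)]]$data_distance
      dest <- accepting_orbit(network, rho, dd, exclude = o)
      if (!is.na(dest)) {
        network$orbit_config$orbits[[dest]] <-
          c(network$orbit_config$orbits[[dest]], ring)
        network$orbit_config$orbits[[o]] <- NULL
        network <- log_event(network,
                             network$clients[[as.character(ring)]]$clock,
                             "rejoin", list(client_id = ring, to_orbit = dest))
        rejoined <- TRUE
      }
    }
    if (rejoined) network <- sort_orbits(network)
  }

  # melioration + assessment, orbit by orbit
  for (o in seq_along(network$orbit_config$orbits)) {
    ring <- network$orbit_config$orbits[[o]]
    for (id in ring) {
      key <- as.character(id)
      cl <- network$clients[[key]]
      cl$model <- inject_shared(cl$model, cl$packet$tensors)
      network$clients[[key]] <- cl
      network <- meliorate_client(network, key)
      cl <- network$clients[[key]]
      cl$packet <- make_packet(extract_shared(cl$model), cl$id, o,
                               cl$meliorations)
      cl$weight_rho <- assess_weight_similarity(cl$model,
                                                network$reference_model,
                                                section = network$rho_section)
      cl$rate <- cl$meliorations / cl$clock
      network$clients[[key]] <- cl
      network <- append_assessment(network, key)
    }
  }

  # threshold-based removal (simultaneous across orbits)
  removals <- list()
  for (o in seq_along(network$orbit_config$orbits)) {
    ring <- network$orbit_config$orbits[[o]]
    if (length(ring) < 2) next
    rhos <- vapply(as.character(ring),
                   function(k) network$clients[[k]]$weight_rho, numeric(1))
    for (i in seq_along(ring)) {
      dev <- abs(rhos[i] - mean(rhos[-i]))
      if (dev > network$threshold)
        removals[[length(removals) + 1L]] <-
          list(client_id = ring[i], from_orbit = o, trigger = dev)
    }
  }
  if (length(removals) > 0) {
    for (rm in removals) {
      o <- orbit_of(network, rm$client_id)
      ring <- network$orbit_config$orbits[[o]]
      network$orbit_config$orbits[[o]] <- ring[ring != rm$client_id]
    }
    network$orbit_config$orbits <-
      Filter(function(r) length(r) > 0, network$orbit_config$orbits)
    for (rm in removals) {
      key <- as.character(rm$client_id)
      rho <- network$clients[[key]]$weight_rho
      dest <- accepting_orbit(network, rho, network$clients[[key]]$data_distance)
      t_now <- network$clients[[key]]$clock
      if (is.na(dest)) {
        network$orbit_config$orbits[[length(network$orbit_config$orbits) + 1L]] <-
          rm$client_id
        network <- log_event(network, t_now, "isolate",
                             list(client_id = rm$client_id,
                                  from_orbit = rm$from_orbit,
                                  to_orbit = "isolated",
                                  trigger = rm$trigger))
      } else {
        network$orbit_config$orbits[[dest]] <-
          c(network$orbit_config$orbits[[dest]], rm$client_id)
        network <- log_event(network, t_now, "regroup",
                             list(client_id = rm$client_id,
                                  from_orbit = rm$from_orbit,
                                  to_orbit = dest, trigger = rm$trigger))
      }
    }
    network <- sort_orbits(network)
  }

  # per-orbit barrier + ring rotation
  for (o in seq_along(network$orbit_config$orbits)) {
    ring <- network$orbit_config$orbits[[o]]
    keys <- as.character(ring)
    barrier <- max(vapply(keys, function(k) network$clients[[k]]$clock,
                          numeric(1)))
    for (k in keys) network$clients[[k]]$clock <- barrier
    packets <- lapply(keys, function(k) network$clients[[k]]$packet)
    packets <- rotate_shared_layers(ring, packets,
                                    network$orbit_config$rotation_direction)
    for (i in seq_along(keys))
      network$clients[[keys[i]]]$packet <- packets[[i]]
    network <- log_event(network, barrier, "rotation",
                         list(orbit_index = o, ring = ring,
                              direction = network$orbit_config$rotation_direction))
  }
  m_idx <- max(vapply(network$clients, function(cl) cl$meliorations, integer(1)))
  record_orbit_history(network, m_idx)
}

#' Pull the most recent shared-layer packet from the next-inner orbit
#'
#' Intelligence is accessible (not shared) across orbits: a client may
#' train on shared layers obtained from an inner orbit only, so biases of
#' outer orbits never flow inward. A request from the innermost orbit is
#' refused.
#'
#' @param network an initiated `ol_network`
#' @param client_id the requesting client
#' @return a packet (copy) whose provenance records the inner origin orbit
#' @export
pull_inner_orbit_layers <- function(network, client_id) {
  o <- orbit_of(network, client_id)
  if (o == 1)
    stop("access denied: the innermost orbit cannot pull from another orbit")
  inner <- network$orbit_config$orbits[[o - 1L]]
  keys <- as.character(inner)
  times <- vapply(keys, function(k) network$clients[[k]]$last_trained,
                  numeric(1))
  donor <- keys[which.max(times)]
  pkt <- network$clients[[donor]]$packet
  pkt$origin_orbit <- o - 1L
  pkt
}

#' Run the full orbital protocol
#'
#' Initiation ([initiate()]) followed by maintenance rounds
#' ([maintenance_round()]) until every client has completed
#' `total_meliorations` on the simulated clock.
#'
#' @param network an `ol_network`
#' @param total_meliorations total meliorations per client, including the
#'   initiation phase (default 15)
#' @return the completed network
#' @export
run_protocol <- function(network, total_meliorations = 15L) {
  if (total_meliorations <= network$n_init)
    stop("total_meliorations must exceed the initiation count")
  network <- initiate(network)
  while (min(vapply(network$clients, function(cl) cl$meliorations,
                    integer(1))) < total_meliorations)
    network <- maintenance_round(network)
  network
}
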