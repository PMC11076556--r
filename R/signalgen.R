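#' Diagnostic class labels of the synthetic waveform generator
#'
#' Five superclasses mirroring the standard clinical ECG taxonomy:
#' normal (NORM), ST/T change (STTC), conduction disturbance (CD),
#' hypertrophy (HYP) and myocardial infarction (MI), encoded 0..4.
#'
#' @return named integer vector mapping acronym to class id
#' @export
class_labels <- function() {
  c(NORM = 0L, STTC = 1L, CD = 2L, HYP = 3L, MI = 4L)
}

#' Morphology parameter table of the waveform generator
#'
#' One row per diagnostic class. Each synthetic beat is a sum of localized
#' Gaussian bumps (P, Q, R, S, T) plus a smooth ST-segment offset bump;
#' the columns below are multiplicative/additive modifiers applied to the
#' NORM baseline morphology:
#' \describe{
#'   \item{st_offset}{additive ST-segment level (amplitude units); negative =
#'     ST depression, as in ischaemic change}
#'   \item{t_amp_mult}{multiplier on T-bump amplitude (STTC flattens T)}
#'   \item{qrs_width_mult}{multiplier on Q/R/S bump widths (CD widens QRS)}
#'   \item{r_amp_mult}{multiplier on R amplitude (HYP increases voltage)}
#'   \item{q_polarity}{sign applied to the Q bump (MI inverts Q polarity)}
#'   \item{q_amp_mult}{multiplier on |Q| amplitude (MI exaggerates Q)}
#' }
#'
#' @return data.frame with one row per class id 0..4
#' @export
class_param_table <- function() {
  data.frame(
    label = 0:4,
    class = names(class_labels()),
    st_offset      = c(0,    -0.15, 0,   0,   -0.10),
    t_amp_mult     = c(1,     0.33, 1,   1,    1),
    qrs_width_mult = c(1,     1,    1.9, 1,    1),
    r_amp_mult     = c(1,     1,    1,   1.6,  1),
    q_polarity     = c(1,     1,    1,   1,   -1),
    q_amp_mult     = c(1,     1,    1,   1,    3),
    stringsAsFactors = FALSE
  )
}

# NORM baseline bump morphology: times in seconds relative to the R peak,
# widths are Gaussian sd in seconds, amplitudes in arbitrary units.
base_morphology <- function() {
  list(
    p = list(t = -0.16, w = 0.025, a = 0.15),
    q = list(t = -0.04, w = 0.010, a = -0.08),
    r = list(t = 0.00,  w = 0.012, a = 1.00),
    s = list(t = 0.03,  w = 0.012, a = -0.25),
    t = list(t = 0.30,  w = 0.060, a = 0.30),
    st = list(t = 0.15, w = 0.080)   # ST-offset bump centre/width
  )
}

#' Generate one synthetic class-conditioned waveform
#'
#' Produces a quasi-periodic beat train: per beat, the sum of localized
#' P/QRS/T Gaussian bumps plus an ST-segment offset bump, with the
#' class-conditioned modifiers of [class_param_table()], low-frequency
#' baseline wander and additive sensor noise. Heart rate and bump amplitudes
#' drift monotonically downwards with age. Multi-channel signals are derived
#' from the single base waveform through a fixed lead-mixing vector plus
#' small independent per-channel noise.
#'
#' @param label class id in 0..4 (see [class_labels()])
#' @param age age in years (must lie within `age_range`)
#' @param seed optional integer; if given the record is generated under its
#'   own RNG state and is a pure function of the arguments
#' @param sampling_rate samples per second (default 100)
#' @param duration record length in seconds (default 10)
#' @param channel_count number of channels (default 1)
#' @param age_range admissible age bounds in years
#' @return object of class `waveform`: list with `samples`
#'   (matrix, time x channel), `label`, `age`, `sampling_rate`, `duration`,
#'   `channel_count`
#' @export
generate_waveform <- function(label, age, seed = NULL,
                              sampling_rate = 100, duration = 10,
                              channel_count = 1L,
                              age_range = c(18, 89)) {
  if (!is.numeric(label) || length(label) != 1 || !(label %in% 0:4))
    stop("unknown label: must be a single class id in 0..4")
  if (!is.finite(age) || age < age_range[1] || age > age_range[2])
    stop("age out of configured range [", age_range[1], ", ", age_range[2], "]")
  if (!is.finite(sampling_rate) || !is.finite(duration) ||
      sampling_rate <= 0 || duration <= 0)
    stop("non-finite or non-positive sampling parameters")
  if (!is.null(seed))
    return(with_seed(seed, generate_waveform(label, age, NULL, sampling_rate,
                                             duration, channel_count, age_range)))

  n <- round(sampling_rate * duration)
  tt <- (seq_len(n) - 1) / sampling_rate
  morph <- base_morphology()
  mods <- class_param_table()[label + 1L, ]

  # age-conditioned drift: both heart rate and voltage decline with age
  hr <- 80 - 0.25 * (age - 18)                   # beats per minute
  amp_scale <- 1.05 - 0.003 * (age - 18)
  period <- 60 / hr

  # beat centres with mild interval jitter
  n_beats <- ceiling(duration / period) + 2L
  intervals <- period * stats::rnorm(n_beats, 1, 0.03)
  centres <- cumsum(c(period * stats::runif(1, 0.2, 0.8), intervals[-1]))
  centres <- centres[centres < duration + 0.5]

  bump <- function(sig, centre, width, amp) {
    lo <- max(1L, floor((centre - 4 * width) * sampling_rate) + 1L)
    hi <- min(n, ceiling((centre + 4 * width) * sampling_rate) + 1L)
    if (lo > hi) return(sig)
    idx <- lo:hi
    sig[idx] <- sig[idx] + amp * exp(-((tt[idx] - centre)^2) / (2 * width^2))
    sig
  }

  sig <- numeric(n)
  qw <- morph$q$w * mods$qrs_width_mult
  rw <- morph$r$w * mods$qrs_width_mult
  sw <- morph$s$w * mods$qrs_width_mult
  for (ct in centres) {
    jit <- stats::rnorm(5, 1, 0.05)   # per-beat amplitude jitter: P,Q,R,S,T
    sig <- bump(sig, ct + morph$p$t, morph$p$w,
                amp_scale * morph$p$a * jit[1])
    sig <- bump(sig, ct + morph$q$t, qw,
                amp_scale * morph$q$a * mods$q_polarity * mods$q_amp_mult * jit[2])
    sig <- bump(sig, ct + morph$r$t, rw,
                amp_scale * morph$r$a * mods$r_amp_mult * jit[3])
    sig <- bump(sig, ct + morph$s$t, sw,
                amp_scale * morph$s$a * jit[4])
    sig <- bump(sig, ct + morph$t$t, morph$t$w,
                amp_scale * morph$t$a * mods$t_amp_mult * jit[5])
    if (mods$st_offset != 0)
      sig <- bump(sig, ct + morph$st$t, morph$st$w, amp_scale * mods$st_offset)
  }

  # baseline wander + sensor noise
  f_bw <- stats::runif(1, 0.15, 0.4)
  sig <- sig + stats::runif(1, 0.03, 0.10) *
    sin(2 * pi * f_bw * tt + stats::runif(1, 0, 2 * pi))
  sig <- sig + stats::rnorm(n, 0, 0.03)

  if (channel_count > 1L) {
    mix <- lead_mixing(channel_count)
    samples <- vapply(seq_len(channel_count), function(j) {
      mix[j] * sig + stats::rnorm(n, 0, 0.02)
    }, numeric(n))
  } else {
    samples <- matrix(sig, ncol = 1)
  }

  structure(list(samples = samples, label = as.integer(label), age = age,
                 sampling_rate = sampling_rate, duration = duration,
                 channel_count = as.integer(channel_count)),
            class = "waveform")
}

# Fixed lead-mixing vector used to derive additional channels from the
# single base waveform (deterministic, not part of any RNG stream).
lead_mixing <- function(channel_count) {
  1 - 0.4 * (seq_len(channel_count) - 1) / max(1L, channel_count - 1L)
}

#' Scenario configuration for the synthetic client network
#'
#' Bundles every knob of the data-generating process: network size, the
#' partitioning scenario, tampering parameters and waveform geometry.
#' Defaults follow the reference study conditions at desk scale: six
#' clients, uniform noise on `[0, 0.2]` added to z-scored signals of
#' clients 2 and 4 in the noise scenario, label shuffling of clients 2 and
#' 4 in the label scenario, and the six age decades 18-39, ..., 80-89 for
#' the age-partitioned scenario.
#'
#' @param n_clients number of clients (default 6)
#' @param samples_per_client records per client (default 300; desk scale)
#' @param scenario one of `"randomised_noniid"`, `"age_partition"`,
#'   `"noise_tamper"`, `"label_tamper"`
#' @param tampered_client_ids clients receiving the tampering operator
#' @param noise_low,noise_high uniform-noise amplitude bounds applied to
#'   z-scored signals
#' @param age_bins list of `c(low, high)` year ranges, one per client
#'   (used by `age_partition`)
#' @param noniid_alpha Dirichlet concentration for label-skewed partitioning
#'   (smaller = more skew)
#' @param benchmark_size records in the central benchmark dataset
#' @param sampling_rate,duration,channel_count waveform geometry
#' @param age_range admissible ages in years
#' @param train_frac training fraction of the stratified split
#' @param seed master seed of the scenario
#' @return object of class `scenario_config`
#' @export
scenario_config <- function(n_clients = 6L,
                            samples_per_client = 300L,
                            scenario = c("randomised_noniid", "age_partition",
                                         "noise_tamper", "label_tamper"),
                            tampered_client_ids = integer(0),
                            noise_low = 0, noise_high = 0.2,
                            age_bins = list(c(18, 39), c(40, 49), c(50, 59),
                                            c(60, 69), c(70, 79), c(80, 89)),
                            noniid_alpha = 0.5,
                            benchmark_size = 500L,
                            sampling_rate = 100, duration = 10,
                            channel_count = 1L,
                            age_range = c(18, 89),
                            train_frac = 0.8,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (noise_low > noise_high || noise_low < 0)
    stop("noise bounds must satisfy 0 <= noise_low <= noise_high")
  if (scenario %in% c("noise_tamper", "label_tamper") &&
      length(tampered_client_ids) == 0)
    tampered_client_ids <- c(2L, 4L)
  if (length(tampered_client_ids) &&
      any(tampered_client_ids < 1 | tampered_client_ids > n_clients))
    stop("tampered_client_ids must be a subset of 1..n_clients")
  if (scenario == "age_partition" && length(age_bins) != n_clients)
    stop("age_partition requires one age bin per client")
  structure(list(
    n_clients = as.integer(n_clients),
    samples_per_client = as.integer(samples_per_client),
    scenario = scenario,
    tampered_client_ids = as.integer(tampered_client_ids),
    noise_low = noise_low, noise_high = noise_high,
    age_bins = age_bins, noniid_alpha = noniid_alpha,
    benchmark_size = as.integer(benchmark_size),
    sampling_rate = sampling_rate, duration = duration,
    channel_count = as.integer(channel_count),
    age_range = age_range, train_frac = train_frac,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

# Generate a pool of waveforms as dense arrays.
# labels/ages may be supplied; otherwise labels are uniform over 0..4 and
# ages uniform over age_range. Returns list(X = n x len x ch array,
# labels, ages, record_ids).
generate_pool <- function(n, config, seed, labels = NULL, ages = NULL,
                          id_prefix = "P") {
  with_seed(seed, {
    if (is.null(labels)) labels <- sample(0:4, n, replace = TRUE)
    if (is.null(ages))
      ages <- stats::runif(n, config$age_range[1], config$age_range[2])
    len <- round(config$sampling_rate * config$duration)
    X <- array(0, dim = c(n, len, config$channel_count))
    for (i in seq_len(n)) {
      w <- generate_waveform(labels[i], ages[i],
                             sampling_rate = config$sampling_rate,
                             duration = config$duration,
                             channel_count = config$channel_count,
                             age_range = config$age_range)
      X[i, , ] <- w$samples
    }
    list(X = X, labels = as.integer(labels), ages = ages,
         record_ids = paste0(id_prefix, seq_len(n)))
  })
}

# Stratified train/test index split (by label), deterministic given seed.
stratified_split <- function(labels, train_frac, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, round(train_frac * length(idx)))
      if (n_tr >= length(idx) && length(idx) > 1L) n_tr <- length(idx) - 1L
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

new_client_dataset <- function(client_id, X, labels, ages, record_ids,
                               train_frac, seed, tamper_tag = "none") {
  sp <- stratified_split(labels, train_frac, derive_seed(seed, "split", client_id))
  structure(list(client_id = client_id, X = X, labels = labels, ages = ages,
                 record_ids = record_ids, train_idx = sp$train,
                 test_idx = sp$test, tamper_tag = tamper_tag),
            class = "client_dataset")
}

#' Partition a waveform pool into client datasets
#'
#' `randomised_noniid` (also used as the base partition of the tamper
#' scenarios): each client draws its label proportions from a
#' Dirichlet(`noniid_alpha`) distribution, producing label-skewed,
#' pairwise-distinct client distributions. `age_partition`: client `k`
#' receives only records whose age lies in `age_bins[[k]]`. Every client
#' dataset carries a stratified train/test split.
#'
#' @param pool list as returned by the internal pool generator
#'   (`X`, `labels`, `ages`, `record_ids`)
#' @param config a [scenario_config()]
#' @return list of `client_dataset` objects
#' @export
partition_clients <- function(pool, config) {
  n_need <- config$n_clients * config$samples_per_client
  if (length(pool$labels) < n_need)
    stop("pool too small: need ", n_need, " records, have ", length(pool$labels))
  seed <- derive_seed(config$seed, "partition")
  if (config$scenario == "age_partition") {
    assign_by_age(pool, config)
  } else {
    assign_dirichlet(pool, config, seed)
  }
}

assign_dirichlet <- function(pool, config, seed) {
  with_seed(seed, {
    n_cl <- config$n_clients
    spc <- config$samples_per_client
    avail <- lapply(0:4, function(cl) sample(which(pool$labels == cl)))
    names(avail) <- as.character(0:4)
    clients <- vector("list", n_cl)
    for (k in seq_len(n_cl)) {
      g <- stats::rgamma(5, shape = config$noniid_alpha)
      if (all(g == 0)) g <- rep(1, 5)
      props <- g / sum(g)
      target <- as.vector(stats::rmultinom(1, spc, props))
      take <- integer(0)
      for (cl in 0:4) {
        key <- as.character(cl)
        n_take <- min(target[cl + 1], length(avail[[key]]))
        if (n_take > 0) {
          take <- c(take, avail[[key]][seq_len(n_take)])
          avail[[key]] <- avail[[key]][-seq_len(n_take)]
        }
      }
      # top up from whatever classes remain if some class ran dry
      short <- spc - length(take)
      if (short > 0) {
        rest <- unlist(avail, use.names = FALSE)
        extra <- rest[seq_len(short)]
        take <- c(take, extra)
        for (cl in 0:4) {
          key <- as.character(cl)
          avail[[key]] <- setdiff(avail[[key]], extra)
        }
      }
      clients[[k]] <- take
    }
    lapply(seq_len(n_cl), function(k) {
      idx <- clients[[k]]
      new_client_dataset(k, pool$X[idx, , , drop = FALSE], pool$labels[idx],
                         pool$ages[idx], pool$record_ids[idx],
                         config$train_frac, config$seed)
    })
  })
}

assign_by_age <- function(pool, config) {
  lapply(seq_len(config$n_clients), function(k) {
    bin <- config$age_bins[[k]]
    idx <- which(pool$ages >= bin[1] & pool$ages <= bin[2])
    if (length(idx) == 0)
      stop("empty age bin [", bin[1], ", ", bin[2], "]")
    if (length(idx) > config$samples_per_client)
      idx <- with_seed(derive_seed(config$seed, "agebin", k),
                       sample(idx, config$samples_per_client))
    new_client_dataset(k, pool$X[idx, , , drop = FALSE], pool$labels[idx],
                       pool$ages[idx], pool$record_ids[idx],
                       config$train_frac, config$seed)
  })
}

# z-score a (time x channel) matrix per channel; zero-variance channels
# are returned unchanged and flagged.
zscore_record <- function(m) {
  sds <- apply(m, 2, stats::sd)
  bad <- !is.finite(sds) | sds == 0
  mus <- colMeans(m)
  out <- sweep(m, 2, mus, "-")
  ok <- !bad
  if (any(ok)) out[, ok] <- sweep(out[, ok, drop = FALSE], 2, sds[ok], "/")
  if (any(bad)) out[, bad] <- m[, bad, drop = FALSE]
  list(x = out, degenerate = any(bad))
}

#' Add bounded uniform noise to a client's z-scored signals
#'
#' Each record is z-score normalised per channel (mean 0, sd 1 over its own
#' samples) and i.i.d. uniform noise on `[low, high]` is then added
#' pointwise. Labels are untouched; the dataset's tamper tag becomes
#' `"noise"`. Records with a zero-variance channel cannot be z-scored and
#' are skipped with a warning.
#'
#' @param dataset a `client_dataset`
#' @param low,high noise amplitude bounds, `0 <= low <= high`
#' @param seed integer seed for the noise stream
#' @return the tampered `client_dataset`
#' @export
tamper_noise <- function(dataset, low, high, seed) {
  if (!(high >= low && low >= 0)) stop("need high >= low >= 0")
  with_seed(seed, {
    n <- dim(dataset$X)[1]
    skipped <- 0L
    for (i in seq_len(n)) {
      m <- dataset$X[i, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, ncol = dim(dataset$X)[3])
      z <- zscore_record(m)
      if (z$degenerate) { skipped <- skipped + 1L; next }
      noise <- matrix(stats::runif(length(z$x), low, high), nrow = nrow(z$x))
      dataset$X[i, , ] <- z$x + noise
    }
    if (skipped > 0)
      warning(skipped, " zero-variance record(s) skipped during noise tampering")
    dataset$tamper_tag <- "noise"
    dataset
  })
}

#' Shuffle a client's labels
#'
#' Replaces the label vector by a uniform random permutation of itself, so
#' the class-count multiset is preserved while the signal-label pairing is
#' destroyed. Signals are untouched; tamper tag becomes `"label_shuffle"`.
#'
#' @param dataset a `client_dataset`
#' @param seed integer seed for the permutation
#' @return the tampered `client_dataset`
#' @export
tamper_labels <- function(dataset, seed) {
  if (length(dataset$labels) == 0) stop("dataset is empty")
  with_seed(seed, {
    dataset$labels <- dataset$labels[sample(length(dataset$labels))]
    dataset$tamper_tag <- "label_shuffle"
    dataset
  })
}

#' Build the central benchmark dataset
#'
#' A class-balanced, untampered, full-age-range reference dataset held by
#' the central node, disjoint (by record id) from every client pool. It is
#' used to train the reference model and the assessor autoencoder.
#'
#' @param config a [scenario_config()]
#' @return a `client_dataset` with `client_id = 0` (the central node)
#' @export
make_benchmark <- function(config) {
  n <- config$benchmark_size
  per <- ceiling(n / 5)
  labels <- rep(0:4, each = per)[seq_len(per * 5)]
  pool <- generate_pool(length(labels), config,
                        derive_seed(config$seed, "benchmark"),
                        labels = labels, id_prefix = "B")
  new_client_dataset(0L, pool$X, pool$labels, pool$ages, pool$record_ids,
                     config$train_frac, derive_seed(config$seed, "benchsplit"))
}

#' Generate a complete scenario: client datasets plus benchmark
#'
#' Generates the waveform pool, partitions it into clients according to the
#' configured scenario, applies the scenario's tampering operator to the
#' configured clients, and builds the disjoint central benchmark dataset.
#' Both protocol arms (orbital and federated averaging) consume the
#' identical output of this function, making per-seed comparisons paired.
#'
#' @param config a [scenario_config()]
#' @return list with `clients` (list of `client_dataset`) and `benchmark`
#' @export
generate_scenario <- function(config) {
  if (config$scenario == "age_partition") {
    # generate exactly samples_per_client records per age bin
    labels <- NULL; ages <- NULL
    n_tot <- config$n_clients * config$samples_per_client
    ages <- with_seed(derive_seed(config$seed, "ages"), {
      unlist(lapply(config$age_bins, function(b)
        stats::runif(config$samples_per_client, b[1], b[2])))
    })
    pool <- generate_pool(n_tot, config, derive_seed(config$seed, "pool"),
                          ages = ages)
  } else {
    n_tot <- config$n_clients * config$samples_per_client
    pool <- generate_pool(n_tot, config, derive_seed(config$seed, "pool"))
  }
  clients <- partition_clients(pool, config)
  if (config$scenario == "noise_tamper") {
    for (k in config$tampered_client_ids)
      clients[[k]] <- tamper_noise(clients[[k]], config$noise_low,
                                   config$noise_high,
                                   derive_seed(config$seed, "noise", k))
  } else if (config$scenario == "label_tamper") {
    for (k in config$tampered_client_ids)
      clients[[k]] <- tamper_labels(clients[[k]],
                                    derive_seed(config$seed, "shuffle", k))
  }
  list(clients = clients, benchmark = make_benchmark(config))
}
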