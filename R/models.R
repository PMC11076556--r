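#' Build the split 1-D convolutional classifier
#'
#' A stack of strided 1-D convolution blocks followed by global average
#' pooling and a dense softmax head, partitioned into split-learning
#' sections: the first block is `private_front`, the middle blocks are
#' `shared` (the section exchanged between clients), and the dense head is
#' `private_back`. Only the shared section ever leaves a client.
#'
#' Two architectures are available: `"desk"` (default, three conv blocks;
#' sized so a full simulated network trains in seconds) and `"deep"`
#' (five conv blocks, closer to a full-scale clinical stack).
#'
#' @param input_len samples per channel
#' @param n_channels input channels
#' @param n_classes output classes (default 5)
#' @param seed integer seed for parameter initialisation; two models built
#'   with the same seed have bitwise-identical parameters
#' @param arch `"desk"` or `"deep"`
#' @return object of class `split_model`
#' @export
build_classifier <- function(input_len, n_channels = 1L, n_classes = 5L,
                             seed = 1L, arch = c("desk", "deep")) {
  arch <- match.arg(arch)
  blocks <- if (arch == "desk") {
    list(list(name = "conv1", k = 9L, stride = 4L, f = 8L),
         list(name = "conv2", k = 5L, stride = 4L, f = 12L),
         list(name = "conv3", k = 3L, stride = 2L, f = 16L))
  } else {
    list(list(name = "conv1", k = 9L, stride = 2L, f = 16L),
         list(name = "conv2", k = 7L, stride = 2L, f = 24L),
         list(name = "conv3", k = 5L, stride = 2L, f = 32L),
         list(name = "conv4", k = 5L, stride = 2L, f = 32L),
         list(name = "conv5", k = 3L, stride = 2L, f = 48L))
  }
  layers <- conv_stack_arch(input_len, n_channels, n_classes, blocks)
  params <- with_seed(seed, init_params(layers))
  conv_names <- vapply(blocks, function(b) b$name, character(1))
  shared_blocks <- conv_names[-1]          # all conv blocks except the first
  if (length(shared_blocks) == 0) stop("section config leaves shared section empty")
  section_map <- character(0)
  for (nm in names(params)) {
    blk <- sub("_[Wb]$", "", nm)
    section_map[nm] <- if (blk == conv_names[1]) "private_front"
                       else if (blk %in% shared_blocks) "shared"
                       else "private_back"
  }
  structure(list(
    layers = layers, params = params,
    section_map = section_map, flatten_order = names(params),
    input_len = as.integer(input_len), n_channels = as.integer(n_channels),
    n_classes = as.integer(n_classes), arch = arch,
    opt = list(), opt_t = 0L
  ), class = "split_model")
}

#' Class probabilities for a batch of records
#'
#' Inputs are z-score normalised per record and channel before the forward
#' pass. Output rows are non-negative and sum to one.
#'
#' @param model a `split_model`
#' @param X array `(n, len, channels)` (a matrix is treated as single-channel)
#' @param preprocess z-score inputs first (default TRUE)
#' @return matrix `n x n_classes` of class probabilities
#' @export
predict_proba <- function(model, X, preprocess = TRUE) {
  if (is.matrix(X)) X <- array(X, c(nrow(X), ncol(X), 1L))
  if (preprocess) X <- prep_inputs(X)
  net_forward(model, X)$probs
}

#' Training recipe (optimiser hyper-parameters) for local meliorations
#'
#' Adam with learning rate 0.001 throughout, matching the federated
#' baseline so the two arms differ only in orchestration. `local_epochs`
#' is the number of passes over the client's training split per
#' melioration; the desk-scale default is 4 (a full-scale run raises it
#' towards the order of 100 used clinically). `base_duration` is the
#' simulated wall time of one melioration; actual durations are
#' `base_duration` times the client's multiplier, so temporal
#' heterogeneity is controlled and hardware-independent.
#'
#' @param learning_rate Adam step size (default 0.001)
#' @param local_epochs epochs per melioration (default 4)
#' @param batch_size mini-batch size (default 16)
#' @param base_duration simulated duration of one melioration (default 1)
#' @return object of class `training_recipe`
#' @export
training_recipe <- function(learning_rate = 0.001, local_epochs = 4L,
                            batch_size = 16L, base_duration = 1) {
  stopifnot(learning_rate > 0, local_epochs >= 1, batch_size >= 1,
            base_duration > 0)
  structure(list(learning_rate = learning_rate,
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 base_duration = base_duration),
            class = "training_recipe")
}

#' Inverse-frequency class weights, normalised to mean one
#'
#' Classes absent from the training labels receive weight zero;
#' normalisation is over the present classes.
#'
#' @param labels integer class labels (0-based)
#' @param n_classes total number of classes
#' @return numeric vector of length `n_classes`
#' @export
class_weights <- function(labels, n_classes = 5L) {
  counts <- tabulate(labels + 1L, nbins = n_classes)
  w <- numeric(n_classes)
  present <- counts > 0
  w[present] <- 1 / counts[present]
  w[present] <- w[present] / mean(w[present])
  w
}

#' One local melioration: bounded local training of a client model
#'
#' Runs `recipe$local_epochs` of weighted cross-entropy minimisation on the
#' client's training split and returns the updated model together with the
#' melioration's simulated duration (`base_duration * duration_multiplier`).
#' Simulated durations, not wall time, drive all temporal behaviour of the
#' orchestrator, so runs are reproducible across machines.
#'
#' @param model a `split_model`
#' @param dataset a `client_dataset`
#' @param recipe a [training_recipe()]
#' @param seed integer seed for batch shuffling
#' @param duration_multiplier relative slowness of this melioration
#' @return list with `model`, `duration`, `first_loss`, `last_loss`,
#'   `flagged` (TRUE if training aborted on a non-finite loss)
#' @export
train_local <- function(model, dataset, recipe, seed, duration_multiplier = 1) {
  idx <- dataset$train_idx
  if (length(idx) == 0) stop("empty training split")
  X <- prep_inputs(dataset$X[idx, , , drop = FALSE])
  y <- dataset$labels[idx]
  cw <- class_weights(y, model$n_classes)
  res <- with_seed(seed, tryCatch(
    net_train_epochs(model, X, y, cw, recipe$local_epochs,
                     recipe$batch_size, recipe$learning_rate),
    error = function(e) e))
  if (inherits(res, "error")) {
    return(list(model = model, duration = recipe$base_duration * duration_multiplier,
                first_loss = NA_real_, last_loss = NA_real_, flagged = TRUE))
  }
  list(model = res$net,
       duration = recipe$base_duration * duration_multiplier,
       first_loss = res$first_loss, last_loss = res$last_loss,
       flagged = FALSE)
}

#' Flatten model parameters into one numeric vector
#'
#' Concatenates the tensors in the model's fixed `flatten_order`,
#' restricted to a section. The order is set at construction and identical
#' across all clients and the reference model, so flattened vectors are
#' directly comparable.
#'
#' @param model a `split_model`
#' @param section `"all"`, `"shared"`, `"private_front"` or `"private_back"`
#' @return numeric vector
#' @export
flatten_params <- function(model,
                           section = c("all", "shared", "private_front",
                                       "private_back")) {
  section <- match.arg(section)
  nms <- model$flatten_order
  if (section != "all") nms <- nms[model$section_map[nms] == section]
  unlist(lapply(nms, function(nm) as.vector(model$params[[nm]])),
         use.names = FALSE)
}

#' Extract the shared section of a split model
#'
#' @param model a `split_model`
#' @return named list of the shared tensors, in flatten order
#' @export
extract_shared <- function(model) {
  nms <- model$flatten_order[model$section_map[model$flatten_order] == "shared"]
  model$params[nms]
}

#' Inject shared tensors into a split model
#'
#' The inverse of [extract_shared()]: replaces the model's shared section.
#' Extraction followed by injection is the identity.
#'
#' @param model a `split_model`
#' @param tensors named list as returned by [extract_shared()]
#' @return the updated `split_model`
#' @export
inject_shared <- function(model, tensors) {
  expected <- model$flatten_order[model$section_map[model$flatten_order] == "shared"]
  if (!identical(sort(names(tensors)), sort(expected)))
    stop("shared-section tensor names do not match this architecture")
  for (nm in expected) {
    if (!identical(dim(model$params[[nm]]), dim(tensors[[nm]])) ||
        length(model$params[[nm]]) != length(tensors[[nm]]))
      stop("shared tensor shape mismatch for ", nm)
    model$params[[nm]] <- tensors[[nm]]
  }
  model
}

#' Build the benchmark autoencoder
#'
#' A dense encoder/decoder (input -> hidden ReLU -> linear bottleneck ->
#' hidden ReLU -> linear output) compressing each channel trace through a
#' bottleneck latent space. Trained on the central benchmark dataset only;
#' at assessment time a dissimilar client signal reconstructs poorly, and
#' the input-to-reconstruction dynamic-time-warping distance scores the
#' dissimilarity.
#'
#' @param input_len samples per channel
#' @param latent_dim bottleneck width (must be `< input_len`; default 32)
#' @param hidden_dim width of the hidden layers (default 128)
#' @param seed integer seed for initialisation
#' @return object of class `autoencoder`
#' @export
build_autoencoder <- function(input_len, latent_dim = 32L, hidden_dim = 128L,
                              seed = 1L) {
  if (latent_dim >= input_len)
    stop("latent dimension must be smaller than the input length (no bottleneck)")
  params <- with_seed(seed, list(
    enc1_W = init_mat(input_len, hidden_dim, input_len),
    enc1_b = numeric(hidden_dim),
    enc2_W = init_mat(hidden_dim, latent_dim, hidden_dim),
    enc2_b = numeric(latent_dim),
    dec1_W = init_mat(latent_dim, hidden_dim, latent_dim),
    dec1_b = numeric(hidden_dim),
    dec2_W = init_mat(hidden_dim, input_len, hidden_dim),
    dec2_b = numeric(input_len)
  ))
  structure(list(params = params, input_len = as.integer(input_len),
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim), trained = FALSE,
                 opt = list(), opt_t = 0L),
            class = "autoencoder")
}

ae_forward <- function(ae, X) {
  p <- ae$params
  H1 <- relu(sweep(X %*% p$enc1_W, 2, p$enc1_b, "+"))
  Z  <- sweep(H1 %*% p$enc2_W, 2, p$enc2_b, "+")
  H2 <- relu(sweep(Z %*% p$dec1_W, 2, p$dec1_b, "+"))
  R  <- sweep(H2 %*% p$dec2_W, 2, p$dec2_b, "+")
  list(H1 = H1, Z = Z, H2 = H2, R = R)
}

#' Reconstruct signals through the autoencoder
#'
#' @param ae an `autoencoder`
#' @param X matrix (records x samples), one z-scored channel trace per row
#' @return matrix of reconstructions, same shape as `X`
#' @export
ae_reconstruct <- function(ae, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  ae_forward(ae, X)$R
}

#' Train the autoencoder on benchmark signals
#'
#' Minimises mean squared reconstruction error with Adam. Each training
#' signal has its own mean subtracted (centering, no rescaling), so the
#' decoder learns zero-mean reconstructions; assessment probes are *not*
#' centred, which keeps scale and offset anomalies — exactly what the
#' assessor exists to flag — visible in the reconstruction distance, and
#' makes the distance respond monotonically to additive positive-mean
#' tamper noise.
#'
#' @param ae an `autoencoder`
#' @param X array `(n, len, channels)` or matrix of channel traces
#' @param epochs training epochs (default 80)
#' @param batch_size mini-batch size (default 32)
#' @param learning_rate Adam step size (default 0.001)
#' @param seed integer seed for shuffling
#' @param center subtract each signal's mean before training (default TRUE)
#' @return the trained `autoencoder`
#' @export
train_autoencoder <- function(ae, X, epochs = 80L, batch_size = 32L,
                              learning_rate = 0.001, seed = 1L,
                              center = TRUE) {
  M <- signals_as_rows(X)
  if (center) M <- M - rowMeans(M)
  with_seed(seed, {
    n <- nrow(M)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- M[idx, , drop = FALSE]
        fw <- ae_forward(ae, Xb)
        p <- ae$params
        dR <- 2 * (fw$R - Xb) / length(Xb)
        grads <- list(dec2_W = crossprod(fw$H2, dR), dec2_b = colSums(dR))
        dH2 <- (dR %*% t(p$dec2_W)) * (fw$H2 > 0)
        grads$dec1_W <- crossprod(fw$Z, dH2)
        grads$dec1_b <- colSums(dH2)
        dZ <- dH2 %*% t(p$dec1_W)
        grads$enc2_W <- crossprod(fw$H1, dZ)
        grads$enc2_b <- colSums(dZ)
        dH1 <- (dZ %*% t(p$enc2_W)) * (fw$H1 > 0)
        grads$enc1_W <- crossprod(Xb, dH1)
        grads$enc1_b <- colSums(dH1)
        ae$opt_t <- ae$opt_t + 1L
        t <- ae$opt_t
        for (nm in names(ae$params)) {
          g <- grads[[nm]]
          if (is.null(ae$opt[[nm]])) ae$opt[[nm]] <- list(m = g * 0, v = g * 0)
          st <- ae$opt[[nm]]
          st$m <- 0.9 * st$m + 0.1 * g
          st$v <- 0.999 * st$v + 0.001 * g * g
          ae$params[[nm]] <- ae$params[[nm]] -
            learning_rate * (st$m / (1 - 0.9^t)) /
            (sqrt(st$v / (1 - 0.999^t)) + 1e-8)
          ae$opt[[nm]] <- st
        }
      }
    }
  })
  ae$trained <- TRUE
  ae
}

# Flatten an (n, len, ch) array (or matrix) into rows of single-channel
# traces: each channel of each record becomes one row.
signals_as_rows <- function(X) {
  if (is.matrix(X)) return(X)
  n <- dim(X)[1]; C <- dim(X)[3]
  do.call(rbind, lapply(seq_len(C), function(c) {
    M <- X[, , c]
    if (is.null(dim(M))) M <- matrix(M, nrow = n)
    M
  }))
}
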