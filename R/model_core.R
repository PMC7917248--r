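# The three-tunnel network.
#
# Tunnel 1 (anchor): protein one-hot (max_len x 26) -> three 1-D convolution
# layers (ReLU) -> global max pooling -> projection into the shared space.
# Tunnels 2/3 (positive / negative drug): 1024-bit ECFP -> four-layer MLP
# (widths 1024, 256, 64, 256, ReLU) -> projection into the shared space; the
# two drug tunnels share one set of weights. A protein-anchored triplet loss
# acts on the shared-space embeddings; the regression head consumes the
# concatenated (anchor, positive-drug) embedding through three fully connected
# layers (dropout after the first two) and predicts pKd. Total objective:
# MSE + triplet_weight * mean triplet loss over positive-labeled records.

#' Model configuration
#'
#' Collects every architectural and optimization hyperparameter of the
#' three-tunnel network. Defaults are the reference configuration: MLP widths
#' 1024/256/64/256 over a 1024-bit fingerprint, three 32-filter convolution
#' layers over a 1000 x 26 protein encoding, a 256-dimensional shared metric
#' space, a 1024/1024/512 fully connected head with dropout 0.1 after the
#' first two layers, triplet margin 1, Adam with learning rate 1e-4, batch
#' size 256, 100 epochs.
#'
#' @param mlp_widths integer vector; `mlp_widths[1]` is the fingerprint length
#'   (the MLP input), the rest are layer widths.
#' @param cnn_filters integer vector of filters per convolution layer.
#' @param cnn_kernel_lengths integer vector of kernel lengths, one per layer.
#'   The default `c(4, 8, 12)` follows the convention of the CNN encoder this
#'   architecture builds on; `c(1, 2, 3)` gives the literal reading of the
#'   "32 x 1, 32 x 2, 32 x 3" kernel description.
#' @param shared_dim dimension of the shared metric space.
#' @param fc_widths widths of the fully connected head layers.
#' @param dropout_rates dropout rates after the first two head layers.
#' @param margin triplet margin (> 0).
#' @param triplet_weight weight of the triplet term in the objective (>= 0).
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param max_len protein encoding rows.
#' @param radius fingerprint circular radius.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return a `model_config` list.
#' @export
model_config <- function(mlp_widths = c(1024L, 256L, 64L, 256L),
                         cnn_filters = c(32L, 32L, 32L),
                         cnn_kernel_lengths = c(4L, 8L, 12L),
                         shared_dim = 256L,
                         fc_widths = c(1024L, 1024L, 512L),
                         dropout_rates = c(0.1, 0.1),
                         margin = 1,
                         triplet_weight = 1,
                         learning_rate = 1e-4,
                         batch_size = 256L,
                         epochs = 100L,
                         max_len = 1000L,
                         radius = 2L,
                         seed = 1L) {
  cfg <- list(
    mlp_widths = as.integer(mlp_widths),
    cnn_filters = as.integer(cnn_filters),
    cnn_kernel_lengths = as.integer(cnn_kernel_lengths),
    shared_dim = as.integer(shared_dim),
    fc_widths = as.integer(fc_widths),
    dropout_rates = as.numeric(dropout_rates),
    margin = as.numeric(margin),
    triplet_weight = as.numeric(triplet_weight),
    learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    max_len = as.integer(max_len),
    radius = as.integer(radius),
    seed = as.integer(seed)
  )
  if (length(cfg$mlp_widths) < 2L) stop("mlp_widths needs input plus >= 1 layer",
                                        call. = FALSE)
  if (length(cfg$cnn_filters) != length(cfg$cnn_kernel_lengths)) {
    stop("cnn_filters and cnn_kernel_lengths must have the same length",
         call. = FALSE)
  }
  if (cfg$margin <= 0) stop("margin must be > 0", call. = FALSE)
  if (cfg$triplet_weight < 0) stop("triplet_weight must be >= 0", call. = FALSE)
  if (any(cfg$dropout_rates < 0 | cfg$dropout_rates >= 1)) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  if (sum(cfg$cnn_kernel_lengths) - length(cfg$cnn_kernel_lengths) + 1L > cfg$max_len) {
    stop("convolution kernels longer than the sequence axis", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

# He-uniform initialized dense layer: W is fan_in x fan_out, bias zero.
init_dense <- function(fan_in, fan_out) {
  r <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
       b = numeric(fan_out))
}

#' Initialize model parameters
#'
#' Fan-in-scaled uniform (He) initialization of every layer, seeded from
#' `config$seed`. Layout: `mlp` (drug encoder layers), `conv` (protein
#' encoder layers, each weight `(C_in * kernel) x filters`), `proj_drug` /
#' `proj_prot` (affine maps into the shared space), `fc` (head layers plus
#' the final scalar output layer).
#'
#' @param config a `model_config`.
#' @return nested list of weight matrices and bias vectors.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    w <- config$mlp_widths
    mlp <- lapply(seq_len(length(w) - 1L), function(l) init_dense(w[l], w[l + 1L]))
    n_vocab <- length(protein_vocab())
    c_in <- c(n_vocab, config$cnn_filters[-length(config$cnn_filters)])
    conv <- lapply(seq_along(config$cnn_filters), function(l) {
      init_dense(c_in[l] * config$cnn_kernel_lengths[l], config$cnn_filters[l])
    })
    proj_drug <- init_dense(w[length(w)], config$shared_dim)
    proj_prot <- init_dense(config$cnn_filters[length(config$cnn_filters)],
                            config$shared_dim)
    fcw <- c(2L * config$shared_dim, config$fc_widths, 1L)
    fc <- lapply(seq_len(length(fcw) - 1L), function(l) init_dense(fcw[l], fcw[l + 1L]))
    list(mlp = mlp, conv = conv, proj_drug = proj_drug, proj_prot = proj_prot,
         fc = fc)
  })
}

# ---- drug tunnel ----------------------------------------------------------

# Forward through the drug MLP. X: batch x fingerprint_bits. ReLU after every
# layer. Returns output and caches for backprop.
mlp_forward <- function(X, params) {
  acts <- list(X)
  pre <- vector("list", length(params$mlp))
  for (l in seq_along(params$mlp)) {
    p <- params$mlp[[l]]
    z <- add_bias(acts[[l]] %*% p$W, p$b)
    pre[[l]] <- z
    acts[[l + 1L]] <- relu(z)
  }
  list(out = acts[[length(acts)]], acts = acts, pre = pre)
}

mlp_backward <- function(dout, fwd, params) {
  grads <- vector("list", length(params$mlp))
  d <- dout
  for (l in rev(seq_along(params$mlp))) {
    d <- d * (fwd$pre[[l]] > 0)
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], d), b = colSums(d))
    if (l > 1L) d <- tcrossprod(d, params$mlp[[l]]$W)
  }
  grads
}

#' Encode a drug fingerprint
#'
#' Runs one fingerprint (or a matrix of fingerprints, one per row) through
#' the drug MLP tunnel in evaluation mode.
#'
#' @param fp a `drug_fingerprint`, plain 0/1 vector, or matrix with one
#'   fingerprint per row.
#' @param params model parameters from [init_params()].
#' @param config the `model_config`.
#' @return numeric matrix, one encoding of width `mlp_widths[length(mlp_widths)]`
#'   per row (a single fingerprint gives one row).
#' @export
drug_encoder <- function(fp, params, config) {
  X <- if (is.matrix(fp)) fp else matrix(as.numeric(fp), nrow = 1L)
  if (ncol(X) != config$mlp_widths[1L]) {
    stop(sprintf("fingerprint length %d does not match mlp input width %d",
                 ncol(X), config$mlp_widths[1L]), call. = FALSE)
  }
  mlp_forward(X, params)$out
}

# ---- protein tunnel -------------------------------------------------------

# Forward through the convolution stack + global max pooling for n stacked
# sequences. X: (n * max_len) x 26, sequence-major. Each layer is a compiled
# BLAS-backed 1-D convolution over the sequence axis.
conv_forward <- function(X, n, config, params) {
  L <- config$max_len
  caches <- vector("list", length(params$conv))
  A <- X
  storage.mode(A) <- "double"
  for (l in seq_along(params$conv)) {
    k <- config$cnn_kernel_lengths[l]
    p <- params$conv[[l]]
    pre <- add_bias(conv1d_forward_cpp(A, p$W, n, L, k), p$b)
    caches[[l]] <- list(A_in = A, pre = pre, L_in = L)
    A <- relu(pre)
    L <- L - k + 1L
  }
  # global max pooling per sequence segment: view the stacked activations as
  # (L x n*f) and take column maxima via max.col on the transpose
  f <- ncol(A)
  M <- A
  dim(M) <- c(L, n * f)
  tM <- t(M)
  argmax <- max.col(tM, ties.method = "first")
  pooled <- matrix(tM[cbind(seq_len(n * f), argmax)], n, f)
  argmax <- matrix(argmax, n, f)
  list(out = pooled, caches = caches, L_out = L, argmax = argmax, A_last = A)
}

conv_backward <- function(dout, fwd, n, config, params) {
  L <- fwd$L_out
  f <- ncol(fwd$A_last)
  dA <- matrix(0, n * L, f)
  # route pooled gradients to the argmax positions
  rows <- (rep(seq_len(n), times = f) - 1L) * L + as.vector(fwd$argmax)
  dA[cbind(rows, rep(seq_len(f), each = n))] <- as.vector(dout)
  grads <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    cache <- fwd$caches[[l]]
    dpre <- relu_backward_cpp(dA, cache$pre)
    bw <- conv1d_backward_cpp(cache$A_in, params$conv[[l]]$W, dpre, n,
                              cache$L_in, config$cnn_kernel_lengths[l])
    grads[[l]] <- list(W = bw$W, b = colSums(dpre))
    if (l > 1L) dA <- bw$dA
  }
  grads
}

#' Encode a protein sequence
#'
#' Runs one protein encoding (or a list of encodings) through the
#' convolutional tunnel in evaluation mode: stacked 1-D convolutions with
#' ReLU over the sequence axis, then global max pooling over positions.
#'
#' @param enc a `protein_encoding` (from [encode_protein()]) or list of them.
#' @param params model parameters from [init_params()].
#' @param config the `model_config`.
#' @return numeric matrix, one row per protein, width
#'   `cnn_filters[length(cnn_filters)]`.
#' @export
protein_encoder <- function(enc, params, config) {
  encs <- if (is.list(enc) && !inherits(enc, "protein_encoding")) enc else list(enc)
  for (e in encs) {
    if (!identical(dim(unclass(e)), c(config$max_len, length(protein_vocab())))) {
      stop(sprintf("protein encoding must be %d x %d", config$max_len,
                   length(protein_vocab())), call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(encs, function(e) matrix(as.numeric(e), nrow = nrow(e))))
  conv_forward(X, length(encs), config, params)$out
}

# ---- shared space and head ------------------------------------------------

#' Project an encoder output into the shared metric space
#'
#' Learned affine map that places drug (width `mlp_widths[last]`) and protein
#' (width `cnn_filters[last]`) representations in one `shared_dim`-dimensional
#' space, where the triplet loss distances are defined.
#'
#' @param v numeric vector or matrix (rows = items) from either encoder.
#' @param params model parameters.
#' @param config the `model_config`.
#' @param tunnel `"drug"` or `"protein"`: which projection to apply.
#' @return numeric matrix with `shared_dim` columns.
#' @export
project_shared <- function(v, params, config, tunnel = c("drug", "protein")) {
  tunnel <- match.arg(tunnel)
  V <- if (is.matrix(v)) v else matrix(as.numeric(v), nrow = 1L)
  p <- if (tunnel == "drug") params$proj_drug else params$proj_prot
  if (ncol(V) != nrow(p$W)) {
    stop(sprintf("input width %d does not match %s projection (%d)",
                 ncol(V), tunnel, nrow(p$W)), call. = FALSE)
  }
  add_bias(V %*% p$W, p$b)
}

# Head forward. H: batch x (2 * shared_dim), columns = (protein, drug).
# Dropout masks (inverted dropout, already scaled) are applied after the ReLU
# of the first two layers when supplied; NULL means evaluation mode.
head_forward <- function(H, params, masks = NULL) {
  nl <- length(params$fc)
  acts <- list(H)
  pre <- vector("list", nl)
  for (l in seq_len(nl)) {
    p <- params$fc[[l]]
    z <- add_bias(acts[[l]] %*% p$W, p$b)
    pre[[l]] <- z
    a <- if (l < nl) relu(z) else z     # final layer is linear
    if (!is.null(masks) && l <= length(masks) && !is.null(masks[[l]])) {
      a <- a * masks[[l]]
    }
    acts[[l + 1L]] <- a
  }
  list(out = acts[[nl + 1L]], acts = acts, pre = pre)
}

head_backward <- function(dout, fwd, params, masks = NULL) {
  nl <- length(params$fc)
  grads <- vector("list", nl)
  d <- dout
  for (l in rev(seq_len(nl))) {
    if (!is.null(masks) && l <= length(masks) && !is.null(masks[[l]])) {
      d <- d * masks[[l]]
    }
    if (l < nl) d <- d * (fwd$pre[[l]] > 0)
    grads[[l]] <- list(W = crossprod(fwd$acts[[l]], d), b = colSums(d))
    if (l > 1L) d <- tcrossprod(d, params$fc[[l]]$W)
  }
  list(grads = grads, dH = tcrossprod(d, params$fc[[1L]]$W))
}

#' Predict pKd from shared-space embeddings
#'
#' Concatenates the protein (anchor) and drug embeddings and runs the fully
#' connected regression head in evaluation mode (dropout inactive).
#'
#' @param drug_vec drug embedding(s) in shared space (vector or matrix).
#' @param prot_vec protein embedding(s) in shared space, same number of rows.
#' @param params model parameters.
#' @param config the `model_config`.
#' @return numeric vector of predicted pKd values.
#' @export
predict_affinity <- function(drug_vec, prot_vec, params, config) {
  D <- if (is.matrix(drug_vec)) drug_vec else matrix(as.numeric(drug_vec), nrow = 1L)
  P <- if (is.matrix(prot_vec)) prot_vec else matrix(as.numeric(prot_vec), nrow = 1L)
  stopifnot(nrow(D) == nrow(P), ncol(D) == config$shared_dim,
            ncol(P) == config$shared_dim)
  as.numeric(head_forward(cbind(P, D), params)$out)
}

# ---- losses ---------------------------------------------------------------

#' Triplet loss
#'
#' Protein-anchored margin loss over shared-space embeddings:
#' \deqn{L = \max(\|a - p\|_2^2 - \|a - n\|_2^2 + M,\; 0)}
#' with squared Euclidean distances and margin `M`. Accepts single vectors or
#' row-aligned matrices of triplets.
#'
#' @param anchor anchor embedding(s): the protein.
#' @param positive positive drug embedding(s).
#' @param negative negative drug embedding(s).
#' @param margin the margin `M` (> 0), default 1.
#' @return non-negative numeric vector, one loss per triplet.
#' @examples
#' triplet_loss(c(0, 0), c(3, 0), c(1, 0))  # max(9 - 1 + 1, 0) = 9
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 1) {
  A <- if (is.matrix(anchor)) anchor else matrix(as.numeric(anchor), nrow = 1L)
  P <- if (is.matrix(positive)) positive else matrix(as.numeric(positive), nrow = 1L)
  N <- if (is.matrix(negative)) negative else matrix(as.numeric(negative), nrow = 1L)
  if (!(identical(dim(A), dim(P)) && identical(dim(A), dim(N)))) {
    stop("anchor, positive and negative embeddings must share one dimension",
         call. = FALSE)
  }
  if (margin <= 0) stop("margin must be > 0", call. = FALSE)
  d_ap <- rowSums((A - P)^2)
  d_an <- rowSums((A - N)^2)
  pmax(d_ap - d_an + margin, 0)
}

#' Combined training objective
#'
#' Mean squared error between predicted and true pKd over all records of a
#' batch, plus `triplet_weight` times the mean triplet loss over the batch's
#' positive-labeled records. With no positive records (or `NULL` triplet
#' inputs) the triplet term is zero and the objective reduces to plain MSE.
#'
#' @param y_true true pKd values.
#' @param y_pred predicted pKd values, same length.
#' @param anchors,positives,negatives shared-space embedding matrices of the
#'   positive-labeled records' triplets (rows aligned), or `NULL`.
#' @param margin triplet margin.
#' @param triplet_weight weight of the triplet term.
#' @return scalar loss value.
#' @export
combined_loss <- function(y_true, y_pred, anchors = NULL, positives = NULL,
                          negatives = NULL, margin = 1, triplet_weight = 1) {
  mse_term <- mse(y_true, y_pred)
  trip_term <- 0
  if (!is.null(anchors) && NROW(anchors) > 0L) {
    trip_term <- mean(triplet_loss(anchors, positives, negatives, margin))
  }
  mse_term + triplet_weight * trip_term
}
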