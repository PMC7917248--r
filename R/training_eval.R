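# Training and evaluation: minibatch Adam on the combined objective
# (MSE + triplet), concordance index and MSE metrics, checkpointing.

# ---- parameter flattening (used by Adam and by gradient checks) -----------

flatten_params <- function(params) {
  leaves <- list()
  rec <- function(x) {
    if (is.list(x)) for (e in x) rec(e)
    else leaves[[length(leaves) + 1L]] <<- as.numeric(x)
  }
  rec(params)
  unlist(leaves, use.names = FALSE)
}

# Index-based inverse of flatten_params (depth-first, column-major leaves).
unflatten_params <- function(theta, skeleton) {
  off <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- theta[off + seq_len(n)]
    off <<- off + n
    if (is.matrix(s)) dim(out) <- dim(s)
    out
  }
  rec(skeleton)
}

# Elementwise maps over aligned numeric leaves of parallel parameter trees.
map_leaves2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_leaves2(a[[i]], b[[i]], f)
    return(out)
  }
  f(a, b)
}

map_leaves3 <- function(a, b, c3, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_leaves3(a[[i]], b[[i]], c3[[i]], f)
    return(out)
  }
  f(a, b, c3)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
}

# Recursive fused Adam step: mutates the leaves of params/m/v in place.
adam_walk <- function(params, m, v, g, lr, beta1, beta2, eps, c1, c2) {
  if (is.list(params)) {
    for (i in seq_along(params)) {
      adam_walk(params[[i]], m[[i]], v[[i]], g[[i]], lr, beta1, beta2, eps, c1, c2)
    }
    return(invisible(NULL))
  }
  adam_update_cpp(params, m, v, g, lr, beta1, beta2, eps, c1, c2)
  invisible(NULL)
}

# ---- metrics --------------------------------------------------------------

#' Mean squared error
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 1).
#' @return mean of squared differences.
#' @export
mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    stop("y_true and y_pred must have equal length >= 1", call. = FALSE)
  }
  mean((y_true - y_pred)^2)
}

#' Concordance index
#'
#' Fraction of comparable pairs (pairs with distinct true values) whose
#' predicted ordering matches the true ordering; prediction ties count 0.5.
#' 0.5 is chance level, 1 is perfect ranking.
#'
#' @param y_true numeric vector of true values (length >= 2, not all equal).
#' @param y_pred numeric vector of predictions, same length.
#' @return scalar in \[0, 1\].
#' @export
concordance_index <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n != length(y_pred) || n < 2L) {
    stop("y_true and y_pred must have equal length >= 2", call. = FALSE)
  }
  dt <- outer(y_true, y_true, "-")
  dp <- outer(y_pred, y_pred, "-")
  comp <- dt > 0            # ordered pairs (i, j) with y_true[i] > y_true[j]
  if (!any(comp)) {
    stop("concordance index undefined: all true values are tied", call. = FALSE)
  }
  score <- sum((dp[comp] > 0) + 0.5 * (dp[comp] == 0))
  score / sum(comp)
}

# ---- batched forward/backward --------------------------------------------

# One forward (and optionally backward) pass of the combined objective on a
# batch. `data` holds precomputed features:
#   fps:        n_drugs x fp_bits fingerprint matrix
#   prot_stack: list of per-protein one-hot matrices (max_len x 26)
# `batch` is a data.frame with drug_index, protein_index, neg_index, pkd,
# label. Dropout masks are drawn from the current RNG when train = TRUE.
batch_loss_grads <- function(params, batch, data, config, train = FALSE,
                             with_grads = TRUE) {
  B <- nrow(batch)
  s <- config$shared_dim
  use_triplet <- config$triplet_weight > 0
  ud <- sort(unique(c(batch$drug_index,
                      if (use_triplet) batch$neg_index[batch$label == "positive"])))
  up <- sort(unique(batch$protein_index))
  map_d <- match(batch$drug_index, ud)
  map_n <- match(batch$neg_index, ud)
  map_p <- match(batch$protein_index, up)

  fwd_mlp <- mlp_forward(data$fps[ud, , drop = FALSE], params)
  E_d <- fwd_mlp$out
  Pd <- add_bias(E_d %*% params$proj_drug$W, params$proj_drug$b)

  n_up <- length(up)
  X_prot <- do.call(rbind, data$prot_stack[up])
  fwd_conv <- conv_forward(X_prot, n_up, config, params)
  E_p <- fwd_conv$out
  Pp <- add_bias(E_p %*% params$proj_prot$W, params$proj_prot$b)

  H <- cbind(Pp[map_p, , drop = FALSE], Pd[map_d, , drop = FALSE])
  masks <- NULL
  if (train && any(config$dropout_rates > 0)) {
    masks <- lapply(seq_along(config$dropout_rates), function(l) {
      rate <- config$dropout_rates[l]
      if (rate <= 0) return(NULL)
      keep <- matrix(stats::rbinom(B * config$fc_widths[l], 1L, 1 - rate),
                     B, config$fc_widths[l])
      keep / (1 - rate)
    })
  }
  fwd_head <- head_forward(H, params, masks)
  pred <- as.numeric(fwd_head$out)

  resid <- pred - batch$pkd
  loss_mse <- mean(resid^2)

  pos <- which(batch$label == "positive")
  loss_trip <- 0
  if (use_triplet && length(pos)) {
    A <- Pp[map_p[pos], , drop = FALSE]
    Pmat <- Pd[map_d[pos], , drop = FALSE]
    Nmat <- Pd[map_n[pos], , drop = FALSE]
    lt <- triplet_loss(A, Pmat, Nmat, config$margin)
    loss_trip <- mean(lt)
  }
  loss <- loss_mse + config$triplet_weight * loss_trip
  if (!with_grads) {
    return(list(loss = loss, loss_mse = loss_mse, loss_triplet = loss_trip,
                pred = pred))
  }

  # ---- backward ----
  dpred <- matrix(2 * resid / B, ncol = 1L)
  bwd_head <- head_backward(dpred, fwd_head, params, masks)
  dPp_rows <- bwd_head$dH[, seq_len(s), drop = FALSE]
  dPd_rows <- bwd_head$dH[, s + seq_len(s), drop = FALSE]

  dPd_extra_idx <- integer(0)
  dPd_extra <- NULL
  if (use_triplet && length(pos)) {
    act <- as.numeric(lt > 0) * config$triplet_weight / length(pos)
    dA <- 2 * (Nmat - Pmat) * act
    dPos <- 2 * (Pmat - A) * act
    dNeg <- 2 * (A - Nmat) * act
    dPp_rows[pos, ] <- dPp_rows[pos, , drop = FALSE] + dA
    dPd_rows[pos, ] <- dPd_rows[pos, , drop = FALSE] + dPos
    dPd_extra_idx <- map_n[pos]
    dPd_extra <- dNeg
  }

  accum <- function(rows_mat, groups, n_groups, extra_mat = NULL, extra_groups = NULL) {
    X <- rows_mat
    g <- groups
    if (!is.null(extra_mat)) {
      X <- rbind(X, extra_mat)
      g <- c(g, extra_groups)
    }
    rs <- rowsum(X, g)
    out <- matrix(0, n_groups, ncol(rows_mat))
    out[as.integer(rownames(rs)), ] <- rs
    out
  }
  dPd_u <- accum(dPd_rows, map_d, length(ud), dPd_extra, dPd_extra_idx)
  dPp_u <- accum(dPp_rows, map_p, n_up)

  g_proj_drug <- list(W = crossprod(E_d, dPd_u), b = colSums(dPd_u))
  dE_d <- tcrossprod(dPd_u, params$proj_drug$W)
  g_proj_prot <- list(W = crossprod(E_p, dPp_u), b = colSums(dPp_u))
  dE_p <- tcrossprod(dPp_u, params$proj_prot$W)

  g_mlp <- mlp_backward(dE_d, fwd_mlp, params)
  g_conv <- conv_backward(dE_p, fwd_conv, n_up, config, params)

  grads <- list(mlp = g_mlp, conv = g_conv, proj_drug = g_proj_drug,
                proj_prot = g_proj_prot, fc = bwd_head$grads)
  list(loss = loss, loss_mse = loss_mse, loss_triplet = loss_trip,
       pred = pred, grads = grads)
}

# Precompute featurization caches for the drugs/proteins referenced by a set
# of records (library-level: fingerprints of all library drugs, one-hot
# encodings and first-layer im2col of all proteins).
build_feature_cache <- function(dataset, config) {
  b <- dataset$base
  fps <- ecfp_fingerprints(b$drug_smiles, radius = config$radius,
                           n_bits = config$mlp_widths[1L])
  prot_stack <- lapply(b$protein_seqs, function(s) {
    e <- encode_protein(s, max_len = config$max_len)
    matrix(as.numeric(e), nrow(e), ncol(e))
  })
  # negative SMILES refer back to library drugs; resolve to indices
  neg_index <- matrix(match(dataset$negative_smiles, b$drug_smiles),
                      nrow(dataset$negative_smiles), ncol(dataset$negative_smiles))
  if (anyNA(neg_index)) {
    canon_lib <- canonical_smiles(b$drug_smiles)
    canon_neg <- canonical_smiles(as.vector(dataset$negative_smiles))
    neg_index <- matrix(match(canon_neg, canon_lib), nrow(neg_index), ncol(neg_index))
    if (anyNA(neg_index)) {
      stop("negative-sample SMILES not found in the drug library", call. = FALSE)
    }
  }
  list(fps = fps, prot_stack = prot_stack, neg_index = neg_index)
}

# ---- training -------------------------------------------------------------

#' Train the three-tunnel model
#'
#' Splits the dataset's records 7:1:2 into train/validation/test (seeded),
#' featurizes drugs and proteins once, and runs `config$epochs` epochs of
#' minibatch Adam on the combined objective. After each epoch the validation
#' MSE and concordance index are recorded; the returned model carries the
#' parameters of the epoch with minimal validation MSE. Fully reproducible
#' for a fixed seed.
#'
#' @param dataset an `extended_dataset`.
#' @param config a `model_config`.
#' @param pkd_override optional numeric vector overriding the records' pKd
#'   targets (in record order), e.g. a permuted copy for a negative control.
#' @return a list of class `tunnel3_model` with elements `params`, `config`,
#'   `history` (a `training_history` data.frame with per-epoch train loss,
#'   validation MSE and CI), `best_epoch`, and `splits` (the record indices
#'   of each split).
#' @export
train <- function(dataset, config = model_config(), pkd_override = NULL) {
  stopifnot(inherits(dataset, "extended_dataset"), inherits(config, "model_config"))
  records <- as_affinity_records(dataset)
  if (!is.null(pkd_override)) {
    stopifnot(length(pkd_override) == nrow(records))
    records$pkd <- as.numeric(pkd_override)
  }
  cache <- build_feature_cache(dataset, config)
  records$neg_index <- cache$neg_index[cbind(records$drug_index,
                                             records$protein_index)]
  records$row_id <- seq_len(nrow(records))
  splits <- split_records(records, seed = config$seed)
  if (!nrow(splits$train)) stop("empty training split", call. = FALSE)

  params <- init_params(config)
  m <- zeros_like(params); v <- zeros_like(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  n_train <- nrow(splits$train)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_mse = numeric(), train_triplet = numeric(),
                        val_mse = numeric(), val_ci = numeric())
  best <- list(epoch = NA_integer_, val_mse = Inf, params = params)

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n_train)
      n_batches <- ceiling(n_train / config$batch_size)
      epoch_loss <- epoch_mse <- epoch_trip <- 0
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n_train)]
        batch <- splits$train[idx, , drop = FALSE]
        res <- batch_loss_grads(params, batch, cache, config, train = TRUE)
        step <- step + 1L
        # fused in-place Adam over the leaves; params/m/v are owned solely by
        # this loop (checkpoints below take deep copies)
        adam_walk(params, m, v, res$grads, lr, beta1, beta2, eps,
                  1 - beta1^step, 1 - beta2^step)
        w <- length(idx) / n_train
        epoch_loss <- epoch_loss + w * res$loss
        epoch_mse <- epoch_mse + w * res$loss_mse
        epoch_trip <- epoch_trip + w * res$loss_triplet
      }
      val <- batch_loss_grads(params, splits$validation, cache, config,
                              train = FALSE, with_grads = FALSE)
      val_mse <- mse(splits$validation$pkd, val$pred)
      val_ci <- tryCatch(concordance_index(splits$validation$pkd, val$pred),
                         error = function(e) NA_real_)
      history[epoch, ] <- list(epoch, epoch_loss, epoch_mse, epoch_trip,
                               val_mse, val_ci)
      if (val_mse < best$val_mse) {
        best <- list(epoch = epoch, val_mse = val_mse,
                     params = map_leaves2(params, params, function(a, b) a + 0))
      }
    }
  })

  params <- best$params
  attr(history, "best_epoch") <- best$epoch
  attr(history, "seed") <- config$seed
  attr(history, "config_hash") <- fnv1a_hash(unclass(config))
  class(history) <- c("training_history", class(history))
  structure(
    list(params = params, config = config, history = history,
         best_epoch = best$epoch,
         splits = lapply(splits, function(s) s$row_id)),
    class = "tunnel3_model"
  )
}

#' @export
print.tunnel3_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<tunnel3_model> %d epochs trained, best epoch %d (val MSE %.4f, val CI %.3f)\n",
    nrow(h), x$best_epoch, h$val_mse[x$best_epoch], h$val_ci[x$best_epoch]
  ))
  invisible(x)
}

# ---- prediction and evaluation -------------------------------------------

#' Predict pKd for affinity records
#'
#' Featurizes the unique drugs and proteins referenced by `records` and runs
#' the model in evaluation mode.
#'
#' @param model a `tunnel3_model`.
#' @param records a data.frame with columns `drug_smiles` and `protein_seq`
#'   (as produced by [as_affinity_records()]).
#' @return numeric vector of predicted pKd values, one per record row.
#' @export
predict_records <- function(model, records) {
  stopifnot(inherits(model, "tunnel3_model"))
  config <- model$config
  params <- model$params
  u_smi <- unique(records$drug_smiles)
  u_seq <- unique(records$protein_seq)
  fps <- ecfp_fingerprints(u_smi, radius = config$radius,
                           n_bits = config$mlp_widths[1L])
  E_d <- drug_encoder(fps, params, config)
  Pd <- project_shared(E_d, params, config, "drug")
  encs <- lapply(u_seq, encode_protein, max_len = config$max_len)
  E_p <- protein_encoder(encs, params, config)
  Pp <- project_shared(E_p, params, config, "protein")
  di <- match(records$drug_smiles, u_smi)
  pi <- match(records$protein_seq, u_seq)
  predict_affinity(Pd[di, , drop = FALSE], Pp[pi, , drop = FALSE], params, config)
}

#' Evaluate a model on a set of records
#'
#' @param model a `tunnel3_model`.
#' @param records a data.frame of affinity records with a `pkd` column.
#' @return a list with elements `mse` and `ci`.
#' @export
evaluate <- function(model, records) {
  pred <- predict_records(model, records)
  list(mse = mse(records$pkd, pred),
       ci = concordance_index(records$pkd, pred))
}

# ---- checkpoint IO --------------------------------------------------------

#' Save a trained model checkpoint
#'
#' Writes the flattened weights (`weights.rds`), a JSON metadata sidecar
#' (`metadata.json`: config, protein vocabulary, fingerprint parameters,
#' seed, config hash) and the training history (`history.tsv`) so inference
#' is self-describing.
#'
#' @param model a `tunnel3_model`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "tunnel3_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(flatten_params(model$params), file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config),
         protein_vocab = protein_vocab(),
         fingerprint = list(radius = model$config$radius,
                            n_bits = model$config$mlp_widths[1L]),
         best_epoch = model$best_epoch,
         seed = model$config$seed,
         config_hash = fnv1a_hash(unclass(model$config))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(model$history)) {
    utils::write.table(as.data.frame(model$history), file.path(dir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load a model checkpoint saved by [save_model()]
#'
#' @param dir checkpoint directory.
#' @return a `tunnel3_model` (without training history splits).
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  config <- do.call(model_config, meta$config[setdiff(names(meta$config), character())])
  theta <- readRDS(file.path(dir, "weights.rds"))
  skeleton <- init_params(config)
  params <- unflatten_params(theta, skeleton)
  structure(list(params = params, config = config, history = NULL,
                 best_epoch = meta$best_epoch, splits = NULL),
            class = "tunnel3_model")
}
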