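# Extended-dataset construction and IO.
#
# The training ground truth is a dense drugs x proteins matrix of dissociation
# constants (Kd, nanomolar). The "extended" layout adds a same-shaped matrix of
# negative-sample SMILES: for each (drug i, protein j) cell, the SMILES of some
# drug that binds protein j only weakly (Kd above the positive/negative
# boundary). Four files: drug SMILES table (TSV), protein FASTA, Kd matrix
# (TSV), negative-sample SMILES matrix (TSV).

#' Convert Kd (nM) to pKd
#'
#' The regression target is the log-space affinity
#' \deqn{pKd = -\log_{10}(Kd \cdot 10^{-9} + 10^{-10})}
#' with Kd in nanomolar. The additive offset keeps the transform finite at
#' Kd = 0, where pKd is exactly 10; the map is strictly decreasing, so higher
#' pKd always means tighter binding.
#'
#' @param kd numeric vector of dissociation constants in nanomolar; must be
#'   finite and non-negative.
#' @return numeric vector of pKd values in (0, 10].
#' @examples
#' kd_to_pkd(c(0, 50, 10000))
#' @seealso [pkd_to_kd()] for the inverse.
#' @export
kd_to_pkd <- function(kd) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd < 0)) {
    stop("kd must be finite and >= 0 (nanomolar)", call. = FALSE)
  }
  -log10(kd * 1e-9 + 1e-10)
}

#' Convert pKd back to Kd (nM)
#'
#' Inverse of [kd_to_pkd()]: `Kd = (10^-pKd - 10^-10) / 10^-9`. Only defined
#' for pKd <= 10 (pKd = 10 maps to Kd = 0).
#'
#' @param pkd numeric vector of pKd values, each <= 10.
#' @return numeric vector of Kd in nanomolar.
#' @export
pkd_to_kd <- function(pkd) {
  if (!is.numeric(pkd) || any(!is.finite(pkd)) || any(pkd > 10 + 1e-12)) {
    stop("pkd must be finite and <= 10", call. = FALSE)
  }
  pmax((10^(-pkd) - 1e-10) / 1e-9, 0)
}

#' Label a drug-target pair as positive or negative
#'
#' A pair is a positive sample when its Kd is at or below the boundary
#' (default 50 nM), negative when strictly above it.
#'
#' @param kd numeric vector of Kd values in nanomolar.
#' @param boundary positive/negative boundary in nanomolar (default 50).
#' @return character vector over `c("positive", "negative")`.
#' @export
label_pair <- function(kd, boundary = 50) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd < 0)) {
    stop("kd must be finite and >= 0 (nanomolar)", call. = FALSE)
  }
  ifelse(kd <= boundary, "positive", "negative")
}

#' Construct an affinity matrix object
#'
#' Bundles aligned drug and protein identifier/sequence lists with the dense
#' Kd matrix. Davis-style data lies in \[0, 10000\] nM; values outside that
#' range are allowed but produce a warning.
#'
#' @param drug_ids character vector of drug identifiers.
#' @param drug_smiles character vector of SMILES, aligned to `drug_ids`.
#' @param protein_ids character vector of protein identifiers.
#' @param protein_seqs character vector of amino-acid sequences, aligned to
#'   `protein_ids`.
#' @param kd numeric matrix of Kd values (nM), rows = drugs, cols = proteins.
#' @return an object of class `affinity_matrix`.
#' @export
affinity_matrix <- function(drug_ids, drug_smiles, protein_ids, protein_seqs, kd) {
  drug_ids <- as.character(drug_ids)
  protein_ids <- as.character(protein_ids)
  kd <- as.matrix(kd)
  if (length(drug_smiles) != length(drug_ids)) {
    stop("drug_smiles must align with drug_ids", call. = FALSE)
  }
  if (length(protein_seqs) != length(protein_ids)) {
    stop("protein_seqs must align with protein_ids", call. = FALSE)
  }
  if (nrow(kd) != length(drug_ids) || ncol(kd) != length(protein_ids)) {
    stop(sprintf(
      "Kd matrix is %d x %d but there are %d drugs and %d proteins",
      nrow(kd), ncol(kd), length(drug_ids), length(protein_ids)
    ), call. = FALSE)
  }
  if (any(!is.finite(kd)) || any(kd < 0)) {
    stop("Kd matrix must be dense with finite values >= 0", call. = FALSE)
  }
  if (any(kd > 10000)) {
    warning("Kd values above 10000 nM found; Davis-style data lies in [0, 10000]",
            call. = FALSE)
  }
  dimnames(kd) <- list(drug_ids, protein_ids)
  structure(
    list(drug_ids = drug_ids, drug_smiles = as.character(drug_smiles),
         protein_ids = protein_ids, protein_seqs = toupper(as.character(protein_seqs)),
         kd = kd),
    class = "affinity_matrix"
  )
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d drugs x %d proteins, Kd in [%.3g, %.3g] nM\n",
              length(x$drug_ids), length(x$protein_ids), min(x$kd), max(x$kd)))
  invisible(x)
}

#' Build the negative-sample SMILES matrix
#'
#' For every cell (drug i, protein j) picks, uniformly at random under a fixed
#' seed, the SMILES of a drug whose Kd against protein j exceeds the boundary
#' (a negative sample for that protein). A protein column with no negative
#' drug at all falls back to sampling from the pooled negatives of the other
#' proteins, with a warning; if no negative exists anywhere the matrix cannot
#' be built and an error is raised.
#'
#' @param base an `affinity_matrix`.
#' @param boundary positive/negative Kd boundary in nM (default 50).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return character matrix of SMILES, same shape as `base$kd`. The indices of
#'   columns that used the fallback pool are recorded in the
#'   `"fallback_columns"` attribute.
#' @export
build_negative_matrix <- function(base, boundary = 50, seed = 1L) {
  stopifnot(inherits(base, "affinity_matrix"))
  n_drug <- length(base$drug_ids)
  n_prot <- length(base$protein_ids)
  neg_by_col <- lapply(seq_len(n_prot), function(j) which(base$kd[, j] > boundary))
  pool <- sort(unique(unlist(neg_by_col)))
  if (!length(pool)) {
    stop("no drug is a negative sample for any protein; cannot build negative matrix",
         call. = FALSE)
  }
  fallback_cols <- which(vapply(neg_by_col, length, 1L) == 0L)
  if (length(fallback_cols)) {
    warning(sprintf(
      "%d protein column(s) have no negative drug; sampling negatives from other proteins for: %s",
      length(fallback_cols),
      paste(utils::head(base$protein_ids[fallback_cols], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  nm <- matrix(NA_character_, n_drug, n_prot,
               dimnames = list(base$drug_ids, base$protein_ids))
  with_seed(seed, {
    for (j in seq_len(n_prot)) {
      adm <- neg_by_col[[j]]
      if (!length(adm)) adm <- pool
      pick <- adm[sample.int(length(adm), n_drug, replace = TRUE)]
      nm[, j] <- base$drug_smiles[pick]
    }
  })
  attr(nm, "fallback_columns") <- fallback_cols
  nm
}

#' Construct an extended dataset
#'
#' Combines an affinity matrix with the positive/negative labeling at the Kd
#' boundary and the negative-sample SMILES matrix (built with
#' [build_negative_matrix()] when not supplied).
#'
#' @param base an `affinity_matrix`.
#' @param negative_smiles optional character matrix of negative-sample SMILES
#'   with the same shape as `base$kd`; built from `base` when `NULL`.
#' @param boundary positive/negative Kd boundary in nM (default 50).
#' @param seed integer seed used when the negative matrix must be built.
#' @return an object of class `extended_dataset` with fields `base`,
#'   `negative_smiles`, `labels` (character matrix over
#'   `c("positive","negative")`) and `boundary`.
#' @export
extend_dataset <- function(base, negative_smiles = NULL, boundary = 50, seed = 1L) {
  stopifnot(inherits(base, "affinity_matrix"))
  if (is.null(negative_smiles)) {
    negative_smiles <- build_negative_matrix(base, boundary = boundary, seed = seed)
  }
  negative_smiles <- as.matrix(negative_smiles)
  if (!identical(dim(negative_smiles), dim(base$kd))) {
    stop(sprintf(
      "negative-sample matrix is %d x %d but the Kd matrix is %d x %d",
      nrow(negative_smiles), ncol(negative_smiles), nrow(base$kd), ncol(base$kd)
    ), call. = FALSE)
  }
  assert_smiles(unique(as.vector(negative_smiles)), what = "negative-sample SMILES")
  labels <- matrix(label_pair(base$kd, boundary), nrow(base$kd), ncol(base$kd),
                   dimnames = dimnames(base$kd))
  structure(
    list(base = base, negative_smiles = negative_smiles, labels = labels,
         boundary = boundary),
    class = "extended_dataset"
  )
}

#' @export
print.extended_dataset <- function(x, ...) {
  n_pos <- sum(x$labels == "positive")
  cat(sprintf(
    "<extended_dataset> %d drugs x %d proteins (%d records), boundary %g nM, %d positive (%.1f%%)\n",
    length(x$base$drug_ids), length(x$base$protein_ids), length(x$labels),
    x$boundary, n_pos, 100 * n_pos / length(x$labels)
  ))
  invisible(x)
}

#' Enumerate a dataset as per-pair affinity records
#'
#' Flattens the dense matrix into one row per drug-target pair with the Kd,
#' pKd, label and the pair's negative-sample SMILES, plus the drug SMILES and
#' protein sequence so downstream featurization needs no back-reference.
#'
#' @param dataset an `extended_dataset`.
#' @return a data.frame with one row per (drug, protein) cell: `drug_index`,
#'   `protein_index`, `drug_id`, `protein_id`, `drug_smiles`, `protein_seq`,
#'   `kd`, `pkd`, `label`, `negative_smiles`.
#' @export
as_affinity_records <- function(dataset) {
  stopifnot(inherits(dataset, "extended_dataset"))
  b <- dataset$base
  n_drug <- length(b$drug_ids)
  n_prot <- length(b$protein_ids)
  di <- rep(seq_len(n_drug), times = n_prot)
  pj <- rep(seq_len(n_prot), each = n_drug)
  data.frame(
    drug_index = di,
    protein_index = pj,
    drug_id = b$drug_ids[di],
    protein_id = b$protein_ids[pj],
    drug_smiles = b$drug_smiles[di],
    protein_seq = b$protein_seqs[pj],
    kd = as.vector(b$kd),
    pkd = kd_to_pkd(as.vector(b$kd)),
    label = as.vector(dataset$labels),
    negative_smiles = as.vector(dataset$negative_smiles),
    stringsAsFactors = FALSE
  )
}

#' Split records into train/validation/test subsets
#'
#' Shuffles the records under a fixed seed and partitions them in the given
#' ratios (default 7:1:2). Subset sizes are `floor(n * ratio)` with the
#' remainder assigned to the training split.
#'
#' @param records a data.frame of affinity records (or anything with rows).
#' @param ratios numeric vector of three ratios summing to 1.
#' @param seed integer seed for the shuffle.
#' @return a list with data.frames `train`, `validation`, `test`; the three
#'   are disjoint and cover the input.
#' @export
split_records <- function(records, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n < 3L) stop("need at least 3 records to split", call. = FALSE)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8 || any(ratios < 0)) {
    stop("ratios must be three non-negative numbers summing to 1", call. = FALSE)
  }
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  list(
    train = records[perm[seq_len(n_train)], , drop = FALSE],
    validation = records[perm[n_train + seq_len(n_val)], , drop = FALSE],
    test = records[perm[n_train + n_val + seq_len(n_test)], , drop = FALSE]
  )
}

#' Read an extended dataset from the four-file layout
#'
#' Expects the layout written by [write_extended_dataset()]: a TSV drug table
#' (`drug_id<TAB>smiles`, with header), a multi-record protein FASTA, a TSV Kd
#' matrix (first column drug ids, header protein ids) and, optionally, a TSV
#' negative-sample SMILES matrix in the same layout. When the negatives file
#' is absent the matrix is built with [build_negative_matrix()].
#'
#' @param smiles_path path to the drug SMILES TSV.
#' @param fasta_path path to the protein FASTA.
#' @param affinity_path path to the Kd matrix TSV.
#' @param negatives_path path to the negative-sample matrix TSV, or `NULL`.
#' @param boundary positive/negative Kd boundary in nM (default 50).
#' @param seed seed used if the negative matrix must be built.
#' @param validate_smiles if `TRUE` (default) every drug SMILES must pass
#'   syntactic validation; the error names the offending row.
#' @return an `extended_dataset`.
#' @export
read_extended_dataset <- function(smiles_path, fasta_path, affinity_path,
                                  negatives_path = NULL, boundary = 50,
                                  seed = 1L, validate_smiles = TRUE) {
  drugs <- utils::read.delim(smiles_path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE)
  if (ncol(drugs) < 2L) stop("drug SMILES table must have columns drug_id, smiles",
                             call. = FALSE)
  names(drugs)[1:2] <- c("drug_id", "smiles")
  if (validate_smiles) {
    ok <- smiles_is_valid(drugs$smiles)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf("unparseable SMILES for drug '%s' (row %d): '%s' (%s)",
                   drugs$drug_id[bad], bad, drugs$smiles[bad],
                   attr(ok, "reasons")[bad]), call. = FALSE)
    }
  }
  prot <- Biostrings::readAAStringSet(fasta_path)
  aff <- utils::read.delim(affinity_path, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  kd <- as.matrix(aff)
  # FASTA ids: first whitespace-delimited token of the record header
  prot_ids <- vapply(strsplit(names(prot), "\\s+"), `[`, "", 1L)
  if (nrow(kd) != nrow(drugs)) {
    stop(sprintf("Kd matrix has %d rows but the drug table has %d",
                 nrow(kd), nrow(drugs)), call. = FALSE)
  }
  if (ncol(kd) != length(prot_ids)) {
    stop(sprintf("Kd matrix has %d columns but the FASTA has %d records",
                 ncol(kd), length(prot_ids)), call. = FALSE)
  }
  ord <- match(colnames(kd), prot_ids)
  if (any(is.na(ord))) {
    stop("Kd matrix column ids do not match FASTA record ids", call. = FALSE)
  }
  base <- affinity_matrix(
    drug_ids = if (!is.null(rownames(kd))) rownames(kd) else drugs$drug_id,
    drug_smiles = drugs$smiles,
    protein_ids = colnames(kd),
    protein_seqs = as.character(prot)[ord],
    kd = kd
  )
  negatives <- NULL
  if (!is.null(negatives_path)) {
    nm <- utils::read.delim(negatives_path, header = TRUE, sep = "\t",
                            row.names = 1L, colClasses = "character",
                            check.names = FALSE)
    negatives <- as.matrix(nm)
    if (!identical(dim(negatives), dim(kd))) {
      stop(sprintf("negative-sample matrix is %d x %d but the Kd matrix is %d x %d",
                   nrow(negatives), ncol(negatives), nrow(kd), ncol(kd)),
           call. = FALSE)
    }
  }
  extend_dataset(base, negative_smiles = negatives, boundary = boundary, seed = seed)
}

#' Write an extended dataset to the four-file layout
#'
#' Writes `drugs.tsv`, `proteins.fasta`, `affinities.tsv`, `negatives.tsv` and
#' a `metadata.json` sidecar (boundary, seed used for the negatives if known,
#' fallback columns) into `dir`.
#'
#' @param dataset an `extended_dataset`.
#' @param dir output directory, created if missing.
#' @param seed optional integer recorded in the sidecar as the seed that
#'   produced the negative matrix.
#' @return `dir`, invisibly.
#' @export
write_extended_dataset <- function(dataset, dir, seed = NULL) {
  stopifnot(inherits(dataset, "extended_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- dataset$base
  utils::write.table(
    data.frame(drug_id = b$drug_ids, smiles = b$drug_smiles),
    file.path(dir, "drugs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  aa <- Biostrings::AAStringSet(b$protein_seqs)
  names(aa) <- b$protein_ids
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.fasta"))
  write_matrix_tsv(b$kd, file.path(dir, "affinities.tsv"))
  write_matrix_tsv(dataset$negative_smiles, file.path(dir, "negatives.tsv"))
  fallback <- attr(dataset$negative_smiles, "fallback_columns")
  jsonlite::write_json(
    list(boundary = dataset$boundary,
         seed = seed,
         n_drugs = length(b$drug_ids),
         n_proteins = length(b$protein_ids),
         fallback_columns = if (length(fallback)) fallback else integer()),
    file.path(dir, "metadata.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(drug_id = rownames(m), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
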