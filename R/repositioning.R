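# Virtual-screening pipeline: score a candidate SMILES library against one
# target protein with a trained model, rank by predicted pKd (descending:
# higher pKd = lower Kd = stronger binding), then annotate post-hoc filters
# (molecular weight, curated exclusion list). Filtering never alters scores;
# it flags rows and re-ranks the survivors.

#' Rank candidate drugs against a target protein
#'
#' Scores every parseable candidate with the trained model and orders them by
#' predicted pKd, strongest binder first. Candidates whose SMILES fail
#' validation are skipped with a warning (and reported in the
#' `"skipped"` attribute), not fatal. Ties keep the input order.
#'
#' @param model a `tunnel3_model`.
#' @param candidates data.frame with columns `drug_id` and `smiles` (first
#'   two columns are used if named differently).
#' @param target_seq amino-acid sequence of the target protein, or a path to
#'   a FASTA file whose first record is used.
#' @return a `ranked_candidates` data.frame with columns `rank`, `drug_id`,
#'   `smiles`, `predicted_pkd`, `molecular_weight`, `excluded`,
#'   `exclusion_reason`, sorted by predicted pKd descending with consecutive
#'   ranks from 1.
#' @export
rank_candidates <- function(model, candidates, target_seq) {
  stopifnot(inherits(model, "tunnel3_model"), is.data.frame(candidates))
  if (!nrow(candidates)) stop("empty candidate list", call. = FALSE)
  names(candidates)[1:2] <- c("drug_id", "smiles")
  if (length(target_seq) == 1L && file.exists(target_seq)) {
    fa <- Biostrings::readAAStringSet(target_seq)
    if (!length(fa)) stop("unreadable or empty target FASTA", call. = FALSE)
    target_seq <- as.character(fa[[1L]])
  }
  ok <- smiles_is_valid(candidates$smiles)
  if (!all(ok)) {
    warning(sprintf("skipping %d unparseable candidate SMILES: %s",
                    sum(!ok),
                    paste(utils::head(candidates$drug_id[!ok], 5L), collapse = ", ")),
            call. = FALSE)
  }
  skipped <- candidates[!ok, , drop = FALSE]
  kept <- candidates[ok, , drop = FALSE]
  if (!nrow(kept)) stop("no candidate has parseable SMILES", call. = FALSE)
  records <- data.frame(drug_smiles = kept$smiles,
                        protein_seq = toupper(target_seq),
                        stringsAsFactors = FALSE)
  pred <- predict_records(model, records)
  mw <- molecular_weight(kept$smiles)
  ord <- order(-pred, seq_along(pred))     # stable: ties keep input position
  out <- data.frame(
    rank = seq_len(nrow(kept)),
    drug_id = kept$drug_id[ord],
    smiles = kept$smiles[ord],
    predicted_pkd = pred[ord],
    molecular_weight = mw[ord],
    excluded = FALSE,
    exclusion_reason = "none",
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ranked_candidates", class(out)), skipped = skipped)
}

#' Apply post-hoc filters to a ranking
#'
#' Flags candidates with molecular weight strictly below `mw_threshold`
#' (reason `"mw_below_threshold"`) and candidates on the curated exclusion
#' list (reason `"exclusion_list"`, e.g. topical drugs; a manual judgment the
#' pipeline takes as input rather than computing). Scores are untouched;
#' surviving rows are re-ranked consecutively from 1 and excluded rows get
#' rank `NA`.
#'
#' @param ranked a `ranked_candidates` data.frame.
#' @param mw_threshold molecular-weight cutoff in Daltons (default 200).
#' @param exclusion_ids character vector of drug ids to remove.
#' @return the annotated `ranked_candidates`; drop the flagged rows with
#'   [retained_candidates()].
#' @export
apply_filters <- function(ranked, mw_threshold = 200, exclusion_ids = character()) {
  stopifnot(inherits(ranked, "ranked_candidates"))
  out <- ranked
  mw_flag <- out$molecular_weight < mw_threshold
  excl_flag <- out$drug_id %in% exclusion_ids
  out$excluded <- mw_flag | excl_flag
  out$exclusion_reason <- ifelse(mw_flag, "mw_below_threshold",
                                 ifelse(excl_flag, "exclusion_list", "none"))
  out$rank <- NA_integer_
  out$rank[!out$excluded] <- seq_len(sum(!out$excluded))
  out
}

#' Retained rows of a filtered ranking
#'
#' @param ranked a `ranked_candidates`, typically after [apply_filters()].
#' @return the rows not flagged as excluded, ranks consecutive from 1.
#' @export
retained_candidates <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_candidates"))
  ranked[!ranked$excluded, , drop = FALSE]
}

#' @export
print.ranked_candidates <- function(x, n = 15L, ...) {
  n_excl <- sum(x$excluded)
  cat(sprintf("<ranked_candidates> %d candidates (%d excluded by filters)\n",
              nrow(x), n_excl))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}
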