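# Featurization: drugs as folded extended-connectivity fingerprints, proteins
# as fixed-size one-hot matrices over a frozen 26-symbol vocabulary.

# Frozen protein vocabulary: the pad/start symbol "?" plus 25 residue codes
# (the 20 standard amino acids and the extended codes B, J, U, X, Z). The
# symbol-to-column map must stay stable across runs and is serialized with
# trained models.
.protein_vocab <- c("?", sort(setdiff(LETTERS, "O")))

#' The frozen protein sequence vocabulary
#'
#' 26 symbols: the prepended `"?"` marker at index 1, then the 25 residue
#' codes (20 standard amino acids plus B, J, U, X, Z) in alphabetical order.
#' One-hot encodings index their columns by this vector.
#'
#' @return character vector of length 26.
#' @export
protein_vocab <- function() .protein_vocab

#' ECFP fingerprint of a molecule
#'
#' Extended-connectivity (circular) fingerprint of the given radius, folded to
#' `n_bits` bits. The SMILES is canonicalized by the underlying toolkit, so
#' different spellings of one molecule (e.g. `"CCO"` and `"OCC"`) yield
#' identical fingerprints. Defaults follow the model's featurization: radius
#' 2, 1024 bits.
#'
#' @param smiles a single SMILES string.
#' @param radius circular radius (number of bond-neighborhood iterations).
#' @param n_bits folded fingerprint length.
#' @return integer 0/1 vector of length `n_bits`, class `drug_fingerprint`,
#'   with attributes `radius` and `source_smiles`.
#' @examples
#' fp <- ecfp_fingerprint("CCO")
#' sum(fp)  # number of on bits
#' @export
ecfp_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- ecfp_fingerprints(smiles, radius = radius, n_bits = n_bits)
  structure(as.integer(m[1L, ]), class = "drug_fingerprint",
            radius = as.integer(radius), source_smiles = smiles)
}

#' ECFP fingerprints for a vector of molecules
#'
#' Vectorized form of [ecfp_fingerprint()]; one batched toolkit call, one row
#' per molecule.
#'
#' @inheritParams ecfp_fingerprint
#' @param smiles character vector of SMILES strings.
#' @return integer 0/1 matrix, `length(smiles)` x `n_bits`.
#' @export
ecfp_fingerprints <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            radius >= 0L, n_bits >= 1L)
  mols <- parse_smiles(smiles)
  # OpenBabel names ECFPs by diameter (ECFP_{2*radius}) and emits 4096 bits
  raw <- ChemmineOB::fingerprint_OB(mols, sprintf("ECFP%d", 2L * as.integer(radius)))
  raw <- matrix(as.integer(raw > 0), nrow = length(smiles))
  out <- matrix(0L, length(smiles), n_bits)
  for (block in seq_len(ceiling(ncol(raw) / n_bits))) {
    cols <- ((block - 1L) * n_bits + 1L):min(block * n_bits, ncol(raw))
    out[, seq_along(cols)] <- pmax(out[, seq_along(cols), drop = FALSE],
                                   raw[, cols, drop = FALSE])
  }
  out
}

#' One-hot encode a protein sequence
#'
#' Prepends the `"?"` marker, label-encodes each character against the frozen
#' 26-symbol vocabulary and one-hot expands to a `max_len` x 26 binary
#' matrix. Sequences shorter than `max_len` are zero-padded below; longer
#' sequences keep the marker plus the first `max_len - 1` residues.
#'
#' @param sequence a single non-empty amino-acid string (case-insensitive).
#' @param max_len number of rows of the encoding (default 1000).
#' @return integer 0/1 matrix, `max_len` x 26, class `protein_encoding`, with
#'   attribute `true_length` = number of encoded rows (marker included).
#' @examples
#' enc <- encode_protein("MKV")
#' attr(enc, "true_length")  # 4: the marker plus three residues
#' @export
encode_protein <- function(sequence, max_len = 1000L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("protein sequence must be non-empty", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, .protein_vocab)
  idx[chars == "?"] <- NA  # "?" is reserved for the prepended marker
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("character '%s' at position %d is not in the protein vocabulary",
                 chars[bad], bad), call. = FALSE)
  }
  idx <- c(1L, idx)                       # prepended "?" marker
  if (length(idx) > max_len) idx <- idx[seq_len(max_len)]
  m <- matrix(0L, max_len, length(.protein_vocab),
              dimnames = list(NULL, .protein_vocab))
  m[cbind(seq_along(idx), idx)] <- 1L
  structure(m, class = c("protein_encoding", class(m)),
            true_length = length(idx))
}
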