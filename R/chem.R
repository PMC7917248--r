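#' @keywords internal
#' @useDynLib tripletDTA, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Characters that may appear in a SMILES string outside bracket atoms.
.smiles_plain_chars <- c(
  LETTERS, letters, as.character(0:9),
  "(", ")", "[", "]", "=", "#", "-", "+", "/", "\\", "%", ".", "@", ":", "*", "~"
)

#' Syntactic validation of SMILES strings
#'
#' OpenBabel (like most toolkits) recovers silently from some malformed
#' inputs, e.g. `"C("` parses as methane. This check rejects clearly broken
#' strings before any chemistry is attempted: unbalanced parentheses or
#' bracket atoms, unpaired ring-closure digits, a dangling bond symbol at the
#' end of the string, characters outside the SMILES alphabet, or an empty
#' string. It is a syntax layer, not a valence model: chemically absurd but
#' well-formed strings still pass here and are caught (if at all) at parse
#' time.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string is syntactically sound.
#'   Invalid entries carry the reason in the `"reasons"` attribute (a
#'   character vector aligned to the input, `NA` where valid).
#' @examples
#' smiles_is_valid(c("CCO", "C(", "c1ccccc1"))
#' @export
smiles_is_valid <- function(smiles) {
  stopifnot(is.character(smiles))
  reasons <- rep(NA_character_, length(smiles))
  ok <- rep(TRUE, length(smiles))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) {
      ok[i] <- FALSE; reasons[i] <- "empty SMILES"; next
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, .smiles_plain_chars)
    if (length(bad)) {
      ok[i] <- FALSE
      reasons[i] <- sprintf("character '%s' not allowed in SMILES", bad[1])
      next
    }
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0) {
      ok[i] <- FALSE; reasons[i] <- "unbalanced parentheses"; next
    }
    bdepth <- cumsum((chars == "[") - (chars == "]"))
    if (any(bdepth < 0 | bdepth > 1) || bdepth[length(bdepth)] != 0) {
      ok[i] <- FALSE; reasons[i] <- "unbalanced bracket atom"; next
    }
    # ring-closure digits: outside bracket atoms, each digit (or %nn pair)
    # must occur an even number of times
    plain <- gsub("\\[[^]]*\\]", "A", s)          # bracket atoms -> dummy atom
    two_digit <- regmatches(plain, gregexpr("%[0-9]{2}", plain))[[1]]
    plain_rest <- gsub("%[0-9]{2}", "", plain)
    digits <- regmatches(plain_rest, gregexpr("[0-9]", plain_rest))[[1]]
    counts <- table(c(digits, two_digit))
    if (length(counts) && any(counts %% 2 != 0)) {
      ok[i] <- FALSE; reasons[i] <- "unpaired ring-closure digit"; next
    }
    if (grepl("[=#/\\\\.+-]$", s)) {
      ok[i] <- FALSE; reasons[i] <- "dangling bond or separator at end"; next
    }
  }
  structure(ok, reasons = reasons)
}

# Stop with an informative error if any SMILES is syntactically invalid.
# `what` names the role of the offending entries in the message.
assert_smiles <- function(smiles, what = "SMILES") {
  ok <- smiles_is_valid(smiles)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf(
      "unparseable %s at position %d: '%s' (%s)",
      what, bad, smiles[bad], attr(ok, "reasons")[bad]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

# Parse a character vector of SMILES into OpenBabel molecule references.
# Validates syntax first so lenient recovery cannot slip through.
parse_smiles <- function(smiles, what = "SMILES") {
  assert_smiles(smiles, what = what)
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES via OpenBabel so that different spellings of the same
#' molecule (e.g. `"CCO"` and `"OCC"`) map to one representative string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  mols <- parse_smiles(smiles)
  props <- ChemmineOB::prop_OB(mols)
  as.character(props$cansmi)
}

#' Molecular weight of a molecule
#'
#' Standard average molecular weight (implicit hydrogens included) of the
#' molecule encoded by a SMILES string, in Daltons. Used by the repositioning
#' filter that removes low-weight molecules.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of molecular weights in Daltons.
#' @examples
#' molecular_weight("O")            # water, ~18.02
#' molecular_weight("[Na+].[Cl-]")  # sodium chloride, ~58.44
#' @export
molecular_weight <- function(smiles) {
  if (!length(smiles)) return(numeric())
  mols <- parse_smiles(smiles)
  props <- ChemmineOB::prop_OB(mols)
  as.numeric(props$MW)
}
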