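#' The twenty canonical amino-acid letters
#'
#' One-letter codes of the residues a common peptide may be composed of.
#' Ambiguity codes (B, J, O, U, X, Z) are not part of the motif alphabet.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.datatable.aware <- TRUE

KINGDOMS <- c("Bacteria", "Eukarya", "Archaea")
GROUPS <- c("Bacteria", "Eukarya", "Archaea", "Mitochondria")
ORGANELLES <- c("nuclear", "mito")

#' Analysis group of a sequence
#'
#' Mitochondrial sequences form a fourth group next to the three kingdoms of
#' life; a sequence's group is `"Mitochondria"` when its organelle flag is
#' `"mito"`, otherwise its kingdom.
#'
#' @param kingdom Character vector over Bacteria/Eukarya/Archaea.
#' @param organelle Character vector over nuclear/mito.
#' @return Character vector over the four analysis groups.
#' @export
analysis_group <- function(kingdom, organelle) {
  ifelse(organelle == "mito", "Mitochondria", kingdom)
}

# Add a `group` column to a records tibble.
add_group <- function(records) {
  dplyr::mutate(records, group = analysis_group(.data$kingdom, .data$organelle))
}

assert_records <- function(records, arg = "records") {
  need <- c("id", "family", "kingdom", "organelle", "residues")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg, paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(records$id)) {
    abort(sprintf("`%s` has duplicated sequence ids", arg))
  }
  invisible(records)
}

# Accept a CP set as a character vector or a tibble with a `motif` column.
as_motif_vector <- function(cps) {
  if (is.character(cps)) return(unique(cps))
  if (is.data.frame(cps) && "motif" %in% names(cps)) return(unique(cps$motif))
  abort("`cps` must be a character vector or a data frame with a `motif` column")
}

check_motif_alphabet <- function(motifs, what = "motif") {
  bad <- !stringi::stri_detect_regex(motifs, "^[ACDEFGHIKLMNPQRSTVWY]+$")
  if (any(bad)) {
    abort(sprintf("%s contains letters outside the 20-residue alphabet: %s",
                  what, paste(head(motifs[bad], 3), collapse = ", ")))
  }
  invisible(motifs)
}
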