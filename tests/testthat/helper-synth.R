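# Small corpus builders shared across tests.

records_tbl <- function(ids, residues, family = "F1", kingdom = "Bacteria",
                        organelle = "nuclear", taxon = NA_character_) {
  tibble::tibble(id = ids, family = family, kingdom = kingdom,
                 organelle = organelle, taxon = taxon, residues = residues)
}

random_residues <- function(n, len, seed = NULL) {
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(cpscan::aa_alphabet(), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a small two-class spec used by several planted-design tests
two_class_spec <- function(n_per_family = 20, motifs = list(), seed = 1,
                           n_I = 4, n_II = 4, ...) {
  fams <- tibble::tibble(
    label = c(sprintf("I%02d", seq_len(n_I)), sprintf("J%02d", seq_len(n_II))),
    class_label = rep(c("I", "II"), c(n_I, n_II)),
    n = n_per_family
  )
  cpscan::synth_spec(fams, motifs = motifs, seed = seed, ...)
}
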