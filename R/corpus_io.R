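#' Read and write the annotated FASTA dialect
#'
#' Headers carry the per-sequence metadata directly:
#' `>id|family|kingdom|organelle[|taxon]` with `kingdom` one of
#' Bacteria/Eukarya/Archaea, `organelle` one of nuclear/mito, and an optional
#' free-text taxon tag. The parse is order-preserving.
#'
#' Residues outside the 20-letter alphabet are rejected unless
#' `map_ambiguous = TRUE`, in which case B, J, O, U, X and Z are mapped to
#' `X`; `X` never takes part in motif matching.
#'
#' @param path FASTA file path.
#' @param map_ambiguous Map ambiguity codes to `X` instead of failing.
#' @return A tibble with columns `id`, `family`, `kingdom`, `organelle`,
#'   `taxon`, `residues`.
#' @export
read_corpus <- function(path, map_ambiguous = FALSE) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  seqs <- unname(toupper(as.character(set)))
  parts <- stringi::stri_split_fixed(headers, "|")
  recs <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) < 4 || length(p) > 5 || any(p[1:4] == "")) {
      abort(sprintf("record %d: header must be id|family|kingdom|organelle[|taxon]", i))
    }
    if (!p[3] %in% KINGDOMS) {
      abort(sprintf("record %d: unknown kingdom \"%s\"", i, p[3]))
    }
    if (!p[4] %in% ORGANELLES) {
      abort(sprintf("record %d: unknown organelle \"%s\"", i, p[4]))
    }
    s <- seqs[i]
    if (map_ambiguous) {
      s <- stringi::stri_replace_all_regex(s, "[BJOUZ]", "X")
    }
    if (!stringi::stri_detect_regex(s, if (map_ambiguous) "^[ACDEFGHIKLMNPQRSTVWYX]+$" else "^[ACDEFGHIKLMNPQRSTVWY]+$")) {
      abort(sprintf("record %d: residues outside the 20-letter alphabet (use map_ambiguous = TRUE to map to X)", i))
    }
    recs[[i]] <- tibble(id = p[1], family = p[2], kingdom = p[3],
                        organelle = p[4],
                        taxon = if (length(p) == 5) p[5] else NA_character_,
                        residues = s)
  }
  out <- bind_rows(recs)
  assert_records(out)
  out
}

#' @rdname read_corpus
#' @param records Sequence record tibble.
#' @param width Line-wrap width for residues.
#' @export
write_corpus <- function(records, path, width = 60) {
  assert_records(records)
  headers <- ifelse(
    is.na(records$taxon),
    paste(records$id, records$family, records$kingdom, records$organelle, sep = "|"),
    paste(records$id, records$family, records$kingdom, records$organelle,
          records$taxon, sep = "|")
  )
  set <- Biostrings::AAStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Alignment identity between two residue strings
#'
#' Identical columns of the best Smith-Waterman local alignment under
#' BLOSUM62 with gap open 11 and gap extension 1, divided by the length of
#' the shorter sequence. Normalizing by the shorter sequence (rather than by
#' aligned columns alone) keeps the measure meaningful for clustering: the
#' best local alignment between two unrelated sequences is a short
#' near-perfect match whose column-wise identity is close to 1, while its
#' shorter-sequence-normalized identity is close to 0. When no
#' positive-scoring local alignment exists the identity is 0.
#'
#' @param a,b Non-empty residue strings.
#' @return Fraction in `[0, 1]`; symmetric, and 1 for identical strings.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("`a` and `b` must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  w <- Biostrings::nchar(aln)
  if (w == 0 || Biostrings::score(aln) <= 0) return(0)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

# All-vs-all identity matrix for a set of sequences (named by id).
# One vectorized one-vs-rest alignment call per sequence.
identity_matrix <- function(records) {
  assert_records(records)
  n <- nrow(records)
  m <- diag(1, n)
  dimnames(m) <- list(records$id, records$id)
  if (n < 2) return(m)
  seqs <- records$residues
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[rest]), seqs[i], type = "local",
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1
    )
    w <- Biostrings::nchar(aln)
    short_len <- pmin(nchar(seqs[rest]), nchar(seqs[i]))
    ident <- ifelse(w == 0 | Biostrings::score(aln) <= 0, 0,
                    Biostrings::nmatch(aln) / short_len)
    m[i, rest] <- ident
    m[rest, i] <- ident
  }
  m
}

#' Redundancy reduction by single-linkage identity clustering
#'
#' Within each family, sequences with pairwise alignment identity at or above
#' the threshold are chained by single linkage into clusters of highly
#' similar proteins (different strains of one species, species of one genus).
#' One representative per cluster is chosen by maximal average identity to
#' the other members, ties broken by lexicographically smallest id, so the
#' result does not depend on record order.
#'
#' @param records Sequence record tibble.
#' @param threshold Identity threshold in `[0, 1]`, default 0.90.
#' @param identities Optional precomputed symmetric identity matrix with
#'   dimnames covering all record ids (otherwise computed per family).
#' @return A tibble with columns `family`, `cluster` (labelled by the
#'   lexicographically smallest member id), `id`, `representative`; the
#'   threshold is stored in the `identity_threshold` attribute. Keep only the
#'   representatives with [nonredundant()].
#' @export
reduce_redundancy <- function(records, threshold = 0.90, identities = NULL) {
  assert_records(records)
  if (nrow(records) < 1) abort("`records` must contain at least one sequence")
  out <- records %>%
    group_by(.data$family) %>%
    dplyr::group_modify(function(df, key) {
      df$family <- key$family
      cluster_family(df, threshold, identities)
    }) %>%
    ungroup() %>%
    select("family", "cluster", "id", "representative")
  attr(out, "identity_threshold") <- threshold
  out
}

cluster_family <- function(df, threshold, identities) {
  n <- nrow(df)
  ids <- df$id
  if (is.null(identities)) {
    m <- identity_matrix(df)
  } else {
    m <- identities[ids, ids, drop = FALSE]
  }
  g <- igraph::graph_from_adjacency_matrix(m >= threshold, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  tibble(id = ids, comp = comp) %>%
    group_by(.data$comp) %>%
    dplyr::group_modify(function(cl, key) {
      members <- cl$id
      if (length(members) == 1) {
        rep_id <- members
      } else {
        avg <- rowMeans(m[members, members, drop = FALSE]) -
          1 / length(members) # remove self-identity contribution
        best <- avg >= max(avg) - 1e-12
        rep_id <- min(members[best])
      }
      tibble(cluster = min(members), id = members,
             representative = members == rep_id)
    }) %>%
    ungroup() %>%
    select("cluster", "id", "representative")
}

#' Keep one representative sequence per redundancy cluster
#'
#' @param records Sequence record tibble.
#' @param clustering Result of [reduce_redundancy()].
#' @return The subset of `records` that are cluster representatives, in the
#'   original record order.
#' @export
nonredundant <- function(records, clustering) {
  semi_join(records, filter(clustering, .data$representative), by = "id")
}

#' Read and write site-annotation tables
#'
#' Tab-separated with columns `seq_id`, `position` (0-based residue index),
#' `site_type` (catalytic/binding), `ligand`, and optional `priority` (lower
#' value = higher priority, e.g. better structure resolution).
#'
#' @param path File path.
#' @param sites Site tibble.
#' @return `read_sites()` returns the site tibble.
#' @export
read_sites <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("seq_id", "site_type", "ligand"),
    integer = "position"
  ))
  out <- as_tibble(dt)
  if (!"priority" %in% names(out)) out$priority <- 1L
  out$priority <- as.integer(out$priority)
  out
}

#' @rdname read_sites
#' @export
write_sites <- function(sites, path) {
  data.table::fwrite(sites, path, sep = "\t", quote = FALSE)
  invisible(path)
}
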