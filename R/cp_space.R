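#' Unify per-family motif lists into a common-peptide set
#'
#' Takes the union of the per-family extractions, merges provenance of exact
#' duplicates, and removes every motif that strictly contains another motif
#' of the union as a substring, leaving an antichain under the substring
#' relation (the shortest informative strings are kept).
#'
#' @param motif_sets Named list (by family) of character vectors or tibbles
#'   with a `motif` column, e.g. from [extract_motifs_by_family()].
#' @return Tibble with columns `motif` and `source_families` (list column),
#'   sorted by motif.
#' @export
unify_and_prune <- function(motif_sets) {
  if (is.null(names(motif_sets)) || any(names(motif_sets) == "")) {
    abort("`motif_sets` must be a named list (one entry per family)")
  }
  long <- purrr::imap(motif_sets, function(x, fam) {
    tibble(motif = as_motif_vector(x), family = fam)
  }) %>% bind_rows()
  if (nrow(long) == 0) {
    return(tibble(motif = character(), source_families = list()))
  }
  if (any(nchar(long$motif) < 5)) abort("motifs must have length >= 5")
  cps <- long %>%
    group_by(.data$motif) %>%
    summarise(source_families = list(sort(unique(.data$family)))) %>%
    arrange(.data$motif)

  keep <- !strictly_contains_any(cps$motif)
  cps[keep, ]
}

# TRUE for strings that strictly contain another member of `motifs`.
strictly_contains_any <- function(motifs) {
  ord <- order(nchar(motifs))
  sorted <- motifs[ord]
  out <- logical(length(motifs))
  for (i in seq_along(sorted)) {
    m <- sorted[i]
    shorter <- sorted[nchar(sorted) < nchar(m)]
    if (length(shorter) > 0 &&
        any(stringi::stri_detect_fixed(m, shorter))) {
      out[ord[i]] <- TRUE
    }
  }
  out
}

#' Read and write CP list files
#'
#' Tab-separated, two columns: the motif and a comma-separated list of the
#' families whose extraction produced it.
#'
#' @param cps CP tibble from [unify_and_prune()].
#' @param path File path.
#' @return `read_cps()` returns the CP tibble.
#' @export
write_cps <- function(cps, path) {
  out <- tibble(
    motif = cps$motif,
    source_families = vapply(cps$source_families, paste, character(1),
                             collapse = ",")
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_cps
#' @export
read_cps <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("motif", "source_families")))
  tibble(motif = dt$motif,
         source_families = stringi::stri_split_fixed(dt$source_families, ","))
}

#' Locate all occurrences of common peptides on all sequences
#'
#' Every CP is searched on every sequence, including families other than the
#' one it was extracted from. Overlapping occurrences (of one CP with itself
#' and of distinct CPs) are all reported. Spans are 0-based, half-open.
#'
#' @param cps Character vector of motifs or tibble with a `motif` column.
#' @param records Sequence record tibble.
#' @return Hit tibble with columns `seq_id`, `motif`, `start`, `end`, ordered
#'   by sequence then position; invariant to CP and sequence input order.
#' @export
locate_hits <- function(cps, records) {
  assert_records(records)
  motifs <- sort(as_motif_vector(cps))
  rows <- vector("list", length(motifs))
  for (k in seq_along(motifs)) {
    loc <- stringi::stri_locate_all_fixed(records$residues, motifs[k],
                                          overlap = TRUE)
    nhit <- vapply(loc, function(x) sum(!is.na(x[, 1])), integer(1))
    if (sum(nhit) == 0) next
    starts <- unlist(lapply(loc[nhit > 0], function(x) x[, 1]),
                     use.names = FALSE)
    rows[[k]] <- tibble(
      seq_id = rep(records$id[nhit > 0], nhit[nhit > 0]),
      motif = motifs[k],
      start = as.integer(starts) - 1L,
      end = as.integer(starts) - 1L + nchar(motifs[k])
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(seq_id = character(), motif = character(),
                  start = integer(), end = integer()))
  }
  out[order(match(out$seq_id, sort(unique(out$seq_id))), out$start, out$end,
            out$motif), ]
}

#' Merge overlapping hits into chained features
#'
#' On each sequence, hits are grouped into maximal chains in which
#' consecutive hits share at least one residue (book-ended adjacent hits do
#' not chain). A chain of one hit counts toward its solo CP feature; a chain
#' of two or more hits counts toward a merged feature identified globally by
#' the sequence substring spanning the chain's union interval, and none of
#' its constituent CPs receive a solo count there. Every hit is accounted
#' exactly once.
#'
#' @param hits Hit tibble from [locate_hits()].
#' @param records Sequence record tibble (source of the spanning substrings).
#' @return List with `features` (tibble `seq_id`, `feature`, `type`
#'   (`"cp"`/`"merged"`), `start`, `end`, `n_hits`) and `registry` (tibble
#'   `feature`, `type` of all distinct features observed).
#' @export
merge_overlaps <- function(hits, records) {
  assert_records(records)
  if (nrow(hits) == 0) {
    feats <- tibble(seq_id = character(), feature = character(),
                    type = character(), start = integer(), end = integer(),
                    n_hits = integer())
    return(list(features = feats,
                registry = tibble(feature = character(), type = character())))
  }
  seq_lookup <- setNames(records$residues, records$id)
  if (any(!hits$seq_id %in% records$id)) abort("hit on unknown seq_id")

  feats <- hits %>%
    arrange(.data$seq_id, .data$start, .data$end) %>%
    group_by(.data$seq_id) %>%
    mutate(chain = cumsum(.data$start >= cummax_lag_end(.data$end))) %>%
    group_by(.data$seq_id, .data$chain) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_hits = n(), solo_motif = .data$motif[1],
              .groups = "drop") %>%
    mutate(
      type = ifelse(.data$n_hits > 1, "merged", "cp"),
      feature = ifelse(
        .data$n_hits > 1,
        stringi::stri_sub(seq_lookup[.data$seq_id], .data$start + 1L,
                          .data$end),
        .data$solo_motif
      )
    ) %>%
    select("seq_id", "feature", "type", "start", "end", "n_hits")

  registry <- feats %>% distinct(.data$feature, .data$type) %>%
    arrange(.data$feature)
  if (anyDuplicated(registry$feature)) {
    # a merged span string could coincide with an existing CP string; keep
    # them apart by tagging the merged feature
    feats <- feats %>%
      mutate(feature = ifelse(
        .data$type == "merged" & .data$feature %in% registry$feature[registry$type == "cp"],
        paste0(.data$feature, "+"), .data$feature))
    registry <- feats %>% distinct(.data$feature, .data$type) %>%
      arrange(.data$feature)
  }
  list(features = feats, registry = registry)
}

# running "previous maximum end" per group; first hit starts a chain
cummax_lag_end <- function(end) {
  c(-1L, cummax(end)[-length(end)])
}

#' Family-by-feature occurrence matrix
#'
#' Cell (family, feature) is the total number of counted occurrences of the
#' feature on that family's sequences divided by the number of sequences of
#' the family, so families of different sizes are comparable.
#'
#' @param feature_hits `features` tibble from [merge_overlaps()].
#' @param records Sequence record tibble defining the family sizes.
#' @return A `cp_feature_matrix` object wrapping the dense numeric matrix
#'   (`$matrix`, families x features) and the feature registry (`$features`).
#' @export
build_feature_matrix <- function(feature_hits, records) {
  assert_records(records)
  if (any(!feature_hits$seq_id %in% records$id)) {
    abort("feature hit on unknown seq_id")
  }
  fam_sizes <- records %>% count(.data$family, name = "n_seq")
  long <- feature_hits %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    count(.data$family, .data$feature, name = "occ") %>%
    inner_join(fam_sizes, by = "family") %>%
    mutate(value = .data$occ / .data$n_seq)

  features <- sort(unique(feature_hits$feature))
  fams <- sort(unique(records$family))
  mat <- matrix(0, nrow = length(fams), ncol = length(features),
                dimnames = list(fams, features))
  mat[cbind(match(long$family, fams), match(long$feature, features))] <-
    long$value
  types <- feature_hits %>% distinct(.data$feature, .data$type)
  structure(
    list(matrix = mat,
         features = tibble(feature = features,
                           type = types$type[match(features, types$feature)]),
         family_sizes = fam_sizes),
    class = "cp_feature_matrix"
  )
}

#' @export
print.cp_feature_matrix <- function(x, ...) {
  cat(sprintf("<cp_feature_matrix> %d families x %d features (%d solo CPs, %d merged)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$features$type == "cp"), sum(x$features$type == "merged")))
  invisible(x)
}

#' @describeIn build_feature_matrix Long tibble (family, feature, type,
#'   value) of the non-zero cells.
#' @param x A `cp_feature_matrix`.
#' @param ... Unused.
#' @export
tidy.cp_feature_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE),
            .name_repair = "minimal") %>%
    setNames(c("family", "feature", "value")) %>%
    filter(.data$value > 0) %>%
    left_join(x$features, by = "feature") %>%
    select("family", "feature", "type", "value") %>%
    arrange(.data$family, .data$feature)
}

#' Run the common-peptide space pipeline
#'
#' Convenience wrapper chaining [locate_hits()], [merge_overlaps()] and
#' [build_feature_matrix()] for a fixed CP set on a corpus.
#'
#' @inheritParams locate_hits
#' @return List with `hits`, `features`, `registry`, `matrix`
#'   (a `cp_feature_matrix`).
#' @export
build_cp_space <- function(cps, records) {
  hits <- locate_hits(cps, records)
  merged <- merge_overlaps(hits, records)
  fm <- build_feature_matrix(merged$features, records)
  list(hits = hits, features = merged$features, registry = merged$registry,
       matrix = fm)
}
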