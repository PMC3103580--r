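#' Kingdom presence profiles of common peptides
#'
#' For each CP, presence (any hit) in each of the four analysis groups, plus
#' the evolutionary origin label implied by the three kingdoms of life
#' (mitochondria excluded from origin labelling).
#'
#' @param hits Hit tibble from [locate_hits()].
#' @param records Sequence record tibble.
#' @return Tibble with columns `motif`, one logical column per group, and
#'   `origin`.
#' @export
cp_kingdom_profiles <- function(hits, records) {
  assert_records(records)
  pres <- hits %>%
    inner_join(add_group(records) %>% select("id", "group"),
               by = c(seq_id = "id")) %>%
    distinct(.data$motif, .data$group) %>%
    mutate(present = TRUE) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "present",
                       values_fill = FALSE)
  for (g in GROUPS) if (!g %in% names(pres)) pres[[g]] <- FALSE
  pres$origin <- vapply(seq_len(nrow(pres)), function(i) {
    classify_origin(KINGDOMS[c(pres$Bacteria[i], pres$Eukarya[i],
                               pres$Archaea[i])])
  }, character(1))
  pres %>% select("motif", all_of(GROUPS), "origin") %>% arrange(.data$motif)
}

#' Evolutionary origin of a kingdom presence set
#'
#' Under a tree of life in which Bacteria is an outgroup of Archaea and
#' Eukarya, a CP's presence set over the three kingdoms maps to one origin
#' label: `ALL3` (all kingdoms), `AE` (the joint Archaea + Eukarya node),
#' `B_only` / `A_only` / `E_only` (single kingdoms), `BE` (Bacteria +
#' Eukarya, excluding Archaea), and `other` (the remaining combination,
#' Bacteria + Archaea).
#'
#' @param presence Character vector: the kingdoms (subset of
#'   Bacteria/Eukarya/Archaea) in which the CP occurs. A CP seen only in
#'   mitochondrial sequences has an empty presence set, which is an error.
#' @return One of `"ALL3"`, `"AE"`, `"B_only"`, `"A_only"`, `"E_only"`,
#'   `"BE"`, `"other"`.
#' @export
classify_origin <- function(presence) {
  presence <- unique(presence)
  if (length(presence) == 0) abort("empty presence set: CP has no kingdom hits")
  if (!all(presence %in% KINGDOMS)) abort("presence must be a subset of the three kingdoms")
  has <- KINGDOMS %in% presence # Bacteria, Eukarya, Archaea
  key <- paste(as.integer(has), collapse = "")
  switch(key,
         "111" = "ALL3",
         "011" = "AE",
         "100" = "B_only",
         "001" = "A_only",
         "010" = "E_only",
         "110" = "BE",
         "101" = "other",
         abort("unreachable presence combination"))
}

#' Per-kingdom CP statistics
#'
#' For each analysis group: how many sequences it holds, what fraction of
#' the full CP list is observed in it, and what fraction of the CPs observed
#' in it occur nowhere else.
#'
#' @inheritParams cp_kingdom_profiles
#' @return Tibble with one row per group: `group`, `n_sequences`,
#'   `n_cps`, `pct_cps`, `n_specific`, `pct_specific` (percent scale).
#' @export
kingdom_cp_stats <- function(hits, records) {
  prof <- cp_kingdom_profiles(hits, records)
  n_all <- dplyr::n_distinct(hits$motif)
  grp_sizes <- add_group(records) %>% count(.data$group, name = "n_sequences")
  purrr::map_dfr(GROUPS, function(g) {
    in_g <- prof[[g]]
    only_g <- in_g & rowSums(as.matrix(prof[setdiff(GROUPS, g)])) == 0
    tibble(
      group = g,
      n_sequences = sum(grp_sizes$n_sequences[grp_sizes$group == g]),
      n_cps = sum(in_g),
      pct_cps = if (n_all > 0) 100 * sum(in_g) / n_all else 0,
      n_specific = sum(only_g),
      pct_specific = if (sum(in_g) > 0) 100 * sum(only_g) / sum(in_g) else 0
    )
  })
}

#' Family- and kingdom-specific CP lists
#'
#' The CPs whose hits within a family's non-mitochondrial sequences fall
#' exclusively in one named kingdom. A CP may occur in other kingdoms on
#' other families and still qualify here: specificity is judged within the
#' family only.
#'
#' @inheritParams cp_kingdom_profiles
#' @param family Family label.
#' @param kingdom One of Bacteria/Eukarya/Archaea.
#' @return Character vector of motifs.
#' @export
family_kingdom_specific_cps <- function(hits, records, family, kingdom) {
  if (!kingdom %in% KINGDOMS) abort("`kingdom` must be one of the three kingdoms")
  if (!family %in% records$family) abort(sprintf("unknown family \"%s\"", family))
  fam_hits <- hits %>%
    inner_join(records %>% filter(.data$family == !!family,
                                  .data$organelle == "nuclear") %>%
                 select("id", "kingdom"),
               by = c(seq_id = "id"))
  fam_hits %>%
    group_by(.data$motif) %>%
    summarise(kingdoms = list(unique(.data$kingdom))) %>%
    filter(purrr::map_lgl(.data$kingdoms, ~ identical(.x, kingdom))) %>%
    pull("motif") %>%
    sort()
}

#' Mitochondrial enrichment of kingdom-specific CPs
#'
#' For each family with mitochondrial sequences and each kingdom, tests
#' whether the CPs hitting the family's mitochondrial sequences are enriched
#' in that family's kingdom-specific CP list. Urn (default `"nonmito"`
#' universe): the CPs hitting the family's non-mitochondrial sequences (N),
#' of which the kingdom-specific ones are successes (K); draw: the CPs
#' hitting the family's mitochondrial sequences that also occur on its
#' non-mitochondrial sequences (n), with k kingdom-specific. p is the
#' upper-tail hypergeometric probability; q is Benjamini-Hochberg adjusted
#' across the whole family x kingdom grid and a family is called enriched at
#' `q < fdr`.
#'
#' @inheritParams cp_kingdom_profiles
#' @param families Families to test; default all families with at least one
#'   mitochondrial sequence. Families without mitochondrial sequences are
#'   skipped and reported with `skipped = TRUE`.
#' @param fdr False-discovery-rate threshold; default 0.01.
#' @param universe `"nonmito"` (default, as described above) or `"all"`
#'   (urn = all CPs hitting the family anywhere, mitochondria included).
#' @return Tibble with one row per family x kingdom: `family`, `kingdom`,
#'   `N`, `K`, `n`, `k`, `p`, `q`, `enriched`, `skipped`.
#' @export
mito_enrichment <- function(hits, records, families = NULL, fdr = 0.01,
                            universe = c("nonmito", "all")) {
  universe <- match.arg(universe)
  assert_records(records)
  if (is.null(families)) families <- sort(unique(records$family))
  rec <- records %>% select("id", "family", "kingdom", "organelle")
  h <- hits %>% inner_join(rec, by = c(seq_id = "id"))

  rows <- list()
  for (f in families) {
    hf <- h %>% filter(.data$family == f)
    mito_cps <- hf %>% filter(.data$organelle == "mito") %>%
      distinct(.data$motif) %>% pull()
    has_mito <- any(rec$family == f & rec$organelle == "mito")
    nonmito_cps <- hf %>% filter(.data$organelle == "nuclear") %>%
      distinct(.data$motif) %>% pull()
    urn <- if (universe == "nonmito") nonmito_cps else
      unique(c(nonmito_cps, mito_cps))
    for (kg in KINGDOMS) {
      if (!has_mito) {
        rows[[length(rows) + 1]] <- tibble(
          family = f, kingdom = kg, N = NA_integer_, K = NA_integer_,
          n = NA_integer_, k = NA_integer_, p = NA_real_, skipped = TRUE)
        next
      }
      spec_cps <- family_kingdom_specific_cps(hits, records, f, kg)
      N <- length(urn)
      K <- length(intersect(spec_cps, urn))
      draw <- intersect(mito_cps, urn)
      n <- length(draw)
      k <- length(intersect(draw, spec_cps))
      p <- if (N == 0 || n == 0) 1 else
        phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        family = f, kingdom = kg, N = N, K = K, n = n, k = k, p = p,
        skipped = FALSE)
    }
  }
  out <- bind_rows(rows)
  out$q <- NA_real_
  tested <- !out$skipped
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out %>% mutate(enriched = !.data$skipped & .data$q < fdr) %>%
    select("family", "kingdom", "N", "K", "n", "k", "p", "q", "enriched",
           "skipped")
}

#' Class-signature CPs
#'
#' A CP is a signature of structural class X when it appears in at least
#' `min_families` families of class X while its other-class presence stays
#' marginal: at most `max_other_families` other-class families and
#' other-class occurrences at most `max(other_occ_abs, other_occ_frac *
#' total occurrences)`. CPs containing any stop-list string (known class
#' signatures such as KMSKS and HIGH) are excluded.
#'
#' @inheritParams cp_kingdom_profiles
#' @param class_map Tibble with columns `family`, `class_label` covering
#'   every family in `records`.
#' @param min_families Minimum same-class family count; default 6.
#' @param max_other_families Maximum other-class family count; default 2.
#' @param other_occ_abs,other_occ_frac Skew tolerance on other-class
#'   occurrence counts; defaults 3 and 0.05.
#' @param stop_list Strings whose containment disqualifies a CP; default
#'   `c("KMSKS", "HIGH")`.
#' @return Tibble: `motif`, `preferred_class`, `n_families_I`, `n_occ_I`,
#'   `n_families_II`, `n_occ_II`.
#' @export
class_signatures <- function(hits, records, class_map, min_families = 6,
                             max_other_families = 2, other_occ_abs = 3,
                             other_occ_frac = 0.05,
                             stop_list = c("KMSKS", "HIGH")) {
  assert_records(records)
  class_map <- as_tibble(class_map)
  unlabelled <- setdiff(unique(records$family), class_map$family)
  if (length(unlabelled) > 0) {
    abort(sprintf("families without class label: %s",
                  paste(unlabelled, collapse = ", ")))
  }
  h <- hits %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    inner_join(class_map, by = "family")
  stats <- h %>%
    group_by(.data$motif) %>%
    summarise(
      n_families_I = n_distinct(.data$family[.data$class_label == "I"]),
      n_occ_I = sum(.data$class_label == "I"),
      n_families_II = n_distinct(.data$family[.data$class_label == "II"]),
      n_occ_II = sum(.data$class_label == "II")
    )
  if (length(stop_list) > 0) {
    banned <- purrr::map_lgl(stats$motif, function(m) {
      any(stringi::stri_detect_fixed(m, stop_list))
    })
    stats <- stats[!banned, ]
  }
  qualifies <- function(n_fam_x, occ_x, n_fam_o, occ_o) {
    n_fam_x >= min_families & n_fam_o <= max_other_families &
      occ_o <= pmax(other_occ_abs, other_occ_frac * (occ_x + occ_o))
  }
  stats %>%
    mutate(preferred_class = dplyr::case_when(
      qualifies(.data$n_families_I, .data$n_occ_I,
                .data$n_families_II, .data$n_occ_II) ~ "I",
      qualifies(.data$n_families_II, .data$n_occ_II,
                .data$n_families_I, .data$n_occ_I) ~ "II",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$preferred_class)) %>%
    select("motif", "preferred_class", "n_families_I", "n_occ_I",
           "n_families_II", "n_occ_II") %>%
    arrange(.data$preferred_class, .data$motif)
}

#' CPs exclusively shared by a family subset
#'
#' Finds the CPs hitting every family of the subset and no family outside
#' it, and contrasts the count with the exclusive-shared counts of every
#' other same-size subset of the same structural class (exhaustive
#' enumeration, e.g. all 210 quartets of a 10-family class).
#'
#' @inheritParams class_signatures
#' @param families Family subset (size >= 2, all of one class).
#' @param enumerate_null Also enumerate all same-size same-class subsets;
#'   default TRUE.
#' @return List with `cps` (character vector), `null` (tibble `subset`,
#'   `n_exclusive` for every enumerated subset) and `max_other` (largest
#'   count over subsets other than the query).
#' @export
exclusive_shared_cps <- function(hits, records, families, class_map,
                                 enumerate_null = TRUE) {
  if (length(families) < 2) abort("`families` must have at least 2 members")
  class_map <- as_tibble(class_map)
  cls <- class_map$class_label[match(families, class_map$family)]
  if (any(is.na(cls))) abort("subset contains a family without class label")
  if (length(unique(cls)) != 1) abort("subset families must all be of one class")

  # a CP is exclusive to a subset iff its full family set equals the subset
  fam_keys <- hits %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    distinct(.data$motif, .data$family) %>%
    group_by(.data$motif) %>%
    summarise(key = paste(sort(unique(.data$family)), collapse = "+"))
  excl_count <- function(subset) {
    fam_keys$motif[fam_keys$key == paste(sort(subset), collapse = "+")]
  }
  cps <- sort(excl_count(families))

  null <- NULL
  max_other <- NA_integer_
  if (enumerate_null) {
    same_class <- class_map$family[class_map$class_label == cls[1]]
    same_class <- intersect(same_class, unique(records$family))
    subs <- combn(sort(same_class), length(families), simplify = FALSE)
    null <- purrr::map_dfr(subs, function(s) {
      tibble(subset = paste(s, collapse = "+"),
             n_exclusive = length(excl_count(s)))
    })
    qkey <- paste(sort(families), collapse = "+")
    others <- null$n_exclusive[null$subset != qkey]
    max_other <- if (length(others) > 0) max(others) else 0L
  }
  list(cps = cps, null = null, max_other = max_other)
}
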