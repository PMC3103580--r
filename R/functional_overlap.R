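#' Prevalent common peptides
#'
#' A CP is prevalent when, in at least one family, strictly more than
#' `threshold` of the family's sequences contain at least one hit of it
#' (solo or absorbed into a merged chain — presence is judged on the raw hit
#' table). CPs containing a stop-list string (known catalytic-site
#' signatures) are removed.
#'
#' @param hits Hit tibble from [locate_hits()].
#' @param records Sequence record tibble.
#' @param threshold Prevalence fraction; strict inequality; default 0.5.
#' @param stop_list Disqualifying strings; default `c("KMSKS", "KLSKR")`.
#' @return Tibble `motif`, `best_family`, `best_fraction` of qualifying CPs.
#' @export
prevalent_cps <- function(hits, records, threshold = 0.5,
                          stop_list = c("KMSKS", "KLSKR")) {
  assert_records(records)
  fam_sizes <- records %>% count(.data$family, name = "n_seq")
  prev <- hits %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    distinct(.data$motif, .data$family, .data$seq_id) %>%
    count(.data$motif, .data$family, name = "n_with") %>%
    inner_join(fam_sizes, by = "family") %>%
    mutate(fraction = .data$n_with / .data$n_seq) %>%
    group_by(.data$motif) %>%
    slice(which.max(.data$fraction)) %>%
    ungroup() %>%
    filter(.data$fraction > threshold) %>%
    rename(best_family = "family", best_fraction = "fraction") %>%
    select("motif", "best_family", "best_fraction")
  if (length(stop_list) > 0 && nrow(prev) > 0) {
    banned <- purrr::map_lgl(prev$motif, function(m) {
      any(stringi::stri_detect_fixed(m, stop_list))
    })
    prev <- prev[!banned, ]
  }
  arrange(prev, .data$motif)
}

# residues strictly between a position and a half-open span (0 if inside)
span_site_gap <- function(start, end, pos) {
  ifelse(pos >= start & pos < end, 0L,
         ifelse(pos >= end, pos - end, start - pos - 1L))
}

#' Overlap of CP hits with annotated functional sites
#'
#' For every CP hitting an annotated sequence, the minimal residue distance
#' between any of its hits and any site: 0 with the site inside the hit span
#' counts as `exact`; a gap of at most `max_dist` residues as `vicinity`;
#' anything farther as `none`. When several annotated sequences exist per
#' family, only those with the best (numerically smallest) `priority` are
#' used, mirroring the use of a single best-resolution structure per family.
#'
#' @inheritParams prevalent_cps
#' @param sites Site tibble (`seq_id`, `position`, `site_type`, `ligand`,
#'   optional `priority`).
#' @param max_dist Vicinity threshold in residues; default 3.
#' @return Tibble `motif`, `distance` (0 when exact), `exact`,
#'   `classification`; one row per CP that hits at least one selected
#'   annotated sequence.
#' @export
site_overlap <- function(hits, sites, records, max_dist = 3) {
  assert_records(records)
  if (any(!sites$seq_id %in% records$id)) {
    abort(sprintf("site on unknown sequence: %s",
                  setdiff(sites$seq_id, records$id)[1]))
  }
  if (!"priority" %in% names(sites)) sites$priority <- 1L
  keep <- sites %>%
    inner_join(select(records, "id", "family"), by = c(seq_id = "id")) %>%
    group_by(.data$family) %>%
    filter(.data$priority == min(.data$priority)) %>%
    ungroup()
  pairs <- hits %>%
    inner_join(select(keep, "seq_id", "position"), by = "seq_id",
               relationship = "many-to-many") %>%
    mutate(gap = span_site_gap(.data$start, .data$end, .data$position),
           inside = .data$position >= .data$start & .data$position < .data$end)
  if (nrow(pairs) == 0) {
    return(tibble(motif = character(), distance = integer(), exact = logical(),
                  classification = character()))
  }
  pairs %>%
    group_by(.data$motif) %>%
    summarise(distance = min(.data$gap), exact = any(.data$inside)) %>%
    mutate(classification = dplyr::case_when(
      .data$exact ~ "exact",
      .data$distance <= max_dist ~ "vicinity",
      TRUE ~ "none"
    )) %>%
    arrange(.data$motif)
}

#' Hypergeometric significance of site overlap among prevalent CPs
#'
#' Urn: all CPs hitting at least one selected annotated sequence (N), with
#' the exact-overlap ones as successes (K). Draw: the prevalent CPs present
#' in the urn (n), with k exact among them; p is the upper-tail
#' hypergeometric probability. A second test counts exact-or-vicinity CPs
#' as successes.
#'
#' @param prevalent Prevalent CP tibble (or character vector of motifs).
#' @param report Overlap report from [site_overlap()] computed on all CPs.
#' @return Tibble with rows `exact` and `vicinity`: `test`, `N`, `K`, `n`,
#'   `k`, `p`.
#' @export
overlap_significance <- function(prevalent, report) {
  prev <- as_motif_vector(prevalent)
  if (nrow(report) == 0) abort("empty urn: no CP hits an annotated sequence")
  drawn <- report$motif %in% prev
  one_test <- function(success, label) {
    N <- nrow(report)
    K <- sum(success)
    n <- sum(drawn)
    k <- sum(success & drawn)
    p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(test = label, N = N, K = K, n = n, k = k, p = p)
  }
  bind_rows(
    one_test(report$classification == "exact", "exact"),
    one_test(report$classification %in% c("exact", "vicinity"), "vicinity")
  )
}

#' CPs shared between two protein-family corpora
#'
#' A CP of corpus A and a CP of corpus B are shared when their strings are
#' equal or one fully includes the other; the match string is the shorter of
#' the two. Shared matches are kept when the match string occurs in at least
#' `min_seqs` distinct sequences of each corpus. Equal-length match strings
#' one substitution apart are optionally grouped (Hamming-distance-1
#' clusters), flagging near-identical variants of one motif.
#'
#' @param cps_a,cps_b CP sets of the two corpora.
#' @param records_a,records_b The two sequence corpora (the prevalence
#'   filter counts sequences containing the match string, which may be a
#'   proper substring of either CP).
#' @param min_seqs Minimum distinct sequences per corpus; default 20.
#' @param hamming_groups Add a `group` column clustering match strings at
#'   Hamming distance 1; default TRUE.
#' @return Tibble `match`, `cp_a`, `cp_b`, `n_seqs_a`, `n_seqs_b`
#'   (one row per shared CP pair passing the filter), plus `group` when
#'   requested. Symmetric in the two corpora up to column naming.
#' @export
cross_family_shared <- function(cps_a, cps_b, records_a, records_b,
                                min_seqs = 20, hamming_groups = TRUE) {
  a <- as_motif_vector(cps_a)
  b <- as_motif_vector(cps_b)
  if (length(a) == 0 || length(b) == 0) {
    return(tibble(match = character(), cp_a = character(), cp_b = character(),
                  n_seqs_a = integer(), n_seqs_b = integer()))
  }
  pairs <- purrr::map_dfr(a, function(x) {
    hit <- stringi::stri_detect_fixed(b, x) | stringi::stri_detect_fixed(x, b)
    if (!any(hit)) return(NULL)
    tibble(cp_a = x, cp_b = b[hit])
  })
  if (nrow(pairs) == 0) {
    return(tibble(match = character(), cp_a = character(), cp_b = character(),
                  n_seqs_a = integer(), n_seqs_b = integer()))
  }
  pairs <- pairs %>%
    mutate(match = ifelse(nchar(.data$cp_a) <= nchar(.data$cp_b),
                          .data$cp_a, .data$cp_b))
  support <- function(m, recs) {
    sum(stringi::stri_detect_fixed(recs$residues, m))
  }
  uniq <- unique(pairs$match)
  supp_a <- vapply(uniq, support, integer(1), recs = records_a)
  supp_b <- vapply(uniq, support, integer(1), recs = records_b)
  pairs <- pairs %>%
    mutate(n_seqs_a = supp_a[.data$match], n_seqs_b = supp_b[.data$match]) %>%
    filter(.data$n_seqs_a >= min_seqs, .data$n_seqs_b >= min_seqs) %>%
    select("match", "cp_a", "cp_b", "n_seqs_a", "n_seqs_b") %>%
    arrange(.data$match, .data$cp_a, .data$cp_b)
  if (hamming_groups && nrow(pairs) > 0) {
    pairs$group <- hamming1_groups(pairs$match)
  }
  pairs
}

# connected components of the Hamming-distance-1 graph over equal-length strings
hamming1_groups <- function(strings) {
  uniq <- unique(strings)
  nu <- length(uniq)
  adj <- matrix(FALSE, nu, nu)
  if (nu > 1) {
    for (i in seq_len(nu - 1)) {
      for (j in (i + 1):nu) {
        if (nchar(uniq[i]) == nchar(uniq[j]) &&
            sum(strsplit(uniq[i], "")[[1]] != strsplit(uniq[j], "")[[1]]) == 1) {
          adj[i, j] <- adj[j, i] <- TRUE
        }
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable labels: smallest member string of each component
  labels <- vapply(split(uniq, comp), min, character(1))
  unname(labels[as.character(comp)][match(strings, uniq)])
}

#' Residue-shuffle control for motif extraction
#'
#' Each shuffle independently permutes the residues within every sequence
#' (length and composition conserved, all order destroyed), re-runs
#' [extract_motifs()], and records how many motifs were extracted and the
#' largest distinct-sequence support among them. On a corpus whose only
#' deterministic signal is real motifs, shuffled replicates should yield a
#' near-empty motif set.
#'
#' @param records Sequence record tibble.
#' @param n_shuffles Number of shuffled replicates; default 20.
#' @param params [mex_params()] for the extraction runs.
#' @param seed Integer seed; the control is deterministic given the seed.
#' @return Tibble `shuffle`, `n_motifs`, `max_support`.
#' @export
shuffle_control <- function(records, n_shuffles = 20, params = mex_params(),
                            seed = 1L) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_shuffles), function(s) {
      shuffled <- records
      shuffled$residues <- vapply(records$residues, function(x) {
        paste(sample(strsplit(x, "")[[1]]), collapse = "")
      }, character(1), USE.NAMES = FALSE)
      m <- extract_motifs(shuffled, params)
      tibble(shuffle = s, n_motifs = nrow(m),
             max_support = if (nrow(m) > 0) max(m$support) else 0L)
    })
  })
}
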