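#' Parameters of the motif-boundary detector
#'
#' The extractor walks candidate substrings and closes a motif where the
#' right (left) continuation probability drops sharply: the decline ratio
#' must fall below `eta` and a one-sided binomial test on the raw counts must
#' reject at level `alpha`. Candidates must be seen in at least `min_support`
#' distinct sequences and have length in `[l_min, l_max]`.
#'
#' @param eta Decline-ratio threshold in (0, 1); default 0.9.
#' @param alpha Significance level of the binomial boundary test; default 0.01.
#' @param l_min Minimum motif length; default 5.
#' @param l_max Maximum candidate length; default 30.
#' @param min_support Minimum number of distinct sequences containing the
#'   motif; default 3.
#' @return A `mex_params` list.
#' @export
mex_params <- function(eta = 0.9, alpha = 0.01, l_min = 5, l_max = 30,
                       min_support = 3) {
  if (!(eta > 0 && eta < 1)) abort("`eta` must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 0.5)) abort("`alpha` must lie in (0, 0.5)")
  if (!(l_min >= 5 && l_min <= l_max)) abort("need 5 <= l_min <= l_max")
  structure(list(eta = eta, alpha = alpha, l_min = as.integer(l_min),
                 l_max = as.integer(l_max),
                 min_support = as.integer(min_support)),
            class = "mex_params")
}

#' Count repeated substrings of a corpus
#'
#' Exact occurrence counts `count` (overlapping self-occurrences included)
#' and distinct-sequence support `support` for every substring of length up
#' to `l_max + 1` that occurs at least `min_count` times. Substrings
#' containing the ambiguity letter `X` are skipped: they can never become
#' motifs.
#'
#' @param records Sequence record tibble (or any data frame with `id` and
#'   `residues` columns).
#' @param l_max Maximum motif length; substrings up to `l_max + 1` are
#'   counted so that boundary extensions can be looked up.
#' @param min_count Minimum occurrence count retained; default 2.
#' @return A `data.table` keyed by `sub` with columns `sub`, `len`, `count`,
#'   `support`.
#' @export
count_substrings <- function(records, l_max = 30, min_count = 2) {
  if (nrow(records) == 0) abort("`records` must be non-empty")
  seqs <- records$residues
  seq_lens <- nchar(seqs)
  # iterative extension: a substring of length l+1 reaching min_count must
  # extend one of length l that did, so only those start positions survive
  starts <- data.table::data.table(
    seq_idx = rep(seq_along(seqs), seq_lens),
    from = unlist(lapply(seq_lens, seq_len), use.names = FALSE)
  )
  pieces <- vector("list", l_max + 1)
  for (l in seq_len(l_max + 1)) {
    keep <- starts$from + l - 1L <= seq_lens[starts$seq_idx]
    starts <- starts[keep, ]
    if (nrow(starts) == 0) break
    starts$sub <- stringi::stri_sub(seqs[starts$seq_idx], from = starts$from,
                                    length = l)
    counts <- starts[, list(count = .N, support = data.table::uniqueN(seq_idx)),
                     by = "sub"]
    counts <- counts[counts$count >= min_count, ]
    if (nrow(counts) == 0) break
    counts$len <- l
    pieces[[l]] <- counts
    starts <- starts[starts$sub %in% counts$sub, c("seq_idx", "from")]
  }
  out <- data.table::rbindlist(pieces)
  if (nrow(out) == 0) {
    out <- data.table::data.table(sub = character(), count = integer(),
                                  support = integer(), len = integer())
  }
  out <- out[!stringi::stri_detect_fixed(out$sub, "X"), ]
  data.table::setcolorder(out, c("sub", "len", "count", "support"))
  data.table::setkeyv(out, "sub")
  out[]
}

# Occurrence count lookup (0 when the substring fell under min_count).
lookup_counts <- function(counts, keys) {
  res <- counts[list(keys), on = "sub"]$count
  res[is.na(res)] <- 0L
  res
}

#' Extract deterministic motifs from a family corpus
#'
#' For a candidate string `a1..an`, the right-continuation probability at
#' position `i` is `p_R(i) = count(a1..ai) / count(a1..a(i-1))`. A right
#' boundary closes the candidate when the strongest one-residue extension
#' declines sharply: `p_R(n+1) / p_R(n) < eta` and a one-sided binomial test
#' (extension count successes out of `count(a1..an)` trials against rate
#' `eta * p_R(n)`) rejects at `alpha`. The left boundary applies the same
#' rule on reversed strings. A substring is emitted iff it has both
#' boundaries, length in `[l_min, l_max]`, and support of at least
#' `min_support` distinct sequences.
#'
#' Extraction is meant to run on a redundancy-reduced corpus
#' (see [reduce_redundancy()]); near-duplicate sequences inflate counts and
#' turn shared strain-level segments into spurious motifs.
#'
#' @param records Sequence record tibble.
#' @param params A [mex_params()] object.
#' @param counts Optional precomputed [count_substrings()] table.
#' @return Tibble with columns `motif`, `count`, `support`, sorted by motif;
#'   deterministic and duplicate-free.
#' @export
extract_motifs <- function(records, params = mex_params(), counts = NULL) {
  if (nrow(records) == 0) abort("`records` must be non-empty")
  if (is.null(counts)) counts <- count_substrings(records, params$l_max)
  cand <- counts[counts$len >= params$l_min & counts$len <= params$l_max &
                   counts$support >= params$min_support, ]
  if (nrow(cand) == 0) {
    return(tibble(motif = character(), count = integer(), support = integer()))
  }
  motifs <- cand$sub
  n <- nchar(motifs)
  cm <- cand$count

  c_pre <- lookup_counts(counts, stringi::stri_sub(motifs, 1, n - 1))
  c_suf <- lookup_counts(counts, stringi::stri_sub(motifs, 2, n))

  ext_max <- function(side) {
    best <- integer(length(motifs))
    for (aa in aa_alphabet()) {
      key <- if (side == "right") paste0(motifs, aa) else paste0(aa, motifs)
      best <- pmax(best, lookup_counts(counts, key))
    }
    best
  }
  ext_r <- ext_max("right")
  ext_l <- ext_max("left")

  boundary <- function(ext, c_adj) {
    p_here <- cm / c_adj
    p_next <- ext / cm
    decline <- p_next / p_here < params$eta
    pval <- pbinom(ext, cm, pmin(1, params$eta * p_here))
    decline & pval < params$alpha
  }
  keep <- boundary(ext_r, c_pre) & boundary(ext_l, c_suf)

  tibble(motif = motifs[keep], count = cm[keep],
         support = cand$support[keep]) %>%
    arrange(.data$motif)
}

#' Per-family motif extraction
#'
#' Runs [extract_motifs()] independently on each family of a corpus, the
#' per-family stage that precedes [unify_and_prune()].
#'
#' @inheritParams extract_motifs
#' @return Named list of per-family motif tibbles.
#' @export
extract_motifs_by_family <- function(records, params = mex_params()) {
  assert_records(records)
  fams <- unique(records$family)
  setNames(lapply(fams, function(f) {
    extract_motifs(filter(records, .data$family == f), params)
  }), fams)
}
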