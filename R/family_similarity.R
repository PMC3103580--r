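#' Pearson correlations between families in CP space
#'
#' Correlates every pair of family feature vectors (rows of the feature
#' matrix) across all features. A constant feature vector has no defined
#' correlation; such pairs are set to 0 with a warning.
#'
#' @param fm A `cp_feature_matrix` or a plain numeric matrix
#'   (families x features).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
family_correlations <- function(fm) {
  m <- feature_mat(fm)
  if (ncol(m) < 2) abort("need at least 2 features to correlate families")
  if (nrow(m) < 2) abort("need at least 2 families")
  constant <- apply(m, 1, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(cor(t(m)))
  if (any(constant)) {
    warn(sprintf("constant feature vector(s) for %s; correlations set to 0",
                 paste(rownames(m)[constant], collapse = ", ")))
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  diag(r) <- 1
  r
}

feature_mat <- function(fm) {
  if (inherits(fm, "cp_feature_matrix")) fm$matrix else as.matrix(fm)
}

#' Permutation null for family correlations
#'
#' Each shuffle independently permutes, for every feature, its per-family
#' values across families, conserving each feature's total; the off-diagonal
#' correlations of every shuffled matrix form the null sample.
#'
#' @inheritParams family_correlations
#' @param n_shuffles Number of shuffles; default 100.
#' @param seed Integer seed.
#' @param per_pair Keep per-pair null values (matrix pairs x shuffles)
#'   instead of pooling into one vector.
#' @return Numeric vector of pooled null correlations, or with
#'   `per_pair = TRUE` a matrix with one row per unordered family pair
#'   (rownames `"A|B"`).
#' @export
shuffle_null <- function(fm, n_shuffles = 100, seed = 1L, per_pair = FALSE) {
  m <- feature_mat(fm)
  nf <- nrow(m)
  ut <- upper.tri(matrix(0, nf, nf))
  pair_names <- outer(rownames(m), rownames(m), paste, sep = "|")[ut]
  withr::with_seed(seed, {
    draws <- lapply(seq_len(n_shuffles), function(i) {
      shuf <- apply(m, 2, sample)
      rownames(shuf) <- rownames(m)
      r <- suppressWarnings(cor(t(shuf)))
      r[is.na(r)] <- 0
      r[ut]
    })
  })
  null <- do.call(cbind, draws)
  rownames(null) <- pair_names
  if (per_pair) null else as.vector(null)
}

#' Significant family pairs against the permutation null
#'
#' The empirical p-value of a pair is `(1 + #null >= r) / (1 + #null)`
#' (add-one corrected so finite shuffles never give p = 0); pairs with
#' `p < p_cut` are retained.
#'
#' @param r Symmetric family correlation matrix.
#' @param null_samples Pooled null vector or per-pair null matrix from
#'   [shuffle_null()].
#' @param p_cut Retention threshold on the empirical p; default 0.01.
#' @return Tibble of all unordered pairs: `family1`, `family2`, `r`, `p`,
#'   `retained`.
#' @export
significant_pairs <- function(r, null_samples, p_cut = 0.01) {
  if (length(null_samples) == 0) abort("`null_samples` must be non-empty")
  nf <- nrow(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- tibble(
    family1 = rownames(r)[ut[, 1]],
    family2 = colnames(r)[ut[, 2]],
    r = r[ut]
  )
  if (is.matrix(null_samples)) {
    key <- paste(pairs$family1, pairs$family2, sep = "|")
    pairs$p <- vapply(seq_len(nrow(pairs)), function(i) {
      nv <- null_samples[key[i], ]
      (1 + sum(nv >= pairs$r[i])) / (1 + length(nv))
    }, numeric(1))
  } else {
    pairs$p <- vapply(pairs$r, function(x) {
      (1 + sum(null_samples >= x)) / (1 + length(null_samples))
    }, numeric(1))
  }
  pairs %>% mutate(retained = .data$p < p_cut) %>% arrange(.data$p)
}

#' Family similarity analysis in CP space
#'
#' End-to-end similarity analysis: build the CP space on the chosen
#' sequences, correlate families, draw the shuffle null, and retain
#' significant pairs. With `group` set, the whole pipeline (from hit
#' location onward) is re-run on that analysis group's sequences only;
#' families without sequences in the group are dropped and reported.
#'
#' @param records Sequence record tibble.
#' @param cps CP set (character vector or tibble with `motif`).
#' @param n_shuffles Number of null shuffles; default 100.
#' @param p_cut Empirical-p retention threshold; default 0.01.
#' @param seed Integer seed for the null.
#' @param group Optional analysis group
#'   (Bacteria/Eukarya/Archaea/Mitochondria).
#' @param exclude_families Families to drop before the analysis (e.g. tiny
#'   outlier families).
#' @param per_pair_null Use pair-specific nulls instead of one pooled null.
#' @return A `cp_similarity` object: `r`, `null_samples`, `pairs`,
#'   `n_shuffles`, `p_cut`, `seed`, `group`, `dropped_families`, `space`.
#' @export
family_similarity <- function(records, cps, n_shuffles = 100, p_cut = 0.01,
                              seed = 1L, group = NULL,
                              exclude_families = NULL,
                              per_pair_null = FALSE) {
  assert_records(records)
  dropped <- character(0)
  if (!is.null(exclude_families)) {
    records <- filter(records, !.data$family %in% exclude_families)
  }
  if (!is.null(group)) {
    if (!group %in% GROUPS) {
      abort(sprintf("unknown group \"%s\"; available: %s", group,
                    paste(GROUPS, collapse = ", ")))
    }
    sub <- records %>% add_group() %>% filter(.data$group == !!group) %>%
      select(-"group")
    if (nrow(sub) == 0) {
      avail <- unique(analysis_group(records$kingdom, records$organelle))
      abort(sprintf("no sequences in group \"%s\"; groups present: %s",
                    group, paste(sort(avail), collapse = ", ")))
    }
    dropped <- setdiff(unique(records$family), unique(sub$family))
    records <- sub
  }
  space <- build_cp_space(cps, records)
  r <- family_correlations(space$matrix)
  null <- shuffle_null(space$matrix, n_shuffles = n_shuffles, seed = seed,
                       per_pair = per_pair_null)
  pairs <- significant_pairs(r, null, p_cut = p_cut)
  structure(
    list(r = r, null_samples = null, pairs = pairs, n_shuffles = n_shuffles,
         p_cut = p_cut, seed = seed, group = group,
         dropped_families = dropped, space = space),
    class = "cp_similarity"
  )
}

#' @rdname family_similarity
#' @param ... Passed on to [family_similarity()].
#' @export
per_kingdom_similarity <- function(records, cps, group, ...) {
  family_similarity(records, cps, group = group, ...)
}

#' @export
print.cp_similarity <- function(x, ...) {
  cat(sprintf("<cp_similarity> %d families%s, %d shuffles, %d/%d pairs retained at p < %g\n",
              nrow(x$r),
              if (is.null(x$group)) "" else paste0(" (", x$group, ")"),
              x$n_shuffles, sum(x$pairs$retained), nrow(x$pairs), x$p_cut))
  if (length(x$dropped_families) > 0) {
    cat("dropped families:", paste(x$dropped_families, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn family_similarity One row per family pair with `r`, empirical
#'   `p` and the retention flag.
#' @param x A `cp_similarity` object.
#' @export
tidy.cp_similarity <- function(x, ...) {
  x$pairs
}

#' @describeIn family_similarity One-row summary of the analysis.
#' @export
glance.cp_similarity <- function(x, ...) {
  tibble(
    n_families = nrow(x$r),
    n_features = ncol(x$space$matrix$matrix),
    n_shuffles = x$n_shuffles,
    p_cut = x$p_cut,
    n_retained = sum(x$pairs$retained),
    group = if (is.null(x$group)) NA_character_ else x$group
  )
}

#' @describeIn family_similarity Correlation heat map with retained pairs
#'   outlined.
#' @param object A `cp_similarity` object.
#' @export
autoplot.cp_similarity <- function(object, ...) {
  df <- as.data.frame.table(object$r, stringsAsFactors = FALSE) %>%
    setNames(c("family1", "family2", "r")) %>%
    filter(.data$family1 != .data$family2)
  kept <- filter(object$pairs, .data$retained)
  kept <- bind_rows(kept, rename(kept, family1 = "family2", family2 = "family1"))
  ggplot2::ggplot(df, ggplot2::aes(.data$family1, .data$family2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = kept, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = if (is.null(object$group)) "Family similarity in CP space"
                  else sprintf("Family similarity in CP space (%s)", object$group)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
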