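# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the libraries standing behind them) so that agreement
# is evidence, not tautology.

# exact occurrence count of `sub` in `s`, overlapping occurrences included
naive_count_one <- function(s, sub) {
  L <- nchar(sub)
  n <- nchar(s)
  if (n < L) return(0L)
  sum(vapply(seq_len(n - L + 1L), function(i) {
    substr(s, i, i + L - 1L) == sub
  }, logical(1)))
}

# occurrence count and distinct-sequence support across a corpus
naive_counts <- function(seqs, sub) {
  per_seq <- vapply(seqs, naive_count_one, integer(1), sub = sub,
                    USE.NAMES = FALSE)
  list(count = sum(per_seq), support = sum(per_seq > 0))
}

# all substrings of all lengths up to l_max with their total counts
naive_substring_table <- function(seqs, l_max) {
  subs <- unlist(lapply(seqs, function(s) {
    unlist(lapply(seq_len(min(l_max, nchar(s))), function(l) {
      vapply(seq_len(nchar(s) - l + 1L), function(i) {
        substr(s, i, i + l - 1L)
      }, character(1))
    }))
  }), use.names = FALSE)
  table(subs)
}

# every occurrence of every pattern on every sequence, 0-based half-open
naive_locate <- function(patterns, ids, seqs) {
  rows <- list()
  for (p in patterns) {
    L <- nchar(p)
    for (j in seq_along(seqs)) {
      n <- nchar(seqs[j])
      if (n < L) next
      for (i in seq_len(n - L + 1L)) {
        if (substr(seqs[j], i, i + L - 1L) == p) {
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = ids[j], motif = p, start = i - 1L, end = i - 1L + L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), motif = character(),
                      start = integer(), end = integer())
  }
  out[order(out$seq_id, out$start, out$end, out$motif), , drop = FALSE]
}

# Gotoh local alignment (affine gaps) returning the identity fraction
# normalized by the shorter sequence; full O(nm) DP with traceback-free
# match counting via a parallel DP on match counts.
sw_identity_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  submat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)   # best local score ending at (i,j)
  E <- matrix(-Inf, n + 1, m + 1) # gap in a
  F <- matrix(-Inf, n + 1, m + 1) # gap in b
  MH <- matrix(0, n + 1, m + 1)  # identical columns along H's best path
  ME <- matrix(0, n + 1, m + 1)
  MF <- matrix(0, n + 1, m + 1)
  best <- 0; best_m <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
      ME[i, j] <- if (E[i, j] == H[i, j - 1] - gap_open - gap_ext)
        MH[i, j - 1] else ME[i, j - 1]
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
      MF[i, j] <- if (F[i, j] == H[i - 1, j] - gap_open - gap_ext)
        MH[i - 1, j] else MF[i - 1, j]
      diag_sc <- H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]]
      diag_m <- MH[i - 1, j - 1] + (A[i - 1] == B[j - 1])
      cand <- c(0, diag_sc, E[i, j], F[i, j])
      cand_m <- c(0, diag_m, ME[i, j], MF[i, j])
      k <- which.max(cand)
      H[i, j] <- cand[k]
      MH[i, j] <- cand_m[k]
      if (H[i, j] > best) { best <- H[i, j]; best_m <- MH[i, j] }
    }
  }
  if (best <= 0) return(0)
  best_m / min(n, m)
}

# connected components by breadth-first search over an adjacency matrix
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# textbook Pearson correlation from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

# upper-tail hypergeometric P(X >= k) by exhaustive enumeration of draws
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K) # label items 1..K as successes
  mean(succ >= k)
}

# maximal overlap chains of half-open intervals by transitive closure
chain_oracle <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] < end[j] & start[j] < end[i]
  })
  diag(adj) <- TRUE
  brute_components(adj)
}
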