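#' Describe a motif to plant in a synthetic corpus
#'
#' A planted motif is a deterministic residue string written verbatim into a
#' controlled fraction of the sequences of chosen families and analysis
#' groups. Planted motifs are the ground truth against which motif-extraction
#' recall is measured.
#'
#' @param motif Residue string, length >= 5, 20-letter alphabet.
#' @param families Character vector of target family labels.
#' @param kingdoms Character vector of target analysis groups
#'   (Bacteria/Eukarya/Archaea/Mitochondria). Default: all four.
#' @param insertion_prob Probability that an eligible sequence carries the
#'   motif, in `[0, 1]`.
#' @param position `"uniform"` (random offset) or `"fixed"` (constant offset).
#' @param offset 0-based start offset used when `position = "fixed"`.
#' @return A `planted_motif` list.
#' @export
planted_motif <- function(motif, families, kingdoms = GROUPS,
                          insertion_prob = 1, position = c("uniform", "fixed"),
                          offset = 0L) {
  position <- match.arg(position)
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) < 5) {
    abort("field `motif`: must be a single string of length >= 5")
  }
  check_motif_alphabet(motif, "field `motif`")
  if (length(families) == 0) abort("field `target_families`: must be non-empty")
  if (length(kingdoms) == 0 || !all(kingdoms %in% GROUPS)) {
    abort("field `target_kingdoms`: must be a non-empty subset of the four analysis groups")
  }
  if (insertion_prob < 0 || insertion_prob > 1) {
    abort("field `insertion_prob`: must lie in [0, 1]")
  }
  structure(
    list(motif = motif, families = unique(families), kingdoms = unique(kingdoms),
         insertion_prob = insertion_prob, position = position,
         offset = as.integer(offset)),
    class = "planted_motif"
  )
}

#' Specify a synthetic protein-family corpus
#'
#' Bundles everything the generator needs: family sizes and class labels, the
#' per-family mixture over the four analysis groups, near-duplicate clone
#' groups, the background residue distribution, planted motifs, and site
#' annotations co-located with planted motifs.
#'
#' The default group mixture mirrors a strongly bacterial corpus
#' (84% Bacteria, 11% Archaea, 3% Eukarya, 2% Mitochondria), the typical
#' composition of enzyme-family sequence collections.
#'
#' @param families Data frame with columns `label`, `class_label` (`"I"` or
#'   `"II"`), `n`, and optionally `length_mean` (default 300) and `length_sd`
#'   (default 0).
#' @param motifs List of [planted_motif()] objects.
#' @param kingdom_mix Named numeric vector over the four groups summing to 1,
#'   applied to every family, or a data frame with a `family` column plus the
#'   four group columns.
#' @param clone_groups Data frame with columns `family`, `size`,
#'   `mutation_rate`; each group is grown from one template by i.i.d.
#'   substitutions. The expected pairwise identity between members,
#'   `1 - 2m + m^2 + m^2/19` at mutation rate `m`, must be >= 0.9.
#' @param background_freqs Named numeric 20-vector of residue frequencies
#'   summing to 1; default uniform.
#' @param sites Data frame with columns `motif_index`, `offset` and optional
#'   `site_type`, `ligand`, `priority`: wherever motif `motif_index` is
#'   planted, a site annotation is emitted at (plant start + offset).
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(families, motifs = list(), kingdom_mix = NULL,
                       clone_groups = NULL, background_freqs = NULL,
                       sites = NULL, seed = 1L) {
  families <- as_tibble(families)
  need <- c("label", "class_label", "n")
  if (!all(need %in% names(families))) {
    abort("field `families`: needs columns label, class_label, n")
  }
  if (!"length_mean" %in% names(families)) families$length_mean <- 300
  if (!"length_sd" %in% names(families)) families$length_sd <- 0
  if (anyDuplicated(families$label)) abort("field `families`: duplicated labels")
  if (!all(families$class_label %in% c("I", "II"))) {
    abort("field `families`: class_label must be \"I\" or \"II\"")
  }

  if (is.null(kingdom_mix)) {
    kingdom_mix <- c(Bacteria = 0.84, Eukarya = 0.03, Archaea = 0.11,
                     Mitochondria = 0.02)
  }
  if (is.numeric(kingdom_mix)) {
    if (!setequal(names(kingdom_mix), GROUPS)) {
      abort("field `kingdom_mix`: must be named with the four analysis groups")
    }
    kingdom_mix <- tibble(family = families$label) %>%
      mutate(!!!as.list(kingdom_mix[GROUPS]))
  }
  kingdom_mix <- as_tibble(kingdom_mix)
  sums <- rowSums(kingdom_mix[GROUPS])
  if (any(abs(sums - 1) > 1e-8)) {
    abort("field `kingdom_mix`: proportions must sum to 1 for every family")
  }

  if (is.null(background_freqs)) {
    background_freqs <- setNames(rep(1 / 20, 20), aa_alphabet())
  }
  if (!setequal(names(background_freqs), aa_alphabet()) ||
      abs(sum(background_freqs) - 1) > 1e-8) {
    abort("field `background_freqs`: must be a named 20-vector summing to 1")
  }
  background_freqs <- background_freqs[aa_alphabet()]

  for (m in motifs) {
    if (!inherits(m, "planted_motif")) abort("field `motifs`: entries must be planted_motif objects")
    if (!all(m$families %in% families$label)) {
      abort(sprintf("field `motifs`: motif %s targets unknown family", m$motif))
    }
  }

  if (!is.null(clone_groups)) {
    clone_groups <- as_tibble(clone_groups)
    if (!all(c("family", "size", "mutation_rate") %in% names(clone_groups))) {
      abort("field `clone_groups`: needs columns family, size, mutation_rate")
    }
    mu <- clone_groups$mutation_rate
    exp_ident <- 1 - 2 * mu + mu^2 + mu^2 / 19
    if (any(mu > 0.1) || any(exp_ident < 0.9)) {
      abort("field `clone_groups`: mutation_rate must keep expected pairwise identity >= 0.9")
    }
  }

  if (!is.null(sites)) {
    sites <- as_tibble(sites)
    if (!all(c("motif_index", "offset") %in% names(sites))) {
      abort("field `sites`: needs columns motif_index, offset")
    }
    if (any(sites$motif_index < 1 | sites$motif_index > length(motifs))) {
      abort("field `sites`: motif_index out of range")
    }
    mlen <- vapply(motifs, function(m) nchar(m$motif), integer(1))
    if (any(sites$offset < 0 | sites$offset >= mlen[sites$motif_index])) {
      abort("field `sites`: offset outside its motif")
    }
    if (!"site_type" %in% names(sites)) sites$site_type <- "binding"
    if (!"ligand" %in% names(sites)) sites$ligand <- "planted"
    if (!"priority" %in% names(sites)) sites$priority <- 1L
  }

  max_motif <- if (length(motifs) > 0) {
    max(vapply(motifs, function(m) nchar(m$motif), integer(1)))
  } else 0L
  if (any(families$length_mean < max_motif + 10)) {
    abort("field `families`: length_mean must be >= longest motif + 10")
  }

  structure(
    list(families = families, motifs = motifs, kingdom_mix = kingdom_mix,
         clone_groups = clone_groups, background_freqs = background_freqs,
         sites = sites, seed = as.integer(seed), min_length = max_motif + 10L),
    class = "synth_spec"
  )
}

new_cp_truth <- function(occurrences, clones, sites) {
  structure(list(occurrences = occurrences, clones = clones, sites = sites),
            class = "cp_truth")
}

empty_truth_occurrences <- function() {
  tibble(seq_id = character(), start = integer(), end = integer(),
         motif = character(), seq_len = integer())
}

empty_truth_clones <- function() {
  tibble(family = character(), clone_group = integer(), seq_id = character())
}

empty_sites <- function() {
  tibble(seq_id = character(), position = integer(), site_type = character(),
         ligand = character(), priority = integer())
}

draw_background <- function(len, freqs) {
  sample(aa_alphabet(), len, replace = TRUE, prob = freqs)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Sequences are i.i.d. draws from the background residue distribution;
#' planted motifs overwrite background residues at their chosen offset, so
#' sequence lengths are untouched. Clone-group members are grown from a
#' single template by i.i.d. substitutions. Every planted occurrence, clone
#' membership and emitted site annotation is recorded in the truth object.
#'
#' Chance occurrences of a motif string in the background are possible and
#' are deliberately not recorded: only planted spans enter the truth.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `records` (sequence tibble), `truth`
#'   (`cp_truth` object), `sites` (site annotation tibble) and `class_map`
#'   (family -> class tibble).
#' @examples
#' sp <- synth_spec(
#'   families = tibble::tibble(label = "F1", class_label = "I", n = 5),
#'   motifs = list(planted_motif("KMSKS", "F1")),
#'   seed = 42
#' )
#' synth_generate(sp)$records
#' @export
synth_generate <- function(spec) {
  if (!inherits(spec, "synth_spec")) abort("`spec` must be a synth_spec object")
  withr::with_seed(spec$seed, generate_impl(spec))
}

generate_impl <- function(spec) {
  fam <- spec$families
  occ <- list()
  clo <- list()
  sit <- list()
  recs <- list()

  for (fi in seq_len(nrow(fam))) {
    f <- fam[fi, ]
    mix <- spec$kingdom_mix %>% filter(.data$family == f$label)
    probs <- as.numeric(mix[1, GROUPS])
    n <- f$n
    groups <- sample(GROUPS, n, replace = TRUE, prob = probs)
    lens <- pmax(spec$min_length,
                 as.integer(round(rnorm(n, f$length_mean, f$length_sd))))
    ids <- sprintf("%s_%04d", f$label, seq_len(n))
    chars <- lapply(lens, draw_background, freqs = spec$background_freqs)

    # clone groups claim leading index blocks of the family
    next_idx <- 1L
    if (!is.null(spec$clone_groups)) {
      cg <- spec$clone_groups %>% filter(.data$family == f$label)
      for (gi in seq_len(nrow(cg))) {
        g <- cg[gi, ]
        idx <- next_idx:(next_idx + g$size - 1L)
        if (max(idx) > n) abort("field `clone_groups`: group larger than family")
        next_idx <- next_idx + g$size
        template <- chars[[idx[1]]]
        lens[idx] <- length(template)
        for (j in idx) {
          mutated <- template
          hit <- which(stats::runif(length(template)) < g$mutation_rate)
          if (length(hit) > 0) {
            for (h in hit) {
              mutated[h] <- sample(setdiff(aa_alphabet(), template[h]), 1)
            }
          }
          chars[[j]] <- mutated
        }
        clo[[length(clo) + 1]] <- tibble(family = f$label, clone_group = gi,
                                         seq_id = ids[idx])
      }
    }

    # plant motifs, avoiding overlap between planted spans on one sequence
    for (si in seq_len(n)) {
      planted_spans <- integer(0) # occupied positions (1-based)
      for (mi in seq_along(spec$motifs)) {
        m <- spec$motifs[[mi]]
        if (!(f$label %in% m$families) || !(groups[si] %in% m$kingdoms)) next
        if (stats::runif(1) >= m$insertion_prob) next
        L <- nchar(m$motif)
        if (m$position == "fixed") {
          starts <- m$offset + 1L
          if (starts + L - 1L > lens[si]) next
          if (any((starts:(starts + L - 1L)) %in% planted_spans)) next
        } else {
          cand <- seq_len(lens[si] - L + 1L)
          if (length(planted_spans) > 0) {
            occupied <- vapply(cand, function(s) {
              any((s:(s + L - 1L)) %in% planted_spans)
            }, logical(1))
            cand <- cand[!occupied]
          }
          if (length(cand) == 0) next
          starts <- cand[sample.int(length(cand), 1)]
        }
        pos <- starts:(starts + L - 1L)
        chars[[si]][pos] <- strsplit(m$motif, "")[[1]]
        planted_spans <- c(planted_spans, pos)
        occ[[length(occ) + 1]] <- tibble(
          seq_id = ids[si], start = starts - 1L, end = starts + L - 1L,
          motif = m$motif, seq_len = lens[si]
        )
        if (!is.null(spec$sites)) {
          srows <- spec$sites %>% filter(.data$motif_index == mi)
          if (nrow(srows) > 0) {
            sit[[length(sit) + 1]] <- tibble(
              seq_id = ids[si],
              position = starts - 1L + as.integer(srows$offset),
              site_type = srows$site_type, ligand = srows$ligand,
              priority = as.integer(srows$priority)
            )
          }
        }
      }
    }

    recs[[fi]] <- tibble(
      id = ids, family = f$label,
      kingdom = ifelse(groups == "Mitochondria", "Eukarya", groups),
      organelle = ifelse(groups == "Mitochondria", "mito", "nuclear"),
      taxon = NA_character_,
      residues = vapply(chars, paste, character(1), collapse = "")
    )
  }

  records <- bind_rows(recs)
  truth <- new_cp_truth(
    occurrences = if (length(occ) > 0) bind_rows(occ) else empty_truth_occurrences(),
    clones = if (length(clo) > 0) bind_rows(clo) else empty_truth_clones(),
    sites = if (length(sit) > 0) bind_rows(sit) else empty_sites()
  )
  list(records = records, truth = truth, sites = truth$sites,
       class_map = tibble(family = fam$label, class_label = fam$class_label))
}

truth_columns <- c("type", "seq_id", "family", "clone_group", "motif",
                   "start", "end", "seq_len", "position", "site_type",
                   "ligand", "priority")

#' Write / read a ground-truth table
#'
#' The truth object (planted occurrences, clone memberships, site positions)
#' is serialized to one TSV with a `type` column; `read_truth()` restores it
#' and enforces the span invariants (spans within the sequence, motif length
#' equal to the span width).
#'
#' @param truth A `cp_truth` object as returned by [synth_generate()].
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns a
#'   `cp_truth` object.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "cp_truth"))
  occ <- truth$occurrences %>% mutate(type = "occurrence")
  clo <- truth$clones %>% mutate(type = "clone")
  sit <- truth$sites %>% mutate(type = "site")
  all <- bind_rows(occ, clo, sit)
  for (col in truth_columns) if (!col %in% names(all)) all[[col]] <- NA
  all <- all[truth_columns]
  data.table::fwrite(all, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(
                            character = c("type", "seq_id", "family", "motif",
                                          "site_type", "ligand"),
                            integer = c("clone_group", "start", "end",
                                        "seq_len", "position", "priority")
                          ))
  all <- as_tibble(dt)
  occ <- all %>% filter(.data$type == "occurrence") %>%
    select("seq_id", "start", "end", "motif", "seq_len")
  bad <- which(occ$start < 0 | occ$end > occ$seq_len | occ$start >= occ$end |
                 nchar(occ$motif) != occ$end - occ$start)
  if (length(bad) > 0) {
    abort(sprintf("truth row %d: span violates sequence bounds or motif length", bad[1]))
  }
  clo <- all %>% filter(.data$type == "clone") %>%
    select("family", "clone_group", "seq_id")
  sit <- all %>% filter(.data$type == "site") %>%
    select("seq_id", "position", "site_type", "ligand", "priority")
  if (nrow(occ) == 0) occ <- empty_truth_occurrences()
  if (nrow(clo) == 0) clo <- empty_truth_clones()
  if (nrow(sit) == 0) sit <- empty_sites()
  new_cp_truth(occ, clo, sit)
}
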