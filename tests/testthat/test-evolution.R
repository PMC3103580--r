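test_that("origin classification maps presence sets deterministically", {
  expect_equal(classify_origin(c("Bacteria", "Eukarya", "Archaea")), "ALL3")
  expect_equal(classify_origin(c("Archaea", "Eukarya")), "AE")
  expect_equal(classify_origin("Bacteria"), "B_only")
  expect_equal(classify_origin("Archaea"), "A_only")
  expect_equal(classify_origin("Eukarya"), "E_only")
  expect_equal(classify_origin(c("Bacteria", "Eukarya")), "BE")
  expect_equal(classify_origin(c("Bacteria", "Archaea")), "other")
  # pure function: repeated and re-ordered inputs give the same label
  expect_equal(classify_origin(c("Eukarya", "Archaea", "Archaea")), "AE")
  expect_error(classify_origin(character(0)), "empty")
  expect_error(classify_origin("Mitochondria"), "kingdoms")
})

test_that("kingdom statistics match a set-algebra recount", {
  withr::with_seed(3, {
    recs <- records_tbl(
      sprintf("s%02d", 1:12), random_residues(12, 40),
      family = rep(c("A", "B"), 6),
      kingdom = rep(c("Bacteria", "Eukarya", "Archaea"), each = 4),
      organelle = rep(c("nuclear", "nuclear", "nuclear", "mito"), 3)
    )
    cps <- substr(recs$residues[c(1, 2, 5, 9)], 4, 9)
  })
  hits <- locate_hits(cps, recs)
  stats <- kingdom_cp_stats(hits, recs)
  # independent recount using plain set algebra on the raw hit table
  grp <- cpscan::analysis_group(recs$kingdom, recs$organelle)
  names(grp) <- recs$id
  cp_groups <- split(grp[hits$seq_id], hits$motif)
  n_all <- length(cp_groups)
  for (g in c("Bacteria", "Eukarya", "Archaea", "Mitochondria")) {
    in_g <- vapply(cp_groups, function(x) g %in% x, logical(1))
    only_g <- vapply(cp_groups, function(x) all(x == g), logical(1))
    row <- stats[stats$group == g, ]
    expect_equal(row$n_cps, sum(in_g))
    expect_equal(row$pct_cps, 100 * sum(in_g) / n_all)
    expect_equal(row$n_specific, sum(only_g))
  }
})

test_that("a CP present everywhere is specific nowhere", {
  recs <- records_tbl(
    c("b", "e", "a", "m"), rep("WWKMSKSWW", 4),
    kingdom = c("Bacteria", "Eukarya", "Archaea", "Eukarya"),
    organelle = c("nuclear", "nuclear", "nuclear", "mito")
  )
  hits <- locate_hits("KMSKS", recs)
  stats <- kingdom_cp_stats(hits, recs)
  expect_equal(stats$pct_cps, rep(100, 4))
  expect_equal(stats$pct_specific, rep(0, 4))
})

test_that("family-kingdom-specific lists apply the within-family rule", {
  # the CP hits family F only in Bacteria, but also Archaea in family G:
  # still specific for (F, Bacteria)
  recs <- records_tbl(
    c("f1", "f2", "g1"), c("WKMSKSW", "WWWWWWW", "WKMSKSW"),
    family = c("F", "F", "G"),
    kingdom = c("Bacteria", "Eukarya", "Archaea")
  )
  hits <- locate_hits("KMSKS", recs)
  expect_equal(family_kingdom_specific_cps(hits, recs, "F", "Bacteria"),
               "KMSKS")
  expect_equal(family_kingdom_specific_cps(hits, recs, "G", "Bacteria"),
               character(0))
  expect_equal(family_kingdom_specific_cps(hits, recs, "G", "Archaea"),
               "KMSKS")

  # a CP hitting F in two kingdoms is excluded
  recs2 <- records_tbl(c("f1", "f2"), c("WKMSKSW", "WKMSKSW"),
                       family = "F", kingdom = c("Bacteria", "Eukarya"))
  hits2 <- locate_hits("KMSKS", recs2)
  expect_equal(family_kingdom_specific_cps(hits2, recs2, "F", "Bacteria"),
               character(0))

  # mitochondrial hits never contribute to kingdom-specific lists
  recs3 <- records_tbl(c("f1", "f2"), c("WKMSKSW", "WKMSKSW"),
                       family = "F", kingdom = c("Bacteria", "Eukarya"),
                       organelle = c("nuclear", "mito"))
  hits3 <- locate_hits("KMSKS", recs3)
  expect_equal(family_kingdom_specific_cps(hits3, recs3, "F", "Bacteria"),
               "KMSKS")
})

test_that("hypergeometric p matches direct evaluation and enumeration", {
  # N=10, K=5, n=4, k=4 -> C(5,4) C(5,0) / C(10,4) = 5/210
  p <- phyper(4 - 1, 5, 5, 4, lower.tail = FALSE)
  expect_equal(p, 5 / 210)
  expect_equal(p, hyper_enum_oracle(10, 5, 4, 4))
  # all-success urn drawn fully: upper-tail p = 1
  expect_equal(phyper(3 - 1, 3, 0, 3, lower.tail = FALSE), 1)
  # random instances with N <= 12 against exhaustive enumeration
  withr::with_seed(9, {
    for (i in 1:10) {
      N <- sample(4:12, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   hyper_enum_oracle(N, K, n, k), tolerance = 1e-12)
    }
  })
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27)
  # textbook: q_i = min over j >= i of p_(j) * m / j
  m <- length(p)
  ranked <- sort(p)
  q_manual <- rev(cummin(rev(ranked * m / seq_len(m))))[rank(p)]
  expect_equal(p.adjust(p, "BH"), q_manual)
})

test_that("degenerate all-success urns give p = 1 in the enrichment test", {
  recs <- records_tbl(
    c("n1", "n2", "m1"), rep("WKMSKSW", 3),
    family = "F", kingdom = "Bacteria",
    organelle = c("nuclear", "nuclear", "mito")
  )
  hits <- locate_hits("KMSKS", recs)
  enr <- mito_enrichment(hits, recs)
  bac <- enr[enr$kingdom == "Bacteria", ]
  expect_equal(bac$N, 1); expect_equal(bac$K, 1)
  expect_equal(bac$n, 1); expect_equal(bac$k, 1)
  expect_equal(bac$p, 1)
  expect_false(bac$enriched)
})

test_that("families without mitochondrial sequences are skipped with a report", {
  recs <- records_tbl(c("a", "b"), c("WKMSKSW", "WKMSKSW"),
                      family = "F", kingdom = "Bacteria")
  enr <- mito_enrichment(locate_hits("KMSKS", recs), recs)
  expect_true(all(enr$skipped))
  expect_true(all(is.na(enr$p)))
})

test_that("planted mitochondrial-Bacterial motifs give Bacteria enrichment only", {
  # family FM's mitochondrial sequences carry motifs otherwise specific to
  # its Bacteria sequences; a background of nonspecific motifs fills the urn
  bac_specific <- c("WHYKDECM", "CMKYWHDE", "EHWYCMKD", "KDCHWEYM",
                    "MYEWKCHD", "DWCHEKYM")
  everywhere <- c("HHWCYKDME", "YMHWDKCEH", "CEHYMKWDH", "WDHCEYMKH",
                  "KHWMYECDH", "EYDHWCKMH", "MHCKEYWDH", "DKYEWHMCH")
  fams <- tibble::tibble(label = c("FM", "FX"), class_label = "I", n = c(80, 40))
  mix <- tibble::tibble(family = c("FM", "FX"),
                        Bacteria = c(0.45, 0.5), Eukarya = c(0.25, 0.5),
                        Archaea = c(0.1, 0), Mitochondria = c(0.2, 0))
  motifs <- c(
    lapply(bac_specific, function(s) {
      planted_motif(s, "FM", kingdoms = c("Bacteria", "Mitochondria"),
                    insertion_prob = 0.9)
    }),
    lapply(everywhere, function(s) {
      # background CPs fill the urn but stay off the mitochondrial sequences
      planted_motif(s, c("FM", "FX"),
                    kingdoms = c("Bacteria", "Eukarya", "Archaea"),
                    insertion_prob = 0.6)
    })
  )
  sp <- synth_spec(fams, motifs = motifs, kingdom_mix = mix, seed = 53)
  g <- synth_generate(sp)
  cps <- unify_and_prune(extract_motifs_by_family(g$records))
  hits <- locate_hits(cps, g$records)
  enr <- mito_enrichment(hits, g$records)
  fm <- enr[enr$family == "FM", ]
  expect_true(fm$enriched[fm$kingdom == "Bacteria"])
  expect_lt(fm$q[fm$kingdom == "Bacteria"], 0.01)
  expect_false(fm$enriched[fm$kingdom == "Eukarya"])
})

test_that("enrichment p equals the combinatorial formula on its own counts", {
  sp <- two_class_spec(
    n_per_family = 30, n_I = 2, n_II = 0, seed = 57,
    kingdom_mix = c(Bacteria = 0.5, Eukarya = 0.3, Archaea = 0.1,
                    Mitochondria = 0.1),
    motifs = list(planted_motif("WKMSKSW", c("I01", "I02"),
                                insertion_prob = 0.7),
                  planted_motif("CHYDEKW", "I01", kingdoms = "Bacteria",
                                insertion_prob = 0.8))
  )
  g <- synth_generate(sp)
  cps <- unify_and_prune(extract_motifs_by_family(g$records))
  hits <- locate_hits(cps, g$records)
  enr <- mito_enrichment(hits, g$records)
  for (i in which(!enr$skipped)) {
    row <- enr[i, ]
    expect_equal(row$p, phyper(row$k - 1, row$K, row$N - row$K, row$n,
                               lower.tail = FALSE))
    expect_true(row$k <= min(row$K, row$n))
  }
})

test_that("class signatures require six same-class families and tolerate skew", {
  fams <- c(sprintf("I%d", 1:7), sprintf("J%d", 1:7))
  classes <- tibble::tibble(family = fams,
                            class_label = rep(c("I", "II"), each = 7))
  mk <- function(id, fam, seq) records_tbl(id, seq, family = fam)
  # signature CP present in 7 class-I families; one stray class-II hit
  recs <- dplyr::bind_rows(
    lapply(1:7, function(i) mk(sprintf("i%d", i), sprintf("I%d", i),
                               "WWACDEFWW")),
    mk("j1", "J1", "WWACDEFWW"),
    lapply(2:7, function(i) mk(sprintf("j%d", i), sprintf("J%d", i),
                               "WWMMMMMWW"))
  )
  hits <- locate_hits(c("ACDEF", "MMMMM"), recs)
  sig <- class_signatures(hits, recs, classes)
  expect_true("ACDEF" %in% sig$motif[sig$preferred_class == "I"])
  # MMMMM: 6 class-II families, 0 class-I -> class II signature
  expect_true("MMMMM" %in% sig$motif[sig$preferred_class == "II"])

  # balanced CP in 6 families of each class is no signature
  recs2 <- dplyr::bind_rows(
    lapply(1:6, function(i) mk(sprintf("bi%d", i), sprintf("I%d", i),
                               "WWHYDEKWW")),
    lapply(1:6, function(i) mk(sprintf("bj%d", i), sprintf("J%d", i),
                               "WWHYDEKWW"))
  )
  hits2 <- locate_hits("HYDEK", recs2)
  expect_equal(nrow(class_signatures(hits2, recs2, classes)), 0)

  # stop-list: CPs containing KMSKS or HIGH are never signatures
  recs3 <- dplyr::bind_rows(lapply(1:7, function(i) {
    mk(sprintf("s%d", i), sprintf("I%d", i), "WWKMSKSWW")
  }))
  hits3 <- locate_hits("WKMSKSW", recs3)
  expect_equal(nrow(class_signatures(hits3, recs3, classes)), 0)

  expect_error(class_signatures(hits, recs,
                                classes[classes$class_label == "I", ]),
               "without class label")
})

test_that("planted class-II-specific motifs are recovered as signatures", {
  sp <- two_class_spec(
    n_per_family = 15, n_I = 7, n_II = 7, seed = 67,
    motifs = list(planted_motif("YHWDECKM", sprintf("J%02d", 1:7),
                                insertion_prob = 0.8))
  )
  g <- synth_generate(sp)
  cps <- unify_and_prune(extract_motifs_by_family(g$records))
  hits <- locate_hits(cps, g$records)
  sig <- class_signatures(hits, g$records, g$class_map)
  expect_true(any(sig$preferred_class == "II" &
                    grepl("YHWDECKM", sig$motif, fixed = TRUE)))
})

test_that("exclusive shared CPs honour subset exclusivity", {
  mk <- function(id, fam, seq) records_tbl(id, seq, family = fam)
  recs <- dplyr::bind_rows(
    mk("a", "A", "WWACDEFWW"), mk("b", "B", "WWACDEFWW"),
    mk("c", "C", "WWACDEFWWHYDEK"), mk("d", "D", "WWWWWWWWW")
  )
  classes <- tibble::tibble(family = c("A", "B", "C", "D"),
                            class_label = "I")
  hits <- locate_hits(c("ACDEF", "HYDEK"), recs)
  # ACDEF hits A, B, C but not D: exclusive to {A,B,C}, not to {A,B,C,D}
  res <- exclusive_shared_cps(hits, recs, c("A", "B", "C"), classes)
  expect_equal(res$cps, "ACDEF")
  res2 <- exclusive_shared_cps(hits, recs, c("A", "B", "C", "D"), classes)
  expect_equal(res2$cps, character(0))
  # subset = all families hit: no exclusivity constraint binds for ACDEF
  expect_error(exclusive_shared_cps(hits, recs, "A", classes), "at least 2")
  expect_error(
    exclusive_shared_cps(hits, recs, c("A", "B"),
                         tibble::tibble(family = c("A", "B"),
                                        class_label = c("I", "II"))),
    "one class")
})

test_that("a planted exclusive quartet is returned exactly, beating all rivals", {
  quartet <- sprintf("I%02d", 1:4)
  excl <- c("WHYKDECM", "CMKYWHDE", "EHWYCMKD", "KDCHWEYM", "MYEWKCHD")
  sp <- two_class_spec(
    n_per_family = 15, n_I = 10, n_II = 0, seed = 71,
    motifs = lapply(excl, function(s) {
      planted_motif(s, quartet, insertion_prob = 0.9)
    })
  )
  g <- synth_generate(sp)
  cps <- unify_and_prune(extract_motifs_by_family(g$records))
  hits <- locate_hits(cps, g$records)
  res <- exclusive_shared_cps(hits, g$records, quartet, g$class_map)
  expect_setequal(res$cps, excl)
  expect_equal(nrow(res$null), choose(10, 4))
  expect_lt(res$max_other, length(excl))
})
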