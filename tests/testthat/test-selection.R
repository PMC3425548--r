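test_that("potential-site counting matches enumeration", {
  expect_equal(ng86_potential_sites("TTT")[["s"]], 1 / 3)
  expect_equal(ng86_potential_sites("TTA")[["s"]], 2 / 3)
  expect_error(ng86_potential_sites("TAA"), "sense")
  # partition s + n = 3 for every sense codon, and agreement with the
  # independent seqinr-based enumeration
  for (cod in genefamdiv:::sense_codons()) {
    sn <- ng86_potential_sites(cod)
    expect_equal(sn[["s"]] + sn[["n"]], 3)
    osn <- oracle_sites(cod)
    expect_equal(sn[["s"]], osn[["s"]], tolerance = 1e-12, info = cod)
  }
})

test_that("pairwise dN/dS matches pinned oracle values", {
  r0 <- pairwise_dn_ds("ATGAAATAG", "ATGAAATAG")
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0)
  expect_true(is.na(r0$ratio))

  # single nonsynonymous difference: ATG contributes n = 3, TTT/TTA
  # average to n = 2.5, so pN = 1/5.5 (biopython-verified dN)
  r1 <- pairwise_dn_ds("ATGTTTTAG", "ATGTTATAG")
  expect_equal(r1$Nd, 1); expect_equal(r1$Sd, 0)
  expect_equal(r1$pN, 1 / 5.5)
  expect_equal(r1$pS, 0)
  expect_equal(r1$dN, 0.20822380244870964, tolerance = 1e-12)

  # 30-codon pair frozen from an independent NG86 implementation
  a <- paste0("GGAACTAACGTTCACATTATGAGAGTTACGGGTGTTTTAGAGACCGCCCGT",
              "AAGAACACCATCATGGAAGCGAACGATATAGTCGGCGTA")
  b <- paste0("CGAACTAACGTTGACATTACGAGAGTTATGGGTGTTTTAGAGAAGGCCAGT",
              "AAGAACACCATCATGGAATCGAACGATATAGTCGGCGTT")
  r2 <- pairwise_dn_ds(paste0(a, "TAA"), paste0(b, "TAA"))
  expect_equal(r2$dN, 0.11651283001437178, tolerance = 1e-9)
  expect_equal(r2$dS, 0.07699061554506251, tolerance = 1e-9)
  expect_error(pairwise_dn_ds("ATGAAATAG", "ATGAAAAAATAG"), "equal length")
})

test_that("pathway-averaged counts equal the enumeration oracle", {
  # spot-check random multi-difference codon pairs (the full sweep over
  # all 1-3 difference pairs runs in the acceptance suite)
  tab <- genefamdiv:::ng86_tables()
  cods <- genefamdiv:::sense_codons()
  set.seed(43)
  for (r in 1:40) {
    pr <- sample(cods, 2)
    o <- oracle_pair_counts(pr[1], pr[2])
    expect_equal(tab$Nd[pr[1], pr[2]], o[["Nd"]], tolerance = 1e-12,
                 info = paste(pr, collapse = "/"))
    expect_equal(tab$Sd[pr[1], pr[2]], o[["Sd"]], tolerance = 1e-12,
                 info = paste(pr, collapse = "/"))
  }
})

test_that("global dN/dS flags degenerate alignments", {
  g <- global_dnds(rep("ATGAAATAG", 3))
  expect_true(g$undefined)
  expect_true(is.na(g$dnds))
})

test_that("global dN/dS recovers the simulated omega", {
  set.seed(47)
  est <- numeric(10)
  for (r in 1:10) {
    anc <- simulate_ancestor(300)
    m <- family_model(codon_count = 300, srs_positions = c(150),
                      omega_background = 0.5, omega_srs = 0.5,
                      locus_divergence = 0.15, n_loci = 6)
    loci <- vapply(1:6, function(i) as.character(evolve_locus(anc, m, i)),
                   character(1))
    est[r] <- global_dnds(loci)$dnds
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("estimated dN/dS increases with simulated omega", {
  set.seed(53)
  omegas <- c(0.1, 0.5, 1.0, 1.5, 2.0)
  res <- NULL
  for (om in omegas) for (r in 1:8) {
    anc <- simulate_ancestor(150)
    m <- family_model(codon_count = 150, srs_positions = c(75),
                      omega_background = om, omega_srs = om,
                      locus_divergence = 0.15, n_loci = 4)
    loci <- vapply(1:4, function(i) as.character(evolve_locus(anc, m, i)),
                   character(1))
    res <- rbind(res, c(om, global_dnds(loci)$dnds))
  }
  res <- res[!is.na(res[, 2]), ]
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.9)
})

test_that("codon z-test detects purifying selection and flags degeneracy", {
  zd <- codon_z_test(rep("ATGAAATAG", 3), n_bootstrap = 100)
  expect_true(zd$undefined)
  expect_error(codon_z_test(rep("ATGAAATAG", 3), n_bootstrap = 10),
               ">= 100")
  set.seed(59)
  hits <- 0
  for (r in 1:10) {
    anc <- simulate_ancestor(250)
    m <- family_model(codon_count = 250, srs_positions = c(125),
                      omega_background = 0.2, omega_srs = 0.2,
                      locus_divergence = 0.2, n_loci = 5)
    loci <- vapply(1:5, function(i) as.character(evolve_locus(anc, m, i)),
                   character(1))
    zt <- codon_z_test(loci, n_bootstrap = 300, seed = r)
    if (!zt$undefined && zt$Z > 0 && zt$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("codon z-test holds its size under neutrality", {
  set.seed(61)
  n_rep <- 200
  rej <- 0
  for (r in 1:n_rep) {
    anc <- simulate_ancestor(150)
    m <- family_model(codon_count = 150, srs_positions = c(75),
                      omega_background = 1, omega_srs = 1,
                      locus_divergence = 0.12, n_loci = 4)
    loci <- vapply(1:4, function(i) as.character(evolve_locus(anc, m, i)),
                   character(1))
    zt <- codon_z_test(loci, n_bootstrap = 150, seed = r)
    if (!zt$undefined && abs(zt$Z) > 1.96) rej <- rej + 1
  }
  rate <- rej / n_rep
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.105)
})

test_that("site scan classifies invariant columns and balances totals", {
  fam <- simulate_family(family_model(codon_count = 120, seed = 67,
                                      srs_positions = c(60),
                                      clones_per_animal = 3,
                                      animals_per_treatment = 2))
  prot <- translate_orf(fam$clones)
  tr <- midpoint_root(nj_tree(aa_distance(setNames(prot, fam$clones$id))))
  cols <- codon_columns(fam$clones)
  scan <- site_selection_scan(tr, cols)
  inv <- invariant_codon_count(cols)
  expect_equal(sum(scan$class == "invariant"), inv)
  expect_equal(sum(scan$class != "invariant"), 120 - inv)
  expect_true(all(scan$Nd >= 0 & scan$Sd >= 0))
  # invariant columns carry no observed change
  expect_true(all(scan$Nd[scan$class == "invariant"] == 0))
  expect_true(all(scan$Sd[scan$class == "invariant"] == 0))
  # potential-site partition per column
  expect_equal(scan$n + scan$s, rep(3, 120))
})

test_that("elevated omega at designated sites enriches positive calls", {
  set.seed(71)
  srs <- seq(10, 190, by = 10)
  anc <- simulate_ancestor(200)
  m <- family_model(codon_count = 200, srs_positions = srs,
                    omega_background = 0.2, omega_srs = 10,
                    locus_divergence = 0.12, n_loci = 30)
  seqs <- vapply(1:30, function(i) as.character(evolve_locus(anc, m, i)),
                 character(1))
  names(seqs) <- paste0("s", 1:30)
  tr <- midpoint_root(nj_tree(p_distance(seqs)))
  cols <- codon_columns(seqs, ids = names(seqs))
  scan <- site_selection_scan(tr, cols)
  in_srs <- scan$codon %in% srs
  pos <- scan$class == "positive"
  ft <- fisher.test(table(factor(in_srs, c(TRUE, FALSE)),
                          factor(pos, c(TRUE, FALSE))))
  expect_gt(mean(pos[in_srs]), mean(pos[!in_srs]))
  expect_lt(ft$p.value, 0.05)
})
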