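# build a 491-residue protein carrying a given residue tuple at the 13
# SRS positions over a fixed background
protein_with_srs <- function(tuple) {
  base <- strsplit(paste(rep("MKVLAGHESTQWND", 36), collapse = ""),
                   "")[[1]][1:491]
  base[srs_default_positions()] <- tuple
  paste(base, collapse = "")
}

clade_A <- c("I", "F", "M", "I", "S", "F", "A", "T", "A", "A", "I", "G", "V")
clade_A1 <- c("I", "F", "M", "I", "S", "L", "A", "T", "A", "A", "I", "G", "V")
clade_H <- c("V", "F", "I", "I", "S", "F", "A", "T", "I", "V", "F", "G", "V")

test_that("fingerprints read the published residue combinations", {
  fpA <- extract_fingerprint(protein_with_srs(clade_A))
  expect_equal(unname(fpA), clade_A)
  expect_equal(names(fpA), as.character(srs_default_positions()))
  fpH <- extract_fingerprint(protein_with_srs(clade_H))
  expect_equal(unname(fpH), clade_H)
  # A vs A1 differ only at residue 297 (F -> L)
  fpA1 <- extract_fingerprint(protein_with_srs(clade_A1))
  expect_equal(sum(fpA != fpA1), 1)
  expect_equal(unname(fpA["297"]), "F")
  expect_equal(unname(fpA1["297"]), "L")
  expect_error(extract_fingerprint("MKV", c(1, 5)), "beyond")
  expect_error(extract_fingerprint("MKVL", c(3, 2)), "increasing")
})

test_that("fingerprint grouping is exact and order-invariant", {
  prots <- c(a1 = protein_with_srs(clade_A), a2 = protein_with_srs(clade_A),
             h1 = protein_with_srs(clade_H), v1 = protein_with_srs(clade_A1))
  g <- group_by_fingerprint(prots)
  expect_length(g$members, 3)
  expect_setequal(g$members[["A"]], c("a1", "a2"))
  # permuted input: same partition (labels follow first appearance)
  g2 <- group_by_fingerprint(prots[c(3, 4, 1, 2)])
  part <- function(gr) unname(lapply(gr$members, sort))
  expect_setequal(part(g2), part(g))
  # all identical -> a single group
  expect_length(group_by_fingerprint(rep(prots[1], 4))$members, 1)
})

test_that("synthetic per-locus fingerprints coincide with truth loci", {
  fam <- simulate_family(family_model(seed = 73, locus_divergence = 0.06,
                                      clones_per_animal = 4))
  prot <- translate_orf(fam$clones)
  g <- group_by_fingerprint(prot, fam$clones$id)
  # the loci themselves must carry distinct fingerprints in this regime
  locus_fp <- vapply(fam$loci, function(l)
    paste(extract_fingerprint(translate_orf(l)), collapse = ""),
    character(1))
  expect_equal(length(unique(locus_fp)), 4)
  # clones with no injected change at an SRS codon carry their locus print
  srs_nt <- as.vector(outer(3 * (srs_default_positions() - 1), 1:3, `+`))
  touched <- vapply(seq_len(nrow(fam$truth)), function(i) {
    hit <- as.integer(unlist(strsplit(
      paste(fam$truth$allele_sites[i], fam$truth$error_sites[i], sep = ","),
      ",")))
    any(hit %in% srs_nt)
  }, logical(1))
  clean <- which(!touched)
  expect_gt(length(clean), 0)
  fp_clone <- g$table$fingerprint[match(fam$truth$id[clean], g$table$id)]
  expect_identical(fp_clone, unname(locus_fp[fam$truth$locus[clean]]))
})

test_that("clade concordance scores monophyly of fingerprint groups", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  groups <- list(A = c("a", "b"), B = c("c", "d"), C = c("e", "f"))
  expect_equal(clade_fingerprint_concordance(tr, groups), 1)
  scattered <- list(A = c("a", "c"), B = c("b", "e"))
  expect_equal(clade_fingerprint_concordance(tr, scattered), 0)
  # singletons excluded from the mean
  mixed <- list(A = c("a", "b"), B = "c", C = "d")
  expect_equal(clade_fingerprint_concordance(tr, mixed), 1)
  expect_true(is.na(clade_fingerprint_concordance(tr,
                                                  list(A = "a", B = "b"))))
})

test_that("perfectly locus-structured data reach full concordance", {
  fam <- simulate_family(family_model(seed = 79, locus_divergence = 0.08,
                                      allele_divergence = 0, error_rate = 0,
                                      clones_per_animal = 4))
  prot <- translate_orf(fam$clones)
  g <- group_by_fingerprint(prot, fam$clones$id)
  tr <- midpoint_root(nj_tree(aa_distance(setNames(prot, fam$clones$id))))
  # zero-noise clones equal their locus, so fingerprints = loci; if the
  # four loci have distinct prints, each group must be monophyletic
  locus_fp <- vapply(fam$loci, function(l)
    paste(extract_fingerprint(translate_orf(l)), collapse = ""),
    character(1))
  expect_equal(length(unique(locus_fp)), 4)
  expect_equal(clade_fingerprint_concordance(tr, g), 1)
})

test_that("Fisher p equals the hypergeometric oracle on random tables", {
  set.seed(83)
  for (r in 1:200) {
    tab <- as.numeric(rmultinom(1, sample(20:500, 1), runif(4, 0.05, 1)))
    p <- genefamdiv:::fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
    expect_equal(p, fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("SRS enrichment reproduces the published contrast", {
  e <- srs_enrichment(counts = c(21, 6, 181, 144))
  expect_equal(round(100 * e$srs_nonsyn_frac), 78)
  expect_equal(round(100 * e$background_nonsyn_frac), 56)
  expect_lt(e$p, 0.05)
  expect_false(e$haldane)
  expect_equal(e$odds_ratio, (21 * 144) / (6 * 181))
  # zero-cell handling
  e0 <- srs_enrichment(counts = c(5, 0, 10, 10))
  expect_true(e0$haldane)
  expect_equal(e0$odds_ratio, (5.5 * 10.5) / (0.5 * 10.5))
  eu <- srs_enrichment(counts = c(0, 0, 0, 0))
  expect_true(eu$undefined)
})

test_that("scan-based enrichment balances alignment-wide totals", {
  fam <- simulate_family(family_model(codon_count = 150, seed = 89,
                                      srs_positions = seq(10, 140, 10),
                                      clones_per_animal = 3,
                                      animals_per_treatment = 2))
  prot <- translate_orf(fam$clones)
  tr <- midpoint_root(nj_tree(aa_distance(setNames(prot, fam$clones$id))))
  scan <- site_selection_scan(tr, codon_columns(fam$clones))
  e <- srs_enrichment(scan, seq(10, 140, 10))
  expect_equal(sum(e$table), round(sum(scan$Nd[scan$codon %in% seq(10, 140, 10)])) +
                 round(sum(scan$Sd[scan$codon %in% seq(10, 140, 10)])) +
                 round(sum(scan$Nd[!scan$codon %in% seq(10, 140, 10)])) +
                 round(sum(scan$Sd[!scan$codon %in% seq(10, 140, 10)])))
})
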