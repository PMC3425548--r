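# small SRS set reused where the full 491-codon default is unnecessary
small_model <- function(...) {
  family_model(codon_count = 80, srs_positions = c(20, 40, 60),
               clones_per_animal = 2, animals_per_treatment = 1, ...)
}

test_that("ancestor simulation is deterministic with the stated length", {
  a1 <- simulate_ancestor(491, seed = 7)
  a2 <- simulate_ancestor(491, seed = 7)
  expect_identical(a1, a2)
  expect_equal(nchar(a1), 1476)
  expect_equal(genefamdiv:::orf_check(a1), "")
  expect_equal(nchar(simulate_ancestor(20, seed = 1)), 3 * 21)
  expect_error(simulate_ancestor(10), "codon_count")
})

test_that("identical models reproduce byte-identical clone sets", {
  f1 <- simulate_family(small_model(seed = 5))
  f2 <- simulate_family(small_model(seed = 5))
  expect_identical(f1$clones$nucleotides, f2$clones$nucleotides)
  expect_identical(f1$truth, f2$truth)
  f3 <- simulate_family(small_model(seed = 6))
  expect_false(identical(f1$clones$nucleotides, f3$clones$nucleotides))
})

test_that("every emitted clone is a valid ORF despite mutation and error", {
  fam <- simulate_family(family_model(codon_count = 60, seed = 2,
                                      srs_positions = c(5, 25),
                                      locus_divergence = 0.2,
                                      allele_divergence = 0.02,
                                      error_rate = 0.02,
                                      clones_per_animal = 3,
                                      animals_per_treatment = 2))
  expect_true(all(vapply(fam$clones$nucleotides,
                         genefamdiv:::orf_check, "") == ""))
  expect_equal(nrow(fam$truth), length(fam$clones$id))
  expect_true(all(fam$truth$locus %in% seq_len(4)))
})

test_that("omega 0 yields only synonymous accepted changes", {
  set.seed(1)
  anc <- simulate_ancestor(120)
  m <- family_model(codon_count = 120, srs_positions = c(50),
                    omega_background = 0, omega_srs = 0,
                    locus_divergence = 0.3)
  for (r in 1:5) {
    loc <- evolve_locus(anc, m)
    expect_identical(translate_orf(as.character(loc)), translate_orf(anc))
  }
})

test_that("acceptance of nonsynonymous proposals tracks omega", {
  set.seed(4)
  anc <- simulate_ancestor(400)
  m <- family_model(codon_count = 400, srs_positions = c(200),
                    omega_background = 0.5, omega_srs = 0.5,
                    locus_divergence = 3)       # ~1e4 proposals per run
  logs <- do.call(rbind, lapply(1:3, function(i)
    attr(evolve_locus(anc, m, log = TRUE), "proposals")))
  expect_gt(nrow(logs), 1e4)
  ns <- logs[!logs$synonymous, ]
  acc_rate <- mean(ns$accepted)
  expect_lt(abs(acc_rate - 0.5), 3 * sqrt(0.25 / nrow(ns)) + 0.01)
  expect_true(all(logs$accepted[logs$synonymous]))

  m1 <- family_model(codon_count = 400, srs_positions = c(200),
                     omega_background = 1, omega_srs = 1,
                     locus_divergence = 3)
  lg <- attr(evolve_locus(anc, m1, log = TRUE), "proposals")
  expect_equal(mean(lg$accepted[!lg$synonymous]), 1)
})

test_that("SRS codons accept nonsynonymous changes more readily", {
  set.seed(9)
  anc <- simulate_ancestor(300)
  m <- family_model(codon_count = 300, srs_positions = seq(10, 290, by = 10),
                    omega_background = 0.3, omega_srs = 5,
                    locus_divergence = 1.5)
  logs <- do.call(rbind, lapply(1:3, function(i)
    attr(evolve_locus(anc, m, log = TRUE), "proposals")))
  ns <- logs[!logs$synonymous, ]
  expect_gt(sum(ns$srs), 100)
  pt <- prop.test(c(sum(ns$accepted[ns$srs]), sum(ns$accepted[!ns$srs])),
                  c(sum(ns$srs), sum(!ns$srs)), alternative = "greater")
  expect_lt(pt$p.value, 0.01)
})

test_that("one-hot expression weights pin every clone to one locus", {
  w <- matrix(0, 4, 3, dimnames = list(treatment_levels(), NULL))
  w[, 1] <- 1
  m <- family_model(n_loci = 3, codon_count = 60, srs_positions = c(30),
                    expression_weights = w, clones_per_animal = 3,
                    animals_per_treatment = 1, seed = 8)
  fam <- simulate_family(m)
  expect_true(all(fam$truth$locus == 1))
})

test_that("zero allelic noise reproduces the source locus exactly", {
  m <- family_model(codon_count = 60, srs_positions = c(30),
                    allele_divergence = 0, error_rate = 0,
                    clones_per_animal = 2, animals_per_treatment = 1,
                    seed = 12)
  fam <- simulate_family(m)
  expect_identical(fam$clones$nucleotides,
                   unname(fam$loci[fam$truth$locus]))
})

test_that("written family round-trips through the FASTA convention", {
  fam <- simulate_family(small_model(seed = 21))
  dir <- tempfile()
  write_family(fam, dir)
  back <- read_coding_fasta(file.path(dir, "clones.fasta"))
  expect_identical(back$nucleotides, fam$clones$nucleotides)
  expect_identical(back$id, fam$clones$id)
  expect_identical(treatment_labels(back), fam$truth$treatment)
  expect_equal(nrow(attr(back, "excluded")), 0)
})

test_that("expression weight validation catches degenerate input", {
  w <- matrix(0.5, 4, 2, dimnames = list(treatment_levels(), NULL))
  expect_silent(family_model(n_loci = 2, expression_weights = w))
  w[1, ] <- c(0.7, 0.7)
  expect_error(family_model(n_loci = 2, expression_weights = w), "sum to 1")
  expect_error(family_model(n_loci = 2,
                            expression_weights = matrix(0.5, 3, 2)),
               "4 x n_loci")
})
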