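# Seeded simulator for multigene-family clone sets: divergent loci evolved
# from a common ancestor under a codon model with per-class omega, then
# treatment-biased sampling of clones with allelic and RT/PCR noise.

.stop_codons <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all, .stop_codons))
}

#' Specify a synthetic gene-family model
#'
#' Defaults emulate the expressed CYP2B family of the woodrat feeding
#' trial: four divergent loci (the four major clades), a 491-residue ORF,
#' purifying background selection (omega 0.5, near the observed global
#' dN/dS of 0.54), elevated nonsynonymous acceptance at the 13 substrate
#' recognition site codons, treatment-biased expression across the four
#' population-by-diet groups, ~8 clones per animal and 3 animals per
#' treatment (96 clones, close to the 87 of the study), and light
#' within-locus allelic plus RT/PCR substitution noise. The divergence
#' and noise rates are calibrated so a default dataset reproduces the
#' observed diversity summaries to first order: between-locus amino-acid
#' divergence around 8% (above the 5% dereplication threshold), overall
#' mean nucleotide p-distance near 0.03, and a minority of clones
#' recurring as exact duplicates.
#'
#' @param n_loci number of loci (>= 1).
#' @param codon_count translated length in residues (start codon included,
#'   stop excluded); nucleotide length is `3 * (codon_count + 1)`.
#' @param locus_divergence expected proposed substitutions per nucleotide
#'   site separating each locus from the family ancestor.
#' @param allele_divergence expected within-locus allelic substitutions per
#'   site applied to each sampled clone.
#' @param omega_background acceptance probability of a proposed
#'   nonsynonymous change at non-SRS codons (synonymous changes are always
#'   accepted), i.e. the simulated dN/dS.
#' @param omega_srs acceptance weight at SRS codons (values > 1 are
#'   truncated to certain acceptance).
#' @param srs_positions 1-based codon indices of the substrate recognition
#'   site residues.
#' @param expression_weights numeric matrix (4 treatments x `n_loci`) of
#'   per-treatment locus expression probabilities; rows must sum to 1.
#'   Row names must be the four treatment labels. Default mimics the
#'   observed clade structure: one locus expressed by all treatments and
#'   the other three each dominated by a different treatment.
#' @param clones_per_animal,animals_per_treatment sampling design.
#' @param error_rate per-nucleotide RT/PCR substitution probability.
#' @param seed integer seed; all randomness flows from one generator.
#' @return Object of class `family_model` (a validated parameter list).
#' @export
family_model <- function(n_loci = 4, codon_count = 491,
                         locus_divergence = 0.035,
                         allele_divergence = 5e-4,
                         omega_background = 0.5, omega_srs = 5,
                         srs_positions = srs_default_positions(),
                         expression_weights = NULL,
                         clones_per_animal = 8, animals_per_treatment = 3,
                         error_rate = 3e-4, seed = 1L) {
  stopifnot(n_loci >= 1, codon_count >= 20, locus_divergence >= 0,
            allele_divergence >= 0, omega_background >= 0, omega_srs >= 0,
            error_rate >= 0, clones_per_animal >= 1,
            animals_per_treatment >= 1)
  if (any(srs_positions < 1 | srs_positions > codon_count))
    stop("srs_positions outside codon range")
  if (is.null(expression_weights)) {
    expression_weights <- default_expression_weights(n_loci)
  }
  if (!is.matrix(expression_weights) ||
      nrow(expression_weights) != 4 ||
      ncol(expression_weights) != n_loci ||
      !identical(sort(rownames(expression_weights)),
                 sort(treatment_levels())))
    stop("expression_weights must be a 4 x n_loci matrix with the four ",
         "treatment labels as row names")
  if (any(expression_weights < 0) ||
      any(abs(rowSums(expression_weights) - 1) > 1e-8))
    stop("expression_weights rows must be non-negative and sum to 1")
  structure(list(n_loci = as.integer(n_loci),
                 codon_count = as.integer(codon_count),
                 locus_divergence = locus_divergence,
                 allele_divergence = allele_divergence,
                 omega_background = omega_background,
                 omega_srs = omega_srs,
                 srs_positions = as.integer(srs_positions),
                 expression_weights = expression_weights,
                 clones_per_animal = as.integer(clones_per_animal),
                 animals_per_treatment = as.integer(animals_per_treatment),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "family_model")
}

# one locus shared by every treatment, remaining loci each dominated by a
# different treatment (clade A vs clades F/G/H of the observed tree)
default_expression_weights <- function(n_loci) {
  trt <- treatment_levels()
  if (n_loci == 1) {
    w <- matrix(1, 4, 1)
  } else {
    w <- matrix(0.1 / (n_loci - 1), 4, n_loci)
    w[, 1] <- 0.35
    own <- 1 + (seq_len(4) - 1) %% (n_loci - 1) + 1
    for (t in 1:4) w[t, own[t]] <- w[t, own[t]] + 1 - 0.35 - 0.1
  }
  rownames(w) <- trt
  w / rowSums(w)
}

#' @export
print.family_model <- function(x, ...) {
  cat("family_model:", x$n_loci, "loci,", x$codon_count, "codons,",
      x$animals_per_treatment * 4 * x$clones_per_animal, "clones\n")
  cat("  locus divergence", x$locus_divergence,
      "| allele divergence", x$allele_divergence,
      "| error rate", x$error_rate, "\n")
  cat("  omega background", x$omega_background,
      "| omega SRS", x$omega_srs,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an ancestral open reading frame
#'
#' Uniform random sense codons with ATG prepended and a stop appended; a
#' `codon_count` of 491 yields the 1476-nt ORF length of the study system.
#'
#' @param codon_count translated length in residues (>= 20).
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (so the simulator's single global seed governs everything).
#' @return A single ORF nucleotide string of length `3 * (codon_count+1)`.
#' @export
simulate_ancestor <- function(codon_count, seed = NULL) {
  stopifnot(codon_count >= 20)
  if (!is.null(seed)) set.seed(seed)
  body <- sample(sense_codons(), codon_count - 1, replace = TRUE)
  stop_c <- sample(.stop_codons, 1)
  paste(c("ATG", body, stop_c), collapse = "")
}

# propose/accept substitution process shared by locus evolution and noise
# injection; keeps the ORF intact (start codon fixed, stops re-drawn).
# omega: acceptance probability per codon index; srs: codon indices flagged
# as substrate recognition sites in the proposal log.
mutate_orf <- function(nt, rate, omega, log = FALSE, srs = integer(0)) {
  cod <- codon_split(nt)
  n_cod <- length(cod) - 1L                     # stop codon immutable
  mutable <- 2:n_cod                            # ATG fixed too
  n_sites <- 3L * length(mutable)
  n_prop <- rpois(1, rate * n_sites)
  logs <- if (log) vector("list", n_prop) else NULL
  changed <- integer(0)
  bases <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  for (k in seq_len(n_prop)) {
    repeat {
      j <- sample(mutable, 1)
      pos <- sample.int(3, 1)
      old <- cod[j]
      nt_old <- substr(old, pos, pos)
      nt_new <- sample(setdiff(bases, nt_old), 1)
      new <- old
      substr(new, pos, pos) <- nt_new
      if (!(new %in% .stop_codons)) break       # re-draw stop proposals
    }
    syn <- code[[new]] == code[[old]]
    # acceptance ratio nonsyn:syn equals omega over the whole range:
    # omega <= 1 thins nonsynonymous proposals, omega > 1 thins
    # synonymous ones instead (so positive selection is expressible)
    p_acc <- if (syn) min(1, 1 / max(omega[j], .Machine$double.eps))
             else min(1, omega[j])
    acc <- runif(1) < p_acc
    if (acc) {
      cod[j] <- new
      changed <- c(changed, 3L * (j - 1L) + pos)
    }
    if (log)
      logs[[k]] <- data.frame(codon = j, pos = pos, from = old, to = new,
                              synonymous = syn, accepted = acc,
                              srs = j %in% srs,
                              stringsAsFactors = FALSE)
  }
  out <- paste(cod, collapse = "")
  attr(out, "changed_sites") <- sort(unique(changed))
  if (log)
    attr(out, "proposals") <- if (n_prop) do.call(rbind, logs) else
      data.frame(codon = integer(), pos = integer(), from = character(),
                 to = character(), synonymous = logical(),
                 accepted = logical(), srs = logical())
  out
}

omega_vector <- function(model) {
  om <- rep(model$omega_background, model$codon_count)
  om[model$srs_positions] <- model$omega_srs
  om
}

#' Evolve one locus from the family ancestor
#'
#' Proposes single-nucleotide codon changes at `locus_divergence` per
#' site and accepts them so that the nonsynonymous:synonymous acceptance
#' ratio equals omega (`omega_srs` at SRS codons, `omega_background`
#' elsewhere): for omega <= 1 synonymous proposals are always accepted
#' and nonsynonymous ones with probability omega; for omega > 1 the
#' thinning flips to the synonymous side (probability 1/omega) so that
#' positive selection is expressible. Proposals that would create a stop
#' codon are re-drawn so the realised rate stays near nominal; the start
#' and stop codons are never touched.
#'
#' @param ancestor ORF nucleotide string from [simulate_ancestor()].
#' @param model a [family_model()].
#' @param locus_index integer label recorded for provenance.
#' @param log if `TRUE`, attach a `"proposals"` data-frame attribute
#'   recording every proposed change and its fate.
#' @return ORF string; attributes `"changed_sites"` (and `"proposals"`).
#' @export
evolve_locus <- function(ancestor, model, locus_index = 1L, log = FALSE) {
  stopifnot(orf_check(ancestor) == "")
  mutate_orf(ancestor, model$locus_divergence, omega_vector(model), log,
             srs = model$srs_positions)
}

#' Sample treatment-labelled clones from evolved loci
#'
#' For each animal in each of the four treatments, draws
#' `clones_per_animal` clones choosing the source locus from that
#' treatment's expression weights, then applies neutral within-locus
#' allelic substitutions (`allele_divergence`) and RT/PCR error
#' substitutions (`error_rate`), both sense-preserving. Provenance is
#' recorded in a truth table.
#'
#' @param loci character vector of locus ORFs (from [evolve_locus()]).
#' @param model a [family_model()].
#' @return List with `clones` (a [clone_set()]) and `truth`, a data frame
#'   with one row per clone: `id`, `animal_id`, `treatment`, `locus`,
#'   `allele_sites`, `error_sites` (comma-separated changed positions).
#' @export
sample_clones <- function(loci, model) {
  stopifnot(length(loci) == model$n_loci)
  w <- model$expression_weights
  if (any(rowSums(w) == 0)) stop("degenerate expression weights")
  trts <- treatment_levels()
  neutral <- rep(1, model$codon_count)
  id <- animal <- pop <- diet <- nt <- character(0)
  truth <- NULL
  k <- 0L
  for (t in trts) {
    pd <- strsplit(t, "_")[[1]]
    for (a in seq_len(model$animals_per_treatment)) {
      an <- sprintf("%s%d", gsub("_", "", t), a)
      for (cl in seq_len(model$clones_per_animal)) {
        k <- k + 1L
        locus <- sample.int(model$n_loci, 1, prob = w[t, ])
        s1 <- mutate_orf(loci[locus], model$allele_divergence, neutral)
        s2 <- mutate_orf(as.character(s1), model$error_rate, neutral)
        id <- c(id, sprintf("c%03d", k)); animal <- c(animal, an)
        pop <- c(pop, pd[1]); diet <- c(diet, pd[2])
        nt <- c(nt, as.character(s2))
        truth <- rbind(truth, data.frame(
          id = sprintf("c%03d", k), animal_id = an, treatment = t,
          locus = locus,
          allele_sites = paste(attr(s1, "changed_sites"), collapse = ","),
          error_sites = paste(attr(s2, "changed_sites"), collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  list(clones = clone_set(id, animal, pop, diet, nt), truth = truth)
}

#' Simulate a complete synthetic clone set
#'
#' Runs [simulate_ancestor()], [evolve_locus()] per locus and
#' [sample_clones()] under the model's single seed, so identical models
#' reproduce byte-identical output.
#'
#' @param model a [family_model()].
#' @return Object of class `family_sim`: list with `model`, `ancestor`,
#'   `loci`, `clones` (a [clone_set()]) and `truth` (provenance table).
#' @export
simulate_family <- function(model) {
  stopifnot(inherits(model, "family_model"))
  set.seed(model$seed)
  anc <- simulate_ancestor(model$codon_count)
  loci <- vapply(seq_len(model$n_loci), function(i)
    as.character(evolve_locus(anc, model, i)), character(1))
  smp <- sample_clones(loci, model)
  structure(list(model = model, ancestor = anc, loci = loci,
                 clones = smp$clones, truth = smp$truth),
            class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat("family_sim:", x$model$n_loci, "loci ->", length(x$clones$id),
      "clones of", nchar(x$clones$nucleotides[1]), "nt (seed",
      x$model$seed, ")\n")
  print(table(locus = x$truth$locus, treatment = x$truth$treatment))
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits the clone FASTA (headers in the `id|animal|population|diet`
#' convention), the provenance truth table (TSV) and a JSON echo of the
#' model parameters.
#'
#' @param sim a `family_sim` from [simulate_family()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_family <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sim$clones
  pop <- names(.populations)[match(cs$population, .populations)]
  fa <- file.path(dir, "clones.fasta")
  writeLines(paste0(">", cs$id, "|", cs$animal_id, "|", pop, "|", cs$diet,
                    "\n", cs$nucleotides), fa)
  tt <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- file.path(dir, "model.json")
  m <- unclass(sim$model)
  m$expression_weights <- as.data.frame(m$expression_weights)
  jsonlite::write_json(m, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, truth = tt, model = js))
}
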