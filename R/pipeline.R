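# End-to-end analysis: one entry point running validation -> dereplication
# -> tree -> UniFrac -> selection -> fingerprints, returning a classed
# object in the style of R model fits.

#' Analyse expressed gene-family diversity in a clone set
#'
#' Runs the full analysis chain on a set of cloned, treatment-labelled
#' coding sequences: translation, exact-unique counts, p-distances,
#' dereplication into variant groups, neighbor-joining tree (Poisson-
#' corrected amino-acid distances) rooted on an outgroup or at the
#' midpoint, UniFrac permutation test of treatment structure, Nei-Gojobori
#' selection analysis (global dN/dS, codon z-test, per-site parsimony
#' scan), SRS fingerprinting with clade concordance, and the SRS
#' substitution enrichment test.
#'
#' @param x a [clone_set()], or the path of a FASTA file in the
#'   `id|animal|population|diet` header convention.
#' @param threshold dereplication identity threshold (default 0.95).
#' @param srs_positions SRS codon positions (default
#'   [srs_default_positions()]).
#' @param n_perm UniFrac permutations (default 1000).
#' @param n_bootstrap codon-column bootstraps for the z-test (default
#'   1000).
#' @param seed integer seed governing permutations and bootstraps.
#' @param outgroup optional named ORF (e.g. a human orthologue),
#'   `c(id = sequence)`, used to root the tree; midpoint rooting is used
#'   when absent.
#' @param p_threshold per-site selection significance threshold (0.1).
#' @param ... unused.
#' @return Object of class `genefam`; see [summary.genefam()]. Components
#'   include `clones`, `proteins`, `derep`, `tree` (rooted `phylo` over
#'   the clone leaves), `unifrac`, `selection` (global dN/dS, z-test,
#'   site scan), `fingerprints`, `concordance`, `enrichment`, and the
#'   configuration used.
#' @examples
#' fam <- simulate_family(family_model(codon_count = 60, seed = 1,
#'                                     srs_positions = c(10, 20, 30),
#'                                     clones_per_animal = 2,
#'                                     animals_per_treatment = 2))
#' fit <- gene_family_analysis(fam$clones, n_perm = 100)
#' print(fit)
#' @export
gene_family_analysis <- function(x, threshold = 0.95,
                                 srs_positions = srs_default_positions(),
                                 n_perm = 1000, n_bootstrap = 1000,
                                 seed = 1L, outgroup = NULL,
                                 p_threshold = 0.1, ...) {
  clones <- if (is.character(x) && length(x) == 1 && file.exists(x))
    read_coding_fasta(x) else x
  if (!inherits(clones, "clone_set"))
    stop("x must be a clone_set or a FASTA path")
  if (length(clones$id) < 3)
    stop("need at least 3 validated sequences to analyse (got ",
         length(clones$id), ")")
  config <- list(threshold = threshold, srs_positions = srs_positions,
                 n_perm = n_perm, n_bootstrap = n_bootstrap, seed = seed,
                 p_threshold = p_threshold,
                 outgroup = if (is.null(outgroup)) NULL else names(outgroup))
  proteins <- translate_orf(clones)
  if (max(srs_positions) > nchar(proteins[1]))
    stop("SRS positions beyond protein length")
  dmat_nt <- p_distance(clones, "nucleotide")
  dmat_aa <- p_distance(clones, "aminoacid")
  drp <- dereplicate(proteins, clones$id, threshold)

  # tree over clone leaves (outgroup used for rooting, then dropped)
  if (!is.null(outgroup)) {
    og_id <- names(outgroup)
    og_prot <- translate_orf(unname(outgroup))
    d <- aa_distance(c(proteins, setNames(og_prot, og_id)))
    tree <- root_with_outgroup(nj_tree(d), og_id)
    tree <- ape::drop.tip(tree, og_id)
  } else {
    tree <- midpoint_root(nj_tree(aa_distance(setNames(proteins,
                                                       clones$id))))
  }

  groups <- setNames(treatment_labels(clones), clones$id)
  uf <- unifrac_permutation_test(tree, groups, n_perm = n_perm,
                                 seed = seed)

  cols <- codon_columns(clones)
  anc <- fitch_ancestral(tree, cols)
  scan <- site_selection_scan(tree, cols, anc, p_threshold)
  gdnds <- global_dnds(clones)
  zt <- codon_z_test(clones, n_bootstrap = n_bootstrap, seed = seed)

  fp <- group_by_fingerprint(proteins, clones$id, srs_positions)
  conc <- clade_fingerprint_concordance(tree, fp)
  enr <- srs_enrichment(scan, srs_positions)

  structure(list(clones = clones, proteins = proteins,
                 p_distance = list(nucleotide = dmat_nt,
                                   aminoacid = dmat_aa),
                 derep = drp, tree = tree, unifrac = uf,
                 selection = list(global = gdnds, z_test = zt,
                                  scan = scan,
                                  invariant = sum(scan$class == "invariant")),
                 fingerprints = fp, concordance = conc, enrichment = enr,
                 config = config),
            class = "genefam")
}

#' @export
print.genefam <- function(x, ...) {
  s <- summary(x)
  cat("Gene-family diversity analysis:", s$n_clones, "clones,",
      s$codon_count, "codons\n")
  cat("  unique sequences: ", s$unique_nt, " nt / ", s$unique_aa,
      " aa; mean nt p-distance ", format(s$mean_p_nt, digits = 3),
      "\n", sep = "")
  cat("  variant groups (>", format(100 * x$config$threshold),
      "% identity): ", s$n_groups, "\n", sep = "")
  cat("  UniFrac treatment structure: p = ",
      format(s$unifrac_p, digits = 4), " (", x$config$n_perm,
      " permutations)\n", sep = "")
  cat("  global dN/dS = ", format(s$global_dnds, digits = 3),
      "; z-test Z = ", format(s$z, digits = 3), ", p = ",
      format(s$z_p, digits = 3), "\n", sep = "")
  cat("  invariant codons: ", s$invariant_codons, " of ", s$codon_count,
      "\n", sep = "")
  cat("  SRS fingerprints: ", s$n_fingerprints, " (clade concordance ",
      format(s$concordance, digits = 3), "); enrichment p = ",
      format(s$enrichment_p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Summarise a gene-family analysis
#'
#' @param object a `genefam` fit.
#' @param ... unused.
#' @return A list of scalar summary quantities: clone and codon counts,
#'   unique-sequence counts, mean p-distances, variant-group count,
#'   UniFrac statistic and p, global dN/dS, z-test results, invariant
#'   codon count, fingerprint count, concordance, enrichment fractions
#'   and p. Deterministic for a fixed input and configuration.
#' @export
summary.genefam <- function(object, ...) {
  x <- object
  out <- list(
    n_clones = length(x$clones$id),
    codon_count = nrow(x$selection$scan),
    unique_nt = count_unique(x$clones, "nucleotide"),
    unique_aa = count_unique(x$clones, "aminoacid"),
    mean_p_nt = attr(x$p_distance$nucleotide, "mean"),
    mean_p_aa = attr(x$p_distance$aminoacid, "mean"),
    n_groups = length(x$derep$groups),
    unifrac_overall = x$unifrac$overall,
    unifrac_p = x$unifrac$overall_p,
    global_dnds = x$selection$global$dnds,
    z = x$selection$z_test$Z,
    z_p = x$selection$z_test$p,
    invariant_codons = x$selection$invariant,
    n_fingerprints = length(x$fingerprints$members),
    concordance = x$concordance,
    enrichment_srs_nonsyn_frac = x$enrichment$srs_nonsyn_frac,
    enrichment_background_nonsyn_frac = x$enrichment$background_nonsyn_frac,
    enrichment_p = x$enrichment$p)
  class(out) <- "summary.genefam"
  out
}

#' @export
print.summary.genefam <- function(x, ...) {
  for (nm in names(x))
    cat(format(nm, width = 34), format(unclass(x)[[nm]], digits = 5), "\n")
  invisible(x)
}

#' Plot the clone tree with treatment and fingerprint annotation
#'
#' Tip symbols are coloured by treatment; tip labels carry the
#' fingerprint letter.
#'
#' @param x a `genefam` fit.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.genefam <- function(x, ...) {
  trt <- setNames(treatment_labels(x$clones), x$clones$id)
  lev <- treatment_levels()
  cols <- setNames(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a"), lev)
  tree <- x$tree
  tip_ids <- tree$tip.label
  lab <- x$fingerprints$table$label[match(tip_ids,
                                          x$fingerprints$table$id)]
  tip_col <- cols[trt[tip_ids]]
  tree$tip.label <- paste0(tip_ids, " [", lab, "]")
  ape::plot.phylo(tree, cex = 0.6, ...)
  ape::tiplabels(pch = 19, col = tip_col, cex = 0.7)
  graphics::legend("bottomleft", legend = lev, col = cols[lev], pch = 19,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Deterministic JSON summary of a fit
#'
#' Serialises [summary.genefam()] plus the run configuration; identical
#' inputs, configuration and seed reproduce a byte-identical string.
#'
#' @param x a `genefam` fit.
#' @return A JSON string.
#' @export
summary_json <- function(x) {
  s <- unclass(summary(x))
  s$config <- x$config[c("threshold", "n_perm", "n_bootstrap", "seed",
                         "p_threshold")]
  as.character(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

#' Write all result tables of a fit
#'
#' Emits the stage outputs as plain text: distance matrices, the
#' dereplication table, the rooted tree (newick), the UniFrac pairwise
#' table, the per-site selection scan, the fingerprint table, the
#' enrichment table, and the JSON summary.
#'
#' @param x a `genefam` fit.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_genefam <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(obj, name) {
    p <- file.path(dir, name)
    write.table(obj, p, sep = "\t", quote = FALSE,
                row.names = is.matrix(obj))
    paths <<- c(paths, p)
  }
  wt(x$p_distance$nucleotide, "p_distance_nt.tsv")
  wt(x$p_distance$aminoacid, "p_distance_aa.tsv")
  wt(x$derep$table, "derep_groups.tsv")
  ape::write.tree(x$tree, file.path(dir, "tree.nwk"))
  paths <- c(paths, file.path(dir, "tree.nwk"))
  wt(as.data.frame(x$unifrac$pairwise), "unifrac_pairwise.tsv")
  wt(x$selection$scan, "site_selection.tsv")
  wt(x$fingerprints$table, "fingerprints.tsv")
  wt(as.data.frame(x$enrichment$table), "srs_enrichment.tsv")
  jp <- file.path(dir, "summary.json")
  writeLines(summary_json(x), jp)
  paths <- c(paths, jp)
  invisible(paths)
}
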