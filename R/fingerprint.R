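# Substrate-recognition-site (SRS) fingerprinting: residue tuples at the 13
# functionally important CYP2B positions, clade concordance, and the
# nonsynonymous/synonymous enrichment contrast at SRS codons.

#' Default substrate recognition site positions
#'
#' The 13 1-based residue positions on the ungapped woodrat CYP2B protein
#' identified as functionally important for substrate recognition in the
#' CYP2B pharmacological literature.
#'
#' @return Integer vector of 13 strictly increasing positions.
#' @export
srs_default_positions <- function() {
  c(114L, 206L, 209L, 290L, 294L, 297L, 298L, 302L, 363L, 367L,
    477L, 478L, 480L)
}

#' Extract the SRS residue fingerprint of a protein
#'
#' @param protein protein sequence (single string).
#' @param positions 1-based residue positions (default the 13 SRS sites);
#'   must be strictly increasing and within the protein length.
#' @return Character vector of residues, named by position.
#' @export
extract_fingerprint <- function(protein, positions = srs_default_positions()) {
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (max(positions) > nchar(protein))
    stop("position beyond protein length")
  setNames(substring(protein, positions, positions), positions)
}

#' Group proteins by SRS fingerprint
#'
#' Exact-tuple grouping of the residues at the SRS positions; fingerprint
#' labels (`A`, `B`, ...) are assigned in order of first appearance, as in
#' clade labelling on an annotated tree. Grouping is invariant to input
#' order up to labels.
#'
#' @param proteins character vector of protein sequences.
#' @param ids sequence identifiers (default names).
#' @param positions SRS positions (default [srs_default_positions()]).
#' @return Object of class `fingerprint_groups`: data frame `table`
#'   (`id`, `label`, `fingerprint`), list `members` (ids per label), and
#'   `fingerprints` (residue string per label).
#' @export
group_by_fingerprint <- function(proteins, ids = NULL,
                                 positions = srs_default_positions()) {
  if (is.null(ids))
    ids <- if (!is.null(names(proteins))) names(proteins)
           else paste0("seq", seq_along(proteins))
  fps <- vapply(proteins, function(p)
    paste(extract_fingerprint(p, positions), collapse = ""),
    character(1), USE.NAMES = FALSE)
  first <- unique(fps)
  labels <- make_clade_labels(length(first))
  lab <- labels[match(fps, first)]
  tab <- data.frame(id = ids, label = lab, fingerprint = fps,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 members = split(ids, factor(lab, labels)),
                 fingerprints = setNames(first, labels),
                 positions = positions),
            class = "fingerprint_groups")
}

make_clade_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(n)]
}

#' @export
print.fingerprint_groups <- function(x, ...) {
  cat("SRS fingerprints at positions",
      paste(x$positions, collapse = ","), "\n")
  sizes <- lengths(x$members)
  for (l in names(x$fingerprints))
    cat("  ", l, " ", paste(strsplit(x$fingerprints[[l]], "")[[1]],
                            collapse = " "),
        "  (", sizes[[l]], " seq)\n", sep = "")
  invisible(x)
}

#' Concordance between fingerprints and tree clades
#'
#' For every fingerprint carried by at least two leaves, scores 1 if its
#' members form a strictly monophyletic group on the tree and 0 otherwise;
#' returns the mean. Single-member fingerprints are excluded from the
#' mean. `NA` when no fingerprint has two or more members.
#'
#' @param tree rooted `phylo`.
#' @param groups a [group_by_fingerprint()] result (or a named list of
#'   member-id vectors).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
clade_fingerprint_concordance <- function(tree, groups) {
  members <- if (inherits(groups, "fingerprint_groups")) groups$members
             else groups
  members <- Filter(function(m) length(m) >= 2, members)
  if (!length(members)) return(NA_real_)
  mono <- vapply(members, function(m)
    ape::is.monophyletic(tree, m), logical(1))
  mean(mono)
}

# two-sided Fisher's exact test for a 2x2 table by full hypergeometric
# summation: condition on the margins, sum the probabilities of all tables
# as or less probable than the observed one (standard conditional rule)
fisher_exact_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

#' SRS substitution enrichment test
#'
#' Contrasts the nonsynonymous/synonymous substitution composition of the
#' SRS codons against the remaining codons with a two-sided Fisher's
#' exact test (full hypergeometric summation). The odds ratio is the
#' cross-product ratio; 0.5 is added to every cell only when some cell is
#' zero (flagged in the result).
#'
#' Two call forms: pass a [site_selection_scan()] table plus the SRS codon
#' positions (substitution counts are the rounded edge tallies summed
#' within and outside the SRS set), or pass the four counts directly via
#' `counts = c(nonsyn_srs, syn_srs, nonsyn_bg, syn_bg)` -- the form used
#' with a published substitution table.
#'
#' @param scan a data frame from [site_selection_scan()] (ignored when
#'   `counts` is given).
#' @param positions SRS codon positions (default
#'   [srs_default_positions()]).
#' @param counts optional length-4 numeric vector of substitution counts,
#'   `c(nonsyn_srs, syn_srs, nonsyn_background, syn_background)`.
#' @return Object of class `srs_enrichment`: the 2x2 `table`,
#'   `srs_nonsyn_frac`, `background_nonsyn_frac`, `odds_ratio`,
#'   `haldane` (zero-cell correction applied), and two-sided `p`.
#' @export
srs_enrichment <- function(scan = NULL, positions = srs_default_positions(),
                           counts = NULL) {
  if (is.null(counts)) {
    if (is.null(scan)) stop("supply a site scan or explicit counts")
    in_srs <- scan$codon %in% positions
    counts <- c(round(sum(scan$Nd[in_srs])), round(sum(scan$Sd[in_srs])),
                round(sum(scan$Nd[!in_srs])), round(sum(scan$Sd[!in_srs])))
  }
  stopifnot(length(counts) == 4, all(counts >= 0))
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  if (a + b + c + d == 0)
    return(structure(list(table = matrix(counts, 2, byrow = TRUE),
                          srs_nonsyn_frac = NA_real_,
                          background_nonsyn_frac = NA_real_,
                          odds_ratio = NA_real_, haldane = FALSE,
                          p = NA_real_, undefined = TRUE),
                     class = "srs_enrichment"))
  haldane <- any(counts == 0)
  h <- if (haldane) 0.5 else 0
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                dimnames = list(c("SRS", "background"),
                                c("nonsyn", "syn")))
  structure(list(table = tab,
                 srs_nonsyn_frac = if (a + b > 0) a / (a + b) else NA_real_,
                 background_nonsyn_frac =
                   if (c + d > 0) c / (c + d) else NA_real_,
                 odds_ratio = ((a + h) * (d + h)) / ((b + h) * (c + h)),
                 haldane = haldane,
                 p = fisher_exact_2x2(a, b, c, d), undefined = FALSE),
            class = "srs_enrichment")
}

#' @export
print.srs_enrichment <- function(x, digits = 4, ...) {
  cat("SRS substitution enrichment (Fisher's exact, two-sided)\n")
  print(x$table)
  cat("  nonsynonymous fraction: SRS ",
      format(100 * x$srs_nonsyn_frac, digits = 3), "% vs background ",
      format(100 * x$background_nonsyn_frac, digits = 3), "%\n", sep = "")
  cat("  odds ratio", format(x$odds_ratio, digits = digits),
      if (x$haldane) "(0.5 added to zero cells)" else "",
      "| p =", format(x$p, digits = digits), "\n")
  invisible(x)
}
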