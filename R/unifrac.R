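# Unweighted UniFrac between treatment groups on the clone tree, with a
# label-permutation significance test and Bonferroni-corrected pairwise
# comparisons.

# logical incidence matrix: edges x tips, TRUE when the tip lies below the
# edge; computed once per tree and reused across permutations
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- reorder(tree, "postorder")
  inc <- matrix(FALSE, nrow(tree$edge), ntip,
                dimnames = list(NULL, tree$tip.label))
  below <- matrix(FALSE, ntip + tree$Nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- match(do.call(paste, as.data.frame(po$edge)),
               do.call(paste, as.data.frame(tree$edge)))
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    inc[ord[k], ] <- below[ch, ]
    below[par, ] <- below[par, ] | below[ch, ]
  }
  inc
}

# core computation on a precomputed incidence: a, b are logical tip masks.
# Edges with no tips from either group, and edges above the MRCA of the
# union (below-set == union), are outside the pruned two-group tree and
# are excluded; this reproduces computing on the tree pruned to the union.
unifrac_from_incidence <- function(inc, edge_len, a, b) {
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) stop("empty group")
  ca <- inc %*% a
  cb <- inc %*% b
  considered <- (ca + cb > 0) & !(ca == na & cb == nb)
  unique_e <- considered & ((ca > 0) != (cb > 0))
  tot <- sum(edge_len[considered])
  if (tot == 0) return(0)
  sum(edge_len[unique_e]) / tot
}

#' Unweighted UniFrac distance between two groups of leaves
#'
#' Fraction of branch length unique to one group's leaf set, out of the
#' total branch length spanned by both, on the tree pruned to the two
#' groups' leaves (presence/absence only). Symmetric, in `[0, 1]`: 0 when
#' every leaf carries both labels' history (identical leaf sets), 1 when
#' the groups occupy disjoint subtrees.
#'
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @param group_a,group_b character vectors of tip labels (non-empty,
#'   subsets of the tree's tips).
#' @return Fraction in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, group_a, group_b) {
  tips <- tree$tip.label
  if (!all(c(group_a, group_b) %in% tips))
    stop("group members missing from the tree")
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  inc <- edge_tip_incidence(tree)
  unifrac_from_incidence(inc, tree$edge.length,
                         tips %in% group_a, tips %in% group_b)
}

#' UniFrac permutation test of treatment structure on a tree
#'
#' The observed statistic is the mean unweighted UniFrac distance over all
#' treatment pairs with at least `min_group` leaves each (6 pairs for four
#' full treatments). The null is built by shuffling leaf labels with group
#' sizes preserved; p-values use the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` so they are never 0.
#' Pairwise tests use each pair's own distance, Bonferroni-corrected by
#' the number of pairs actually tested.
#'
#' @param tree rooted `phylo`.
#' @param groups named character vector: `groups[tip.label]` is the
#'   treatment of each leaf (every leaf must appear).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @param min_group smallest group size admitted to a pairwise test;
#'   groups below it are skipped with a warning.
#' @return Object of class `unifrac_test`: observed overall statistic and
#'   p-value, matrix `pairwise` (distance, raw and Bonferroni-corrected p
#'   per treatment pair), `n_perm`, `seed`.
#' @export
unifrac_permutation_test <- function(tree, groups, n_perm = 1000,
                                     seed = 1L, min_group = 2L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  tips <- tree$tip.label
  if (!all(tips %in% names(groups)))
    stop("every leaf needs a treatment label")
  lab <- unname(groups[tips])
  lev <- sort(unique(lab))
  sizes <- table(factor(lab, lev))
  usable <- names(sizes)[sizes >= min_group]
  if (length(setdiff(lev, usable)))
    warning("group(s) with < ", min_group, " leaves skipped: ",
            paste(setdiff(lev, usable), collapse = ", "))
  if (length(usable) < 2)
    stop("need at least two groups with >= ", min_group, " leaves")
  pairs <- combn(usable, 2)
  np <- ncol(pairs)
  inc <- edge_tip_incidence(tree)
  el <- tree$edge.length
  gsize <- as.vector(sizes[usable])
  names(gsize) <- usable
  ia <- match(pairs[1, ], usable); ib <- match(pairs[2, ], usable)

  # one incidence x indicator product per labelling, then all 6 pairwise
  # distances from the per-edge group counts
  pair_stats <- function(lab) {
    G <- vapply(usable, function(g) as.numeric(lab == g),
                numeric(length(lab)))
    cnt <- inc %*% G
    vapply(seq_len(np), function(j) {
      ca <- cnt[, ia[j]]; cb <- cnt[, ib[j]]
      considered <- (ca + cb > 0) &
        !(ca == gsize[ia[j]] & cb == gsize[ib[j]])
      tot <- sum(el[considered])
      if (tot == 0) return(0)
      sum(el[considered & ((ca > 0) != (cb > 0))]) / tot
    }, numeric(1))
  }
  obs <- pair_stats(lab)
  obs_overall <- mean(obs)
  set.seed(seed)
  ge_overall <- 0L
  ge_pair <- integer(np)
  for (r in seq_len(n_perm)) {
    perm <- sample(lab)
    st <- pair_stats(perm)
    if (mean(st) >= obs_overall) ge_overall <- ge_overall + 1L
    ge_pair <- ge_pair + (st >= obs)
  }
  raw_p <- (1 + ge_pair) / (1 + n_perm)
  pw <- cbind(distance = obs, raw_p = raw_p,
              corrected_p = pmin(1, raw_p * np))
  rownames(pw) <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  structure(list(overall = obs_overall,
                 overall_p = (1 + ge_overall) / (1 + n_perm),
                 pairwise = pw, n_pairs = np, n_perm = n_perm,
                 seed = seed),
            class = "unifrac_test")
}

#' @export
print.unifrac_test <- function(x, digits = 4, ...) {
  cat("UniFrac permutation test (", x$n_perm, " permutations, seed ",
      x$seed, ")\n", sep = "")
  cat("  overall mean pairwise distance: ",
      format(x$overall, digits = digits),
      ", p = ", format(x$overall_p, digits = digits), "\n", sep = "")
  cat("  pairwise (Bonferroni x", x$n_pairs, "):\n", sep = "")
  print(round(x$pairwise, digits))
  invisible(x)
}
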