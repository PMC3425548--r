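# Distance-based tree construction and parsimony ancestral states.
# Trees are ape "phylo" objects throughout; leaves map to clone ids.

#' Amino-acid distance matrix for tree building
#'
#' p-distance between translated clones, optionally Poisson-corrected
#' (`d = -ln(1 - p)`), the standard correction for multiple hits on
#' amino-acid sequences.
#'
#' @param x a [clone_set()] or character vector of aligned proteins.
#' @param correction `"poisson"` (default) or `"p"` (raw p-distance).
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
aa_distance <- function(x, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  d <- if (inherits(x, "clone_set")) p_distance(x, "aminoacid")
       else p_distance(x, "aminoacid")
  if (correction == "poisson") {
    if (any(d[upper.tri(d)] >= 1)) stop("saturated distances (p >= 1)")
    d[] <- -log(1 - d)
  }
  attr(d, "mean") <- NULL
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor joining (via [ape::nj()]) followed by clamping of
#' negative branch-length estimates: each negative length is set to zero
#' and the deficit transferred to the adjacent branch toward the root-side
#' node, the usual practice when a tree feeds branch-length-based methods
#' such as UniFrac that require non-negative lengths.
#'
#' @param d symmetric distance matrix with zero diagonal and labels as
#'   dimnames (>= 3 taxa).
#' @param labels optional taxon labels overriding the dimnames.
#' @return An unrooted `phylo` object with all edge lengths `>= 0`.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  clamp_negative_branches(tr)
}

# transfer each negative estimate to the sibling edge sharing its parent
# node, then clamp whatever remains
clamp_negative_branches <- function(tr) {
  el <- tr$edge.length
  neg <- which(el < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) {
      sib <- sib[1]
      el[sib] <- el[sib] + el[e]
    }
    el[e] <- 0
  }
  el[el < 0] <- 0
  tr$edge.length <- el
  tr
}

#' Root a tree on an outgroup branch
#'
#' Places the root at the midpoint of the branch subtending the outgroup
#' leaf, so the ingroup forms a clade sister to the outgroup. Re-rooting
#' with the same outgroup is idempotent on topology.
#'
#' @param tree a `phylo` object.
#' @param outgroup_id tip label of the outgroup.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  tip <- match(outgroup_id, tree$tip.label)
  if (is.na(tip)) stop("outgroup '", outgroup_id, "' is not a leaf")
  edge <- which(tree$edge[, 2] == tip)
  phytools::reroot(tree, tip, position = tree$edge.length[edge] / 2)
}

#' Midpoint-root a tree
#'
#' Used when no outgroup sequence is supplied; the root is placed halfway
#' along the longest leaf-to-leaf path ([phytools::midpoint.root()]).
#'
#' @param tree a `phylo` object.
#' @return A rooted `phylo` object.
#' @export
midpoint_root <- function(tree) phytools::midpoint.root(tree)

#' Codon columns of a clone set
#'
#' Splits equal-length ORFs into their analysis codons (start codon
#' included, terminal stop excluded; columns are 1-based over codons).
#'
#' @param x a [clone_set()] or character vector of equal-length ORFs.
#' @param ids row names (defaults to clone ids).
#' @return Character matrix, sequences x codon columns.
#' @export
codon_columns <- function(x, ids = NULL) {
  if (inherits(x, "clone_set")) {
    ids <- x$id
    x <- x$nucleotides
  }
  stopifnot(length(unique(nchar(x))) == 1)
  m <- do.call(rbind, lapply(x, codon_split))
  m <- m[, -ncol(m), drop = FALSE]
  rownames(m) <- ids
  m
}

#' Fitch parsimony ancestral states per codon column
#'
#' Classic two-pass Fitch parsimony on a rooted (binary) tree: bottom-up
#' state sets with one change counted per empty intersection, then a
#' deterministic top-down resolution (the parent state is kept when
#' admissible, otherwise the lexicographically smallest member of the
#' node's set). The realised assignment attains the Fitch minimum change
#' count for every column.
#'
#' @param tree rooted `phylo` whose tip labels index rows of `columns`.
#' @param columns character matrix of states (tips x columns), e.g. from
#'   [codon_columns()].
#' @return Object of class `fitch_anc`: list with `states` (matrix, all
#'   nodes x columns; rows 1..Ntip are the observed tip states) and
#'   `changes` (integer minimum change count per column).
#' @export
fitch_ancestral <- function(tree, columns) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(columns)))
    stop("tree leaves missing from the alignment: ",
         paste(setdiff(tips, rownames(columns)), collapse = ", "))
  columns <- columns[tips, , drop = FALSE]
  ntip <- length(tips)
  nnode <- tree$Nnode
  edge <- tree$edge
  po <- reorder(tree, "postorder")$edge
  ncol_ <- ncol(columns)
  states <- matrix(NA_character_, ntip + nnode, ncol_)
  states[seq_len(ntip), ] <- columns
  changes <- integer(ncol_)
  root <- ntip + 1L
  children <- split(edge[, 2], edge[, 1])
  # preorder: parents before children
  pre <- rev(unique(po[, 1]))
  for (col in seq_len(ncol_)) {
    sets <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) sets[[i]] <- columns[i, col]
    nch <- 0L
    for (nd in unique(po[, 1])) {            # postorder over internal nodes
      ch <- children[[as.character(nd)]]
      s <- sets[[ch[1]]]
      for (c2 in ch[-1]) {
        inter <- intersect(s, sets[[c2]])
        if (length(inter)) s <- inter
        else { s <- sort(union(s, sets[[c2]])); nch <- nch + 1L }
      }
      sets[[nd]] <- s
    }
    changes[col] <- nch
    # top-down resolution
    states[root, col] <- sort(sets[[root]])[1]
    for (nd in pre) {
      for (ch in children[[as.character(nd)]]) {
        if (ch <= ntip) next
        p <- states[nd, col]
        states[ch, col] <- if (p %in% sets[[ch]]) p else sort(sets[[ch]])[1]
      }
    }
  }
  structure(list(states = states, changes = changes, tree = tree),
            class = "fitch_anc")
}

#' @export
print.fitch_anc <- function(x, ...) {
  cat("fitch_anc:", ncol(x$states), "columns,",
      sum(x$changes), "total minimum changes,",
      sum(x$changes == 0), "invariant column(s)\n")
  invisible(x)
}
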