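# Nei-Gojobori (1986) synonymous/nonsynonymous accounting: potential-site
# counting, pathway-averaged observed changes, Jukes-Cantor correction,
# global dN/dS, codon z-test of neutrality, and a parsimony-based per-site
# selection scan in the spirit of SLAC.

.bases <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous potential sites of a codon
#'
#' NG86 site counting: for each of the three positions, the fraction of
#' the three possible single-nucleotide changes that are synonymous
#' contributes `syn/3` to `s`; changes creating a stop codon are excluded
#' from the synonymous count, so `n = 3 - s` absorbs them (stop-adjusted).
#'
#' @param codon a sense codon string, e.g. `"TTT"`.
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n = 3`.
#' @export
ng86_potential_sites <- function(codon) {
  tab <- ng86_tables()$sites
  if (!codon %in% rownames(tab)) stop("not a sense codon: ", codon)
  c(s = tab[codon, "s"], n = tab[codon, "n"])
}

# Build (once) the NG86 lookup tables over the 61 sense codons:
#   sites: per-codon s and n
#   Nd, Sd: pathway-averaged observed nonsyn/syn differences for every
#           ordered codon pair (equal weight across minimal mutational
#           pathways; pathways passing through a stop codon are excluded,
#           or re-admitted with stop steps counted as nonsynonymous in the
#           rare case every pathway is blocked)
ng86_tables <- function() {
  cache <- .genefamdiv_cache
  if (!is.null(cache$ng86)) return(cache$ng86)
  code <- Biostrings::GENETIC_CODE
  cods <- sense_codons()
  n <- length(cods)
  sites <- matrix(0, n, 2, dimnames = list(cods, c("s", "n")))
  for (c1 in cods) {
    s <- 0
    for (pos in 1:3) for (b in setdiff(.bases, substr(c1, pos, pos))) {
      c2 <- c1; substr(c2, pos, pos) <- b
      if (!(c2 %in% .stop_codons) && code[[c2]] == code[[c1]])
        s <- s + 1 / 3
    }
    sites[c1, ] <- c(s, 3 - s)
  }
  Nd <- Sd <- matrix(0, n, n, dimnames = list(cods, cods))
  step_class <- function(a, b) {          # 1 = nonsyn, 0 = syn
    if (code[[a]] == code[[b]]) 0 else 1
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- cods[i]; b <- cods[j]
    diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    k <- length(diffpos)
    perms <- if (k == 1) list(diffpos)
             else if (k == 2) list(diffpos, rev(diffpos))
             else list(diffpos[c(1, 2, 3)], diffpos[c(1, 3, 2)],
                       diffpos[c(2, 1, 3)], diffpos[c(2, 3, 1)],
                       diffpos[c(3, 1, 2)], diffpos[c(3, 2, 1)])
    walk <- function(ord, allow_stop) {
      cur <- a; nd <- 0; sd <- 0
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
        if (nxt %in% .stop_codons || cur %in% .stop_codons) {
          if (!allow_stop) return(NULL)
          nd <- nd + 1                    # stop-involving step: nonsyn
        } else {
          cl <- step_class(cur, nxt)
          nd <- nd + cl; sd <- sd + (1 - cl)
        }
        cur <- nxt
      }
      c(nd, sd)
    }
    res <- lapply(perms, walk, allow_stop = FALSE)
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
    m <- do.call(rbind, res)
    Nd[i, j] <- mean(m[, 1]); Sd[i, j] <- mean(m[, 2])
  }
  cache$ng86 <- list(sites = sites, Nd = Nd, Sd = Sd,
                     index = setNames(seq_len(n), cods))
  cache$ng86
}

# codon index matrix (integer) for fast lookups; NA impossible for valid ORFs
codon_index_matrix <- function(columns) {
  tab <- ng86_tables()
  matrix(tab$index[columns], nrow(columns), ncol(columns),
         dimnames = dimnames(columns))
}

#' Pairwise NG86 dN and dS between two coding sequences
#'
#' Observed synonymous/nonsynonymous differences are averaged with equal
#' weight over the minimal mutational pathways of each codon pair
#' (stop-containing pathways excluded); potential sites are averaged over
#' the two sequences. Proportions `pN = Nd/N`, `pS = Sd/S` receive the
#' Jukes-Cantor correction `d = -(3/4) ln(1 - 4p/3)` (set
#' `correction = "none"` for raw proportions). `dS` (or `dN`) is `NA`
#' when its proportion is saturated (`p >= 3/4`); the ratio is reported
#' as `NA` rather than infinite when `dS` is 0 or undefined.
#'
#' @param a,b valid ORF nucleotide strings of equal length.
#' @param correction `"jc"` (default) or `"none"`.
#' @return List with `dN`, `dS`, `ratio`, and the underlying `Nd`, `Sd`,
#'   `N`, `S`, `pN`, `pS`.
#' @export
pairwise_dn_ds <- function(a, b, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  cols <- codon_columns(c(a, b), ids = c("a", "b"))
  tab <- ng86_tables()
  ia <- tab$index[cols[1, ]]; ib <- tab$index[cols[2, ]]
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  S <- (sum(tab$sites[ia, "s"]) + sum(tab$sites[ib, "s"])) / 2
  N <- (sum(tab$sites[ia, "n"]) + sum(tab$sites[ib, "n"])) / 2
  pN <- Nd / N; pS <- Sd / S
  corr <- function(p) {
    if (correction == "none") return(p)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dN <- corr(pN); dS <- corr(pS)
  ratio <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  list(dN = dN, dS = dS, ratio = ratio, Nd = Nd, Sd = Sd, N = N, S = S,
       pN = pN, pS = pS)
}

#' Global dN/dS of a coding alignment
#'
#' `method = "pairwise"` (default): mean pairwise dN divided by mean
#' pairwise dS over all sequence pairs with defined values.
#' `method = "tree"`: substitutions tallied once over the edges of a
#' supplied tree from parsimony ancestral states (via
#' [site_selection_scan()] machinery), then converted to rates.
#'
#' @param x a [clone_set()] or character vector of equal-length ORFs.
#' @param method `"pairwise"` or `"tree"`.
#' @param tree rooted `phylo` (required for `method = "tree"`).
#' @param correction passed to [pairwise_dn_ds()].
#' @return List with `dnds` (`NA` with a flag when undefined, e.g. all
#'   sequences identical), `mean_dN`, `mean_dS`, `n_pairs`.
#' @export
global_dnds <- function(x, method = c("pairwise", "tree"), tree = NULL,
                        correction = "jc") {
  method <- match.arg(method)
  nt <- if (inherits(x, "clone_set")) x$nucleotides else x
  ids <- if (inherits(x, "clone_set")) x$id else names(x)
  if (length(nt) < 2) stop("need at least two sequences")
  if (method == "tree") {
    if (is.null(tree)) stop("tree required for method = 'tree'")
    cols <- codon_columns(if (inherits(x, "clone_set")) x else nt, ids)
    anc <- fitch_ancestral(tree, cols)
    scan <- site_selection_scan(tree, cols, anc)
    Nd <- sum(scan$Nd); Sd <- sum(scan$Sd)
    N <- sum(scan$n); S <- sum(scan$s)
    pN <- Nd / N; pS <- Sd / S
    dnds <- if (Sd == 0) NA_real_ else (pN) / (pS)
    return(list(dnds = dnds, mean_dN = pN, mean_dS = pS,
                n_pairs = NA_integer_,
                undefined = is.na(dnds)))
  }
  pr <- combn(length(nt), 2)
  dn <- ds <- numeric(ncol(pr))
  for (j in seq_len(ncol(pr))) {
    r <- pairwise_dn_ds(nt[pr[1, j]], nt[pr[2, j]], correction)
    dn[j] <- r$dN; ds[j] <- r$dS
  }
  ok <- !is.na(dn) & !is.na(ds)
  mdn <- mean(dn[ok]); mds <- mean(ds[ok])
  dnds <- if (!any(ok) || mds == 0) NA_real_ else mdn / mds
  list(dnds = dnds, mean_dN = mdn, mean_dS = mds, n_pairs = sum(ok),
       undefined = is.na(dnds))
}

# per-column aggregated NG86 statistics: potential n, s averaged over
# sequences and (optionally) Nd, Sd summed over all sequence pairs
column_ng86_stats <- function(cols, pairs = TRUE) {
  tab <- ng86_tables()
  idx <- codon_index_matrix(cols)
  nseq <- nrow(idx); ncols <- ncol(idx)
  Nd <- Sd <- numeric(ncols)
  n_pairs <- 0L
  if (pairs) {
    pr <- combn(nseq, 2)
    n_pairs <- ncol(pr)
    for (j in seq_len(n_pairs)) {
      ia <- idx[pr[1, j], ]; ib <- idx[pr[2, j], ]
      Nd <- Nd + tab$Nd[cbind(ia, ib)]
      Sd <- Sd + tab$Sd[cbind(ia, ib)]
    }
  }
  s <- colMeans(matrix(tab$sites[idx, "s"], nseq, ncols))
  n <- colMeans(matrix(tab$sites[idx, "n"], nseq, ncols))
  list(Nd = Nd, Sd = Sd, n = n, s = s, n_pairs = n_pairs)
}

#' Codon-by-codon z-test of neutrality
#'
#' Tests the negative-selection alternative `dS > dN` across the whole
#' alignment. Per-column synonymous/nonsynonymous differences (summed
#' over all sequence pairs) and potential sites are bootstrapped over
#' codon columns to estimate the standard error of `dS - dN`;
#' `Z = (dS - dN) / SE` with a one-tailed normal p-value.
#'
#' @param x a [clone_set()] or character vector of equal-length ORFs.
#' @param n_bootstrap codon-column bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param correction `"jc"` or `"none"`, as in [pairwise_dn_ds()].
#' @return List with `Z`, `p`, `dN`, `dS`, `n_bootstrap`; `Z` and `p` are
#'   `NA` (flagged `undefined`) for degenerate alignments.
#' @export
codon_z_test <- function(x, n_bootstrap = 1000, seed = 1L,
                         correction = c("jc", "none")) {
  correction <- match.arg(correction)
  if (n_bootstrap < 100) stop("n_bootstrap must be >= 100")
  cols <- if (inherits(x, "clone_set")) codon_columns(x)
          else codon_columns(x, ids = paste0("s", seq_along(x)))
  st <- column_ng86_stats(cols)
  P <- st$n_pairs
  corr <- function(p) {
    if (correction == "none") return(p)
    ifelse(p >= 3 / 4, NA_real_, -3 / 4 * log(1 - 4 * p / 3))
  }
  d_of <- function(idx) {
    pN <- sum(st$Nd[idx]) / (P * sum(st$n[idx]))
    pS <- sum(st$Sd[idx]) / (P * sum(st$s[idx]))
    c(dN = corr(pN), dS = corr(pS))
  }
  ncols <- ncol(cols)
  obs <- d_of(seq_len(ncols))
  if (any(is.na(obs)) || (obs["dN"] == 0 && obs["dS"] == 0))
    return(list(Z = NA_real_, p = NA_real_, dN = obs[["dN"]],
                dS = obs[["dS"]], n_bootstrap = n_bootstrap,
                undefined = TRUE))
  set.seed(seed)
  diffs <- vapply(seq_len(n_bootstrap), function(r) {
    d <- d_of(sample.int(ncols, ncols, replace = TRUE))
    d[["dS"]] - d[["dN"]]
  }, numeric(1))
  se <- sd(diffs, na.rm = TRUE)
  Z <- (obs[["dS"]] - obs[["dN"]]) / se
  list(Z = Z, p = pnorm(Z, lower.tail = FALSE), dN = obs[["dN"]],
       dS = obs[["dS"]], n_bootstrap = n_bootstrap, undefined = FALSE)
}

#' Per-site selection scan from parsimony ancestral states
#'
#' A parsimony analogue of single-ancestor counting (SLAC): for every
#' codon column, observed nonsynonymous and synonymous changes are
#' tallied over all tree edges from the Fitch ancestral assignment
#' (pathway-averaged within each edge), the expected nonsynonymous
#' fraction is `n_c / (n_c + s_c)` from the column's potential sites, and
#' a two-tailed binomial test (on rounded counts) gives the per-site
#' p-value. Sites are classed `positive` (`dN > dS`, `p < p_threshold`),
#' `negative` (`dN < dS`, `p < p_threshold`), `neutral`, or `invariant`
#' (no observed change among the leaves).
#'
#' @param tree rooted `phylo` over the alignment's sequences.
#' @param columns codon matrix from [codon_columns()].
#' @param anc [fitch_ancestral()] result for `tree` and `columns`
#'   (computed when omitted).
#' @param p_threshold per-site significance threshold (default 0.1).
#' @return Data frame with one row per codon column: `codon`, `Nd`, `Sd`,
#'   `n`, `s`, `dn_minus_ds`, `p`, `class`.
#' @export
site_selection_scan <- function(tree, columns, anc = NULL,
                                p_threshold = 0.1) {
  if (is.null(anc)) anc <- fitch_ancestral(tree, columns)
  tab <- ng86_tables()
  st <- column_ng86_stats(columns[tree$tip.label, , drop = FALSE],
                          pairs = FALSE)
  idx_all <- codon_index_matrix(anc$states)
  edge <- tree$edge
  ncols <- ncol(columns)
  Nd <- Sd <- numeric(ncols)
  for (e in seq_len(nrow(edge))) {
    ip <- idx_all[edge[e, 1], ]; ic <- idx_all[edge[e, 2], ]
    Nd <- Nd + tab$Nd[cbind(ip, ic)]
    Sd <- Sd + tab$Sd[cbind(ip, ic)]
  }
  invariant <- anc$changes == 0
  n_c <- st$n; s_c <- st$s
  dn <- Nd / n_c
  ds <- ifelse(s_c > 0, Sd / s_c, 0)
  p <- rep(NA_real_, ncols)
  class <- rep("neutral", ncols)
  for (c0 in seq_len(ncols)) {
    if (invariant[c0]) { class[c0] <- "invariant"; next }
    x <- round(Nd[c0]); m <- round(Nd[c0] + Sd[c0])
    if (m == 0) { class[c0] <- "invariant"; next }
    p[c0] <- binom.test(x, m, n_c[c0] / (n_c[c0] + s_c[c0]))$p.value
    if (p[c0] < p_threshold)
      class[c0] <- if (dn[c0] > ds[c0]) "positive" else
                   if (dn[c0] < ds[c0]) "negative" else "neutral"
  }
  data.frame(codon = seq_len(ncols), Nd = Nd, Sd = Sd,
             n = n_c, s = s_c, dn_minus_ds = dn - ds, p = p,
             class = class, stringsAsFactors = FALSE)
}

#' Count invariant codon columns
#'
#' Columns with no variation across all sequences (e.g. 302 of 491 codons
#' in the study's deposited alignment).
#'
#' @param x a [clone_set()] or codon matrix from [codon_columns()].
#' @return Integer count.
#' @export
invariant_codon_count <- function(x) {
  cols <- if (is.matrix(x)) x else codon_columns(x)
  sum(apply(cols, 2, function(col) length(unique(col)) == 1))
}
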