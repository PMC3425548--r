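# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# --- exhaustive global-alignment oracle (short sequences only) ----------
# enumerates every alignment recursively; returns the best identity under
# the package's scoring contract (max score, then fewest gaps)
align_oracle <- function(a, b) {
  best <- list(score = -Inf, gaps = Inf, matches = 0, columns = 0)
  rec <- function(i, j, score, gaps, matches, columns) {
    if (i > nchar(a) && j > nchar(b)) {
      if (score > best$score ||
          (score == best$score && gaps < best$gaps)) {
        best <<- list(score = score, gaps = gaps, matches = matches,
                      columns = columns)
      }
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      m <- substr(a, i, i) == substr(b, j, j)
      rec(i + 1, j + 1, score + m, gaps, matches + m, columns + 1)
    }
    if (i <= nchar(a)) rec(i + 1, j, score - 1, gaps + 1, matches,
                           columns + 1)
    if (j <= nchar(b)) rec(i, j + 1, score - 1, gaps + 1, matches,
                           columns + 1)
  }
  rec(1, 1, 0, 0, 0, 0)
  best$matches / best$columns
}

# --- NG86 pathway-enumeration oracle ------------------------------------
# recomputes per-codon-pair observed Nd/Sd by explicit permutation walks,
# translating with seqinr (the package uses Biostrings), and potential
# sites by direct mutation enumeration
oracle_translate1 <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}
oracle_stops <- c("TAA", "TAG", "TGA")

oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, pos, pos))) {
    alt <- codon
    substr(alt, pos, pos) <- nt
    if (!(alt %in% oracle_stops) &&
        oracle_translate1(alt) == oracle_translate1(codon))
      s <- s + 1 / 3
  }
  c(s = s, n = 3 - s)
}

# all orderings of the differing positions as permutation matrices
oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(1:2, 2:1))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

oracle_pair_counts <- function(a, b) {
  dp <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dp)) return(c(Nd = 0, Sd = 0))
  paths <- list()
  for (perm in oracle_perms(length(dp))) {
    cur <- a; nd <- 0; sd <- 0; ok <- TRUE
    for (p in dp[perm]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (nxt %in% oracle_stops) { ok <- FALSE; break }
      if (oracle_translate1(nxt) == oracle_translate1(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) paths[[length(paths) + 1]] <- c(nd, sd)
  }
  m <- do.call(rbind, paths)
  c(Nd = mean(m[, 1]), Sd = mean(m[, 2]))
}

# --- UniFrac brute-force oracle -----------------------------------------
# prunes the tree to the two groups' leaves and classifies every branch by
# the tip set below it (via phangorn::Descendants)
oracle_unifrac <- function(tree, ga, gb) {
  keep <- unique(c(ga, gb))
  tr <- if (length(setdiff(tree$tip.label, keep)))
    ape::keep.tip(tree, keep) else tree
  desc <- phangorn::Descendants(tr, tr$edge[, 2], type = "tips")
  uniq <- tot <- 0
  for (e in seq_len(nrow(tr$edge))) {
    tips <- tr$tip.label[desc[[e]]]
    ina <- any(tips %in% ga); inb <- any(tips %in% gb)
    if (!ina && !inb) next
    tot <- tot + tr$edge.length[e]
    if (xor(ina, inb)) uniq <- uniq + tr$edge.length[e]
  }
  if (tot == 0) 0 else uniq / tot
}

# --- Fitch brute-force oracle (<= 6 leaves) -----------------------------
# minimum number of state changes over all internal-node labelings
oracle_fitch_min <- function(tree, tip_states) {
  states <- unique(tip_states)
  nnode <- tree$Nnode
  ntip <- length(tree$tip.label)
  grids <- expand.grid(rep(list(states), nnode),
                       stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    assign_all <- c(tip_states[tree$tip.label], unlist(grids[r, ]))
    ch <- sum(assign_all[tree$edge[, 1]] != assign_all[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# --- Fisher 2x2 oracle ---------------------------------------------------
# hypergeometric enumeration from binomial coefficients (log scale)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lp <- function(x) lchoose(r1, x) + lchoose(n - r1, c1 - x) -
    lchoose(n, c1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- exp(vapply(xs, lp, numeric(1)))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-9)])
}

# --- Welch closed form ---------------------------------------------------
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# --- misc helpers ---------------------------------------------------------
random_orf <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(c("ATG", sample(genefamdiv:::sense_codons(), n_codons - 1,
                        replace = TRUE), "TAA"), collapse = "")
}

random_protein <- function(len) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), len,
               replace = TRUE), collapse = "")
}
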