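# Relative gene copy number from qPCR quantification cycles against a
# single-copy reference gene, with Welch two-sample comparisons.

#' Read a qPCR quantification-cycle table
#'
#' TSV with columns `sample`, `population`, `primer_set` (one of
#' `woodrat_specific`, `rodent_conserved`, `reference`), `replicate`,
#' `cq`.
#'
#' @param path file path.
#' @return Data frame with those columns, `cq` numeric.
#' @export
read_qpcr <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "primer_set", "replicate", "cq")
  if (!all(need %in% names(df)))
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  df$cq <- as.numeric(df$cq)
  if (any(is.na(df$cq)) || any(df$cq <= 0)) stop("Cq values must be > 0")
  df
}

#' Relative copy number from target and reference Cq replicates
#'
#' `ratio = efficiency^(mean Cq_ref - mean Cq_target)`: with ideal
#' doubling (efficiency 2) a target amplifying 3 cycles earlier than the
#' single-copy reference has 8 relative copies. Replicate scatter is
#' propagated to the ratio by the delta method and a warning is raised
#' when either well set's replicate SD exceeds 0.5 cycles.
#'
#' @param target,reference numeric vectors of replicate Cq values for the
#'   same sample (>= 2 replicates each).
#' @param efficiency amplification factor per cycle, in (1, 2]
#'   (default 2).
#' @return List with `ratio`, `sd` (propagated), `dCq`.
#' @export
copy_ratio <- function(target, reference, efficiency = 2) {
  stopifnot(length(target) >= 2, length(reference) >= 2,
            all(target > 0), all(reference > 0))
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must be in (1, 2]")
  if (sd(target) > 0.5 || sd(reference) > 0.5)
    warning("replicate SD exceeds 0.5 cycles")
  dcq <- mean(reference) - mean(target)
  ratio <- efficiency^dcq
  se_d <- sqrt(var(target) / length(target) +
               var(reference) / length(reference))
  list(ratio = ratio, sd = ratio * log(efficiency) * se_d, dCq = dcq)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a two-sided
#' p-value; the fractional df reported alongside published copy-number
#' comparisons identifies this form even when labelled a Student's test.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return List with `t`, `df`, `p`; `t` is `NA` (flagged) when both
#'   groups have zero variance and equal means.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  undefined = TRUE))
    stop("zero variance in both groups with unequal means")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, undefined = FALSE)
}

#' Per-sample copy-number ratios and primer-set comparison
#'
#' Computes the relative copy number of every sample under each non-
#' reference primer set (against the sample's own reference wells), then
#' compares the two primer sets and, within each primer set, the two
#' populations, with Welch tests.
#'
#' @param df qPCR table as from [read_qpcr()].
#' @param efficiency amplification factor per cycle.
#' @return Object of class `copy_number`: data frame `ratios` (`sample`,
#'   `population`, `primer_set`, `ratio`, `sd`) and list `comparisons`
#'   of Welch results.
#' @export
copy_number_analysis <- function(df, efficiency = 2) {
  targets <- setdiff(unique(df$primer_set), "reference")
  if (!"reference" %in% df$primer_set)
    stop("no reference primer_set wells")
  rows <- list()
  for (s in unique(df$sample)) {
    ref <- df$cq[df$sample == s & df$primer_set == "reference"]
    if (length(ref) < 2) stop("sample ", s, " lacks reference replicates")
    for (ps in targets) {
      tgt <- df$cq[df$sample == s & df$primer_set == ps]
      if (length(tgt) < 2) next
      cr <- copy_ratio(tgt, ref, efficiency)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, population = df$population[df$sample == s][1],
        primer_set = ps, ratio = cr$ratio, sd = cr$sd,
        stringsAsFactors = FALSE)
    }
  }
  ratios <- do.call(rbind, rows)
  comparisons <- list()
  if (length(targets) == 2) {
    g <- split(ratios$ratio, ratios$primer_set)
    if (all(lengths(g) >= 2))
      comparisons[[paste(targets, collapse = "_vs_")]] <-
        welch_t(g[[targets[1]]], g[[targets[2]]])
  }
  for (ps in targets) {
    sub <- ratios[ratios$primer_set == ps, ]
    g <- split(sub$ratio, sub$population)
    if (length(g) == 2 && all(lengths(g) >= 2))
      comparisons[[paste0(ps, "_by_population")]] <-
        welch_t(g[[1]], g[[2]])
  }
  structure(list(ratios = ratios, comparisons = comparisons,
                 efficiency = efficiency),
            class = "copy_number")
}

#' @export
print.copy_number <- function(x, digits = 3, ...) {
  cat("relative copy number (efficiency", x$efficiency, ")\n")
  agg <- aggregate(ratio ~ primer_set, x$ratios, function(v)
    c(mean = mean(v), sd = sd(v)))
  for (i in seq_len(nrow(agg)))
    cat("  ", agg$primer_set[i], ": mean ",
        format(agg$ratio[i, "mean"], digits = digits), " +/- ",
        format(agg$ratio[i, "sd"], digits = digits), " s.d.\n", sep = "")
  for (nm in names(x$comparisons)) {
    w <- x$comparisons[[nm]]
    cat("  ", nm, ": t = ", format(w$t, digits = digits),
        ", df = ", format(w$df, digits = digits),
        ", p = ", format(w$p, digits = digits), "\n", sep = "")
  }
  invisible(x)
}
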