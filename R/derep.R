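# FastGroupII-style dereplication: greedy centroid grouping of amino-acid
# sequences by percent identity with gaps.

#' Dereplicate protein sequences into variant groups
#'
#' Greedy centroid clustering: sequences are processed in order; each joins
#' the first existing group whose *representative* it matches at strictly
#' more than `threshold` identity (percent identity with gaps), otherwise
#' it founds a new group with itself as representative. The default order
#' is input order, which is how dereplication programs typically behave;
#' `order = "length_id"` pre-sorts by decreasing length then id for an
#' input-order-independent variant.
#'
#' @param proteins character vector of protein sequences.
#' @param ids optional identifiers (default: names of `proteins`, else
#'   `seq1..seqN`).
#' @param threshold identity threshold in (0, 1]; a sequence joins a group
#'   only when identity to the representative is `> threshold` (so the
#'   default 0.95 implements ">95% amino acid similarity").
#' @param order `"input"` or `"length_id"`.
#' @return Object of class `derep_groups`: a list with `groups` (list of
#'   member-id vectors), `representatives`, `threshold`, and `table`, a
#'   data frame with one row per member (`group`, `representative`,
#'   `member`, `identity`).
#' @export
dereplicate <- function(proteins, ids = NULL, threshold = 0.95,
                        order = c("input", "length_id")) {
  order <- match.arg(order)
  if (length(proteins) == 0) stop("no sequences to dereplicate")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(ids))
    ids <- if (!is.null(names(proteins))) names(proteins)
           else paste0("seq", seq_along(proteins))
  if (order == "length_id") {
    o <- order(-nchar(proteins), ids)
    proteins <- proteins[o]; ids <- ids[o]
  }
  rep_seq <- character(0); rep_id <- character(0)
  member_group <- integer(length(proteins))
  member_ident <- numeric(length(proteins))
  for (i in seq_along(proteins)) {
    placed <- FALSE
    for (g in seq_along(rep_seq)) {
      idy <- percent_identity(proteins[i], rep_seq[g])
      if (idy > threshold) {
        member_group[i] <- g; member_ident[i] <- idy
        placed <- TRUE; break
      }
    }
    if (!placed) {
      rep_seq <- c(rep_seq, proteins[i]); rep_id <- c(rep_id, ids[i])
      member_group[i] <- length(rep_seq); member_ident[i] <- 1
    }
  }
  tab <- data.frame(group = member_group,
                    representative = rep_id[member_group],
                    member = ids, identity = member_ident,
                    stringsAsFactors = FALSE)
  structure(list(groups = split(ids, member_group),
                 representatives = rep_id, threshold = threshold,
                 table = tab),
            class = "derep_groups")
}

#' @export
print.derep_groups <- function(x, ...) {
  cat("dereplication at >", format(100 * x$threshold), "% identity: ",
      length(x$groups), " variant group(s)\n", sep = "")
  sizes <- lengths(x$groups)
  for (g in seq_along(x$groups))
    cat("  group ", g, " (rep ", x$representatives[g], "): ",
        sizes[g], " member(s)\n", sep = "")
  invisible(x)
}

#' Count unique sequences by exact deduplication
#'
#' @param x a [clone_set()] or character vector of sequences.
#' @param level `"nucleotide"` (default) or `"aminoacid"`; for a
#'   `clone_set`, amino-acid level counts unique translations.
#' @return Integer count of distinct sequences.
#' @export
count_unique <- function(x, level = c("nucleotide", "aminoacid")) {
  level <- match.arg(level)
  seqs <- if (inherits(x, "clone_set")) {
    if (level == "aminoacid") translate_orf(x) else x$nucleotides
  } else {
    if (level == "aminoacid" && all(vapply(x, orf_check, "") == ""))
      translate_orf(x) else x
  }
  length(unique(seqs))
}
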