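# Core sequence types and I/O: validated coding sequences with treatment
# metadata, translation, percent identity with gaps, p-distance matrices.

.populations <- c(GB = "GreatBasin", MJ = "Mojave")
.diets <- c("juniper", "creosote")

#' Construct a set of validated coding sequences
#'
#' A `clone_set` is the package's container for cloned open reading frames
#' with treatment metadata: parallel vectors of clone id, animal id,
#' population (`"GreatBasin"` or `"Mojave"`), diet (`"juniper"` or
#' `"creosote"`) and nucleotide sequence. Every sequence must be a complete
#' uninterrupted ORF: length divisible by 3, starting with ATG, exactly one
#' stop codon located at the end, and only unambiguous A/C/G/T characters.
#'
#' @param id character vector of clone identifiers (unique).
#' @param animal_id character vector of source animal identifiers.
#' @param population character vector; `"GreatBasin"`/`"Mojave"` (or the
#'   short codes `"GB"`/`"MJ"`).
#' @param diet character vector; `"juniper"` or `"creosote"`.
#' @param nucleotides character vector of ORF sequences over A/C/G/T.
#' @return An object of class `clone_set`.
#' @seealso [read_coding_fasta()] to build one from a FASTA file.
#' @export
clone_set <- function(id, animal_id, population, diet, nucleotides) {
  n <- length(id)
  stopifnot(length(animal_id) == n, length(population) == n,
            length(diet) == n, length(nucleotides) == n)
  if (anyDuplicated(id))
    stop("clone ids must be unique")
  population <- ifelse(population %in% names(.populations),
                       .populations[population], population)
  if (!all(population %in% .populations))
    stop("population must be GreatBasin/Mojave (or GB/MJ)")
  if (!all(diet %in% .diets))
    stop("diet must be juniper or creosote")
  bad <- vapply(nucleotides, function(x) orf_check(x), character(1))
  if (any(bad != ""))
    stop("invalid ORF for ", paste(id[bad != ""], collapse = ", "), ": ",
         bad[bad != ""][1])
  structure(list(id = as.character(id),
                 animal_id = as.character(animal_id),
                 population = unname(population),
                 diet = as.character(diet),
                 nucleotides = unname(as.character(nucleotides))),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("clone_set:", length(x$id), "coding sequences,",
      if (length(x$id)) nchar(x$nucleotides[1]) else 0, "nt\n")
  tab <- table(treatment_labels(x))
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' @export
length.clone_set <- function(x) length(x$id)

#' @export
`[.clone_set` <- function(x, i) {
  structure(lapply(unclass(x), `[`, i), class = "clone_set")
}

#' Treatment labels of a clone set
#'
#' Combines population and diet into the four treatment labels used
#' throughout (`GB_juniper`, `GB_creosote`, `MJ_juniper`, `MJ_creosote`).
#'
#' @param x a `clone_set`.
#' @return Character vector, one label per clone.
#' @export
treatment_labels <- function(x) {
  pop <- names(.populations)[match(x$population, .populations)]
  paste(pop, x$diet, sep = "_")
}

#' The four treatment labels
#' @return `c("GB_juniper", "GB_creosote", "MJ_juniper", "MJ_creosote")`
#' @export
treatment_levels <- function() {
  as.vector(outer(names(.populations), .diets, paste, sep = "_"))[c(1, 3, 2, 4)]
}

# "" if valid, else the reason the ORF is rejected
orf_check <- function(nt) {
  if (is.na(nt) || !nzchar(nt)) return("empty sequence")
  if (grepl("[^ACGT]", nt)) return("ambiguous or non-ACGT characters")
  if (nchar(nt) %% 3 != 0) return("length not divisible by 3")
  if (nchar(nt) < 6) return("shorter than start plus stop")
  cod <- codon_split(nt)
  if (cod[1] != "ATG") return("does not begin with ATG")
  stops <- which(cod %in% c("TAA", "TAG", "TGA"))
  if (length(stops) == 0) return("no stop codon")
  if (!identical(stops, length(cod)))
    return("internal stop codon")
  ""
}

codon_split <- function(nt) {
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

#' Read coding sequences with treatment metadata from FASTA
#'
#' Headers follow the convention `id|animal|population|diet` (delimiter
#' configurable), with population given as `GB`/`MJ` (long names accepted)
#' and diet as `juniper`/`creosote`. Records that are not complete,
#' uninterrupted ORFs are excluded -- mirroring how incomplete clones are
#' dropped from cloned cDNA datasets -- and reported in the `"excluded"`
#' attribute of the result.
#'
#' @param path FASTA file path.
#' @param delim header field delimiter (default `"|"`).
#' @return A [clone_set()]; attribute `"excluded"` is a data frame with
#'   columns `id` and `reason` for rejected records.
#' @export
read_coding_fasta <- function(path, delim = "|") {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e)))
  headers <- names(seqs)
  fields <- strsplit(headers, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4))
    stop("unparseable header(s), expected id", delim, "animal", delim,
         "population", delim, "diet: ",
         paste(utils::head(headers[nf != 4], 3), collapse = "; "))
  meta <- do.call(rbind, fields)
  nt <- toupper(as.character(seqs))
  reasons <- vapply(nt, orf_check, character(1), USE.NAMES = FALSE)
  pop_raw <- meta[, 3]
  badpop <- !(pop_raw %in% c(names(.populations), .populations))
  baddiet <- !(meta[, 4] %in% .diets)
  reasons[reasons == "" & badpop] <- "unknown population code"
  reasons[reasons == "" & baddiet] <- "unknown diet code"
  keep <- reasons == ""
  cs <- clone_set(meta[keep, 1], meta[keep, 2], pop_raw[keep],
                  meta[keep, 4], nt[keep])
  attr(cs, "excluded") <- data.frame(id = meta[!keep, 1],
                                     reason = reasons[!keep],
                                     stringsAsFactors = FALSE)
  cs
}

#' Translate open reading frames
#'
#' Standard genetic code; the terminal stop codon is dropped, so a valid
#' ORF of `3*(k+1)` nucleotides yields `k` residues (1476 nt -> 491 aa).
#'
#' @param nt character vector of valid ORF nucleotide sequences, or a
#'   [clone_set()].
#' @return Character vector of protein sequences (named by clone id for a
#'   `clone_set`).
#' @export
translate_orf <- function(nt) {
  if (inherits(nt, "clone_set"))
    return(setNames(translate_orf(nt$nucleotides), nt$id))
  vapply(nt, function(x) {
    bad <- orf_check(x)
    if (bad != "") stop("invalid ORF: ", bad)
    cod <- codon_split(x)
    cod <- cod[-length(cod)]                      # drop terminal stop
    paste(Biostrings::GENETIC_CODE[cod], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Percent identity with gaps between two protein sequences
#'
#' Global alignment by dynamic programming with match +1, mismatch 0 and a
#' linear gap penalty of -1; among maximal-score alignments the one with
#' the fewest gap columns is used (score and gap count jointly determine
#' the matched-column count, so the exact gap placement cannot change the
#' value). Identity is matches divided by alignment length *including* gap
#' columns, hence symmetric and 1 only for identical sequences.
#'
#' @param a,b protein sequences (single character strings; unequal lengths
#'   allowed).
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .nw_identity_cpp(a, b)$identity
}

#' Pairwise p-distance matrix
#'
#' Proportion of sites at which two aligned sequences differ, at the
#' nucleotide or amino-acid level, computed over every aligned site
#' (nucleotide comparisons span the full ORF including the stop codon,
#' as when a raw alignment is fed to a distance program).
#'
#' @param seqs character vector of equal-length aligned sequences (or a
#'   [clone_set()] for nucleotide level).
#' @param level `"nucleotide"` or `"aminoacid"`.
#' @return Symmetric matrix with zero diagonal; attribute `"mean"` holds
#'   the mean over off-diagonal pairs.
#' @export
p_distance <- function(seqs, level = c("nucleotide", "aminoacid")) {
  level <- match.arg(level)
  if (inherits(seqs, "clone_set")) {
    ids <- seqs$id
    seqs <- if (level == "aminoacid") translate_orf(seqs$nucleotides)
            else seqs$nucleotides
  } else ids <- names(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least two sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must have equal length")
  chm <- do.call(cbind, strsplit(seqs, ""))       # sites x seqs
  L <- nrow(chm)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    di <- colSums(chm[, (i + 1):n, drop = FALSE] != chm[, i]) / L
    d[i, (i + 1):n] <- di
    d[(i + 1):n, i] <- di
  }
  attr(d, "mean") <- mean(d[upper.tri(d)])
  d
}
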