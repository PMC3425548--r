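# Thin optional helper to fetch deposited coding sequences from GenBank.
# Network access is required; all analyses accept any local FASTA instead.

#' Fetch deposited accessions from GenBank (optional helper)
#'
#' Downloads nucleotide FASTA records for a run of accession numbers via
#' the NCBI efetch service and writes them to one file. The default range
#' is the deposited woodrat CYP2B clone set (JN105874-JN105960). Headers
#' are kept verbatim; such files can be re-labelled to the
#' `id|animal|population|diet` convention before analysis. Fails cleanly
#' without network access.
#'
#' @param path output FASTA path.
#' @param first,last first and last accession of the run.
#' @return `path`, invisibly.
#' @export
fetch_genbank_range <- function(path, first = "JN105874",
                                last = "JN105960") {
  prefix <- gsub("[0-9]+$", "", first)
  lo <- as.integer(gsub("^[A-Z]+", "", first))
  hi <- as.integer(gsub("^[A-Z]+", "", last))
  acc <- sprintf("%s%06d", prefix, lo:hi)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/",
                "efetch.fcgi?db=nuccore&rettype=fasta&retmode=text&id=",
                paste(acc, collapse = ","))
  utils::download.file(url, path, quiet = TRUE)
  invisible(path)
}
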