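ALPHABET <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors. `N` is preserved.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Integer-encode a sequence: A=1, C=2, G=3, T=4, anything else NA.
encode_seq <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], ALPHABET)
  code
}

# midpoint of a 0-based half-open interval, as a (possibly fractional) bp
interval_mid <- function(start, end) (start + end) / 2

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Constant-time window extraction over long sequences: a genome "view" is
# a list of DNAString objects keyed by chromosome; seq_window pulls
# [lo, hi) (0-based half-open) as a plain character scalar.
genome_view <- function(genome) {
  if (is.list(genome) && !is.null(attr(genome, "is_genome_view")))
    return(genome)
  v <- lapply(genome, Biostrings::DNAString)
  attr(v, "is_genome_view") <- TRUE
  v
}

seq_window <- function(view, chrom, lo, hi) {
  as.character(Biostrings::subseq(view[[chrom]], start = lo + 1L,
                                  end = hi))
}

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Deterministic numeric formatting used by every table writer so that
# identical inputs give byte-identical files.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                sprintf("%d", as.integer(round(x))),
                formatC(x, digits = digits, format = "g")))
}

#' Write a data frame as a deterministic TSV
#'
#' Plain tab-separated output with a header, no quoting and no row names;
#' used by the command-line pipeline so that re-runs with the same seed are
#' byte-identical.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
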