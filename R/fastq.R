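#' Read a FASTQ file into a read set
#'
#' A read set is the package's working representation of sequencing
#' reads: a data.frame with columns `id`, `seq` (bases over A/C/G/T/N)
#' and `qual` (Phred+33 encoded string, same length as `seq`). Parsing is
#' delegated to Biostrings, so gzip-compressed files are transparent.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  read_set(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write a read set to FASTQ
#'
#' @param reads a read set (see [read_fastq()]).
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

# constructor/validator for the internal read-set data.frame
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality lengths differ for some read(s)")
  }
  df <- data.frame(id = as.character(id), seq = as.character(seq),
                   qual = as.character(qual), stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

# Phred+33 helpers ----------------------------------------------------------

phred_offset <- 33L

# decode all quality strings into one integer vector + per-read lengths
qual_to_int <- function(qual) {
  n <- nchar(qual)
  if (sum(n) == 0L) {
    return(list(q = integer(0L), len = n))
  }
  list(q = utf8ToInt(paste(qual, collapse = "")) - phred_offset, len = n)
}

int_to_qual_string <- function(q) {
  intToUtf8(q + phred_offset)
}

# reverse complement for plain character vectors (IUPAC-aware)
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

reverse_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
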