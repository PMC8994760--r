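#' Per-barcode quality-control parameters
#'
#' Defaults encode the per-barcode filtering regime used throughout the
#' package: length bounds of 150-510 bp for ITS2 and a 75 bp minimum for
#' trnL; a rolling 5 bp window (step 1) whose mean Phred score must stay
#' at or above 20; no ambiguous bases; no homopolymer run longer than 8;
#' exact (0-mismatch) 7 bp MID tags; exact primer matches by default.
#'
#' @param barcode `"ITS2"` or `"trnL"` (case-insensitive); sets the
#'   length bounds.
#' @param min_len,max_len override length bounds (bp); `max_len = Inf`
#'   disables the upper bound.
#' @param window window width in bp for the rolling quality rule.
#' @param min_window_q minimum mean Phred score per window.
#' @param max_homopolymer longest allowed homopolymer run (bp).
#' @param max_barcode_errors allowed MID mismatches (0 = exact).
#' @param max_primer_mismatches allowed mismatches per primer.
#' @return list of class `"qc_params"`.
#' @export
qc_params <- function(barcode = c("ITS2", "trnL"),
                      min_len = NULL, max_len = NULL,
                      window = 5L, min_window_q = 20,
                      max_homopolymer = 8L,
                      max_barcode_errors = 0L,
                      max_primer_mismatches = 0L) {
  barcode <- match_barcode(barcode)
  if (is.null(min_len)) min_len <- if (barcode == "ITS2") 150L else 75L
  if (is.null(max_len)) max_len <- if (barcode == "ITS2") 510L else Inf
  stopifnot(min_len > 0L, max_len >= min_len, window >= 1L,
            max_homopolymer >= 1L)
  structure(
    list(
      barcode = barcode, min_len = min_len, max_len = max_len,
      window = as.integer(window), min_window_q = min_window_q,
      max_homopolymer = as.integer(max_homopolymer),
      max_barcode_errors = as.integer(max_barcode_errors),
      max_primer_mismatches = as.integer(max_primer_mismatches)
    ),
    class = "qc_params"
  )
}

match_barcode <- function(barcode) {
  b <- toupper(as.character(barcode)[1L])
  if (b %in% c("ITS2", "ITS")) return("ITS2")
  if (b %in% c("TRNL", "TRNL-UAA")) return("trnL")
  stop("unknown barcode label: ", barcode)
}

#' Barcode/primer sheet for demultiplexing
#'
#' @param sample_id sample identifiers (unique).
#' @param mid_fwd,mid_rev 7-base MID tags; the pair must be unique per
#'   sample. The read is expected to start with `mid_fwd` and end with
#'   the reverse complement of `mid_rev`.
#' @param primer_fwd,primer_rev amplification primers (IUPAC codes
#'   allowed); located inside the MIDs.
#' @param barcode barcode label for the whole sheet (`"ITS2"`/`"trnL"`).
#' @return data.frame of class `"barcode_sheet"`.
#' @export
barcode_sheet <- function(sample_id, mid_fwd, mid_rev,
                          primer_fwd, primer_rev, barcode = "ITS2") {
  df <- data.frame(
    sample_id = as.character(sample_id),
    mid_fwd = toupper(mid_fwd), mid_rev = toupper(mid_rev),
    primer_fwd = toupper(primer_fwd), primer_rev = toupper(primer_rev),
    barcode = match_barcode(barcode),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sheet")
  if (any(nchar(df$mid_fwd) != 7L) || any(nchar(df$mid_rev) != 7L)) {
    stop("MID tags must be exactly 7 bases")
  }
  if (anyDuplicated(paste(df$mid_fwd, df$mid_rev))) {
    stop("duplicate (mid_fwd, mid_rev) pair across samples")
  }
  class(df) <- c("barcode_sheet", "data.frame")
  df
}

#' Read a MID/primer sheet from TSV
#'
#' Columns: `sample_id`, `mid_fwd`, `mid_rev`, `primer_fwd`,
#' `primer_rev`, optional `barcode`.
#'
#' @param path TSV file.
#' @param barcode fallback barcode label when the file has no `barcode`
#'   column.
#' @return a [barcode_sheet()].
#' @export
read_barcode_sheet <- function(path, barcode = "ITS2") {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  barcode_sheet(
    df$sample_id, df$mid_fwd, df$mid_rev, df$primer_fwd, df$primer_rev,
    barcode = if ("barcode" %in% names(df)) df$barcode[1L] else barcode
  )
}

#' Demultiplex MID-tagged reads
#'
#' A read is assigned to a sample iff its first 7 bases equal the
#' sample's forward MID and its last 7 bases equal the reverse
#' complement of the reverse MID, with zero mismatches (the
#' `max_barcode_errors = 0` policy). Both MIDs (14 bases total, with
#' their qualities) are removed from assigned reads. Unassigned reads go
#' to the reject stream with reason `"barcode"`.
#'
#' @param reads a read set (see [read_fastq()]).
#' @param sheet a [barcode_sheet()].
#' @param both_orientations also try the reverse-complemented read when
#'   the as-given orientation does not match (default `FALSE`).
#' @return list with `samples` (named list of read sets, one per
#'   sample_id in the sheet) and `rejects` (read set with a `reason`
#'   column).
#' @export
demultiplex <- function(reads, sheet, both_orientations = FALSE) {
  stopifnot(inherits(sheet, "barcode_sheet"))
  key <- paste(sheet$mid_fwd, sheet$mid_rev, sep = "|")
  n <- nchar(reads$seq)
  rc_rev <- revcomp(sheet$mid_rev)
  names(key) <- NULL
  lookup <- stats::setNames(sheet$sample_id, paste0(sheet$mid_fwd, "|", rc_rev))
  probe <- function(seq) {
    paste0(substr(seq, 1L, 7L), "|", substr(seq, n - 6L, n))
  }
  hit <- lookup[probe(reads$seq)]
  if (both_orientations && anyNA(hit)) {
    flip <- is.na(hit) & n >= 14L
    if (any(flip)) {
      rcseq <- revcomp(reads$seq[flip])
      nr <- nchar(rcseq)
      hit2 <- lookup[paste0(substr(rcseq, 1L, 7L), "|",
                            substr(rcseq, nr - 6L, nr))]
      ok2 <- !is.na(hit2)
      idx <- which(flip)[ok2]
      reads$seq[idx] <- rcseq[ok2]
      reads$qual[idx] <- reverse_string(reads$qual[which(flip)[ok2]])
      hit[idx] <- hit2[ok2]
    }
  }
  assigned <- !is.na(hit) & n >= 15L
  trimmed <- read_set(
    reads$id[assigned],
    substr(reads$seq[assigned], 8L, n[assigned] - 7L),
    substr(reads$qual[assigned], 8L, n[assigned] - 7L)
  )
  samples <- split(
    trimmed,
    factor(hit[assigned], levels = sheet$sample_id)
  )
  samples <- lapply(samples, function(d) {
    class(d) <- c("read_set", "data.frame")
    rownames(d) <- NULL
    d
  })
  rejects <- reads[!assigned, , drop = FALSE]
  rejects$reason <- rep("barcode", nrow(rejects))
  rownames(rejects) <- NULL
  list(samples = samples, rejects = rejects)
}

# IUPAC nucleotide code expansions
iupac_codes <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# vectorized: mismatches of pattern (IUPAC) against subject substrings
# anchored at position `at` (same length as subjects or scalar)
iupac_mismatches <- function(subjects, pattern, at = 1L) {
  m <- integer(length(subjects))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  for (i in seq_along(pat)) {
    allowed <- iupac_codes[[pat[i]]]
    if (is.null(allowed)) stop("bad IUPAC code in primer: ", pat[i])
    ch <- substr(subjects, at + i - 1L, at + i - 1L)
    m <- m + !(ch %in% allowed)
  }
  m
}

#' Trim amplification primers
#'
#' Expects MIDs already removed (see [demultiplex()]): the forward
#' primer is anchored at the 5' end and the reverse complement of the
#' reverse primer at the 3' end. Matching is IUPAC-aware and allows up
#' to `params$max_primer_mismatches` mismatches per primer. Reads in
#' which either primer is not found (or that are shorter than the two
#' primers combined) are rejected with reason `"primer"`.
#'
#' @param reads a read set.
#' @param spec one row of a [barcode_sheet()] (or any list with
#'   `primer_fwd`, `primer_rev`).
#' @param params a [qc_params()].
#' @return list with `kept` (primer-excised read set) and `rejects`
#'   (read set with `reason` column).
#' @export
trim_primers <- function(reads, spec, params = qc_params()) {
  pf <- toupper(spec$primer_fwd[1L])
  pr_rc <- revcomp(toupper(spec$primer_rev[1L]))
  lf <- nchar(pf)
  lr <- nchar(pr_rc)
  n <- nchar(reads$seq)
  long_enough <- n >= (lf + lr + 1L)
  ok <- long_enough
  if (any(long_enough)) {
    idx <- which(long_enough)
    mm_f <- iupac_mismatches(reads$seq[idx], pf, at = 1L)
    mm_r <- iupac_mismatches(reads$seq[idx], pr_rc,
                             at = n[idx] - lr + 1L)
    ok[idx] <- mm_f <= params$max_primer_mismatches &
      mm_r <= params$max_primer_mismatches
  }
  kept <- read_set(
    reads$id[ok],
    substr(reads$seq[ok], lf + 1L, n[ok] - lr),
    substr(reads$qual[ok], lf + 1L, n[ok] - lr)
  )
  rejects <- reads[!ok, , drop = FALSE]
  rejects$reason <- rep("primer", nrow(rejects))
  rownames(rejects) <- NULL
  list(kept = kept, rejects = rejects)
}

#' Length, quality, ambiguity and homopolymer filter
#'
#' Applies, in order: the per-barcode length bounds; rejection of any
#' read containing an N; rejection of homopolymer runs longer than
#' `max_homopolymer`; and the rolling-window quality rule (a read is
#' rejected if any window of `window` consecutive bases has mean Phred
#' below `min_window_q`; reads shorter than the window are evaluated as
#' a single window). The first failing rule names the reject reason
#' (`"length"`, `"ambiguous"`, `"homopolymer"`, `"quality"`).
#'
#' @param reads a read set with MIDs and primers already removed.
#' @param params a [qc_params()]; its `barcode` sets the length bounds.
#' @return list with `kept` (read set) and `rejects` (read set with
#'   `reason`).
#' @export
qc_filter <- function(reads, params = qc_params()) {
  n <- nchar(reads$seq)
  reason <- rep(NA_character_, nrow(reads))
  bad_len <- n < params$min_len | n > params$max_len
  reason[bad_len] <- "length"
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  reason[is.na(reason) & has_n] <- "ambiguous"
  # four fixed-string searches beat any regex by an order of magnitude
  runs <- strrep(c("A", "C", "G", "T"), params$max_homopolymer + 1L)
  hp <- grepl(runs[1L], reads$seq, fixed = TRUE) |
    grepl(runs[2L], reads$seq, fixed = TRUE) |
    grepl(runs[3L], reads$seq, fixed = TRUE) |
    grepl(runs[4L], reads$seq, fixed = TRUE)
  reason[is.na(reason) & hp] <- "homopolymer"
  todo <- which(is.na(reason))
  if (length(todo)) {
    badq <- window_quality_fail(
      reads$qual[todo], params$window, params$min_window_q
    )
    reason[todo[badq]] <- "quality"
  }
  ok <- is.na(reason)
  kept <- reads[ok, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("read_set", "data.frame")
  rejects <- reads[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  rownames(rejects) <- NULL
  list(kept = kept, rejects = rejects)
}

# TRUE for reads with any length-`w` window of mean quality < min_q;
# reads shorter than w are one single window. Vectorized via a global
# cumulative sum over the concatenated quality strings.
window_quality_fail <- function(qual, w, min_q) {
  dec <- qual_to_int(qual)
  len <- dec$len
  out <- logical(length(qual))
  if (length(dec$q) == 0L) {
    return(out)
  }
  offset <- c(0L, cumsum(len))[seq_along(len)]
  short <- len < w & len > 0L
  if (any(short)) {
    sums <- vapply(which(short), function(i) {
      sum(dec$q[(offset[i] + 1L):(offset[i] + len[i])])
    }, numeric(1L))
    out[short] <- sums / len[short] < min_q
  }
  longi <- which(len >= w)
  if (length(longi)) {
    S <- c(0, cumsum(as.numeric(dec$q)))
    nwin <- len[longi] - w + 1L
    starts <- sequence(nwin) + rep.int(offset[longi], nwin)
    wsum <- S[starts + w] - S[starts]
    grp <- rep.int(seq_along(longi), nwin)
    nbad <- rowsum(as.integer(wsum < w * min_q), grp, reorder = TRUE)[, 1L]
    out[longi] <- nbad > 0L
  }
  out
}

#' Full per-sample QC: primer trimming plus read filters
#'
#' @param reads a demultiplexed read set (MIDs removed).
#' @param spec sheet row with the sample's primers.
#' @param params a [qc_params()].
#' @return list with `kept` and `rejects` (reasons `primer`, `length`,
#'   `ambiguous`, `homopolymer`, `quality`).
#' @export
qc_reads <- function(reads, spec, params = qc_params()) {
  tr <- trim_primers(reads, spec, params)
  fl <- qc_filter(tr$kept, params)
  rejects <- rbind(tr$rejects, fl$rejects)
  rownames(rejects) <- NULL
  list(kept = fl$kept, rejects = rejects)
}

#' Tabulate QC outcomes per sample
#'
#' @param results named list (by sample) of lists with `kept` and
#'   `rejects` as returned by [qc_reads()] or [qc_filter()].
#' @return data.frame with one row per sample: `input`, `kept` and one
#'   column per reject reason; `kept` plus rejects reconcile to `input`.
#' @export
qc_stats <- function(results) {
  reasons <- c("barcode", "primer", "length", "ambiguous",
               "homopolymer", "quality")
  rows <- lapply(names(results), function(s) {
    r <- results[[s]]
    tab <- table(factor(r$rejects$reason, levels = reasons))
    data.frame(
      sample_id = s, input = nrow(r$kept) + nrow(r$rejects),
      kept = nrow(r$kept), as.list(tab),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
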