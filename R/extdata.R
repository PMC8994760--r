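#' Path to an installed fixture file
#'
#' @param file file name under the package's `extdata` directory; empty
#'   to list the directory.
#' @return absolute path.
#' @export
herbaudit_extdata <- function(file = "") {
  p <- system.file("extdata", file, package = "herbaudit",
                   mustWork = file != "")
  p
}

#' Load a transcribed per-sample PHS detection table
#'
#' The package ships transcriptions of the published per-sample
#' detection tables of two preparations (NJW, DHW) under both barcodes
#' as binary species-by-sample matrices. Row totals (number of samples
#' a species was detected in) are authoritative transcription; where
#' the source table does not unambiguously identify *which* samples
#' carry a mark, marks are placed left-to-right, so per-sample columns
#' are approximate (see the file headers).
#'
#' @param preparation `"NJW"` or `"DHW"`.
#' @param barcode barcode label.
#' @return integer 0/1 matrix, species x samples.
#' @export
load_detection_fixture <- function(preparation, barcode) {
  preparation <- toupper(preparation)
  stopifnot(preparation %in% c("NJW", "DHW"))
  bc <- tolower(match_barcode(barcode))
  path <- herbaudit_extdata(
    sprintf("%s_%s_presence.tsv", tolower(preparation), bc)
  )
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$species
  storage.mode(m) <- "integer"
  m
}

#' Load the published per-preparation PHM detection counts
#'
#' The per-barcode and union counts of detected prescribed herbal
#' materials for the four studied preparations, with their PHM totals,
#' as printed; inputs to the sensitivity arithmetic.
#'
#' @return data.frame with columns `preparation`, `n_phms`,
#'   `detected_its2`, `detected_trnl`, `detected_union`.
#' @export
load_reported_phm_counts <- function() {
  utils::read.delim(
    herbaudit_extdata("reported_phm_counts.tsv"), comment.char = "#",
    stringsAsFactors = FALSE
  )
}
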