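#' Audit one sample's detected species against a prescription
#'
#' Every species with a positive post-filter read count is classified as
#' prescribed (PHS), substituted (SHS, same genus as a PHS) or
#' contaminated (CHS); see [classify_species()]. The three sets are
#' disjoint by construction.
#'
#' @param counts named read-count vector for one sample (post
#'   threshold), or one row of an [abundance_table()] `counts` matrix.
#' @param rx a [prescription()].
#' @param sample_id sample label carried into the summary.
#' @param barcode barcode label.
#' @return object of class `"audit_summary"`: list with `sample_id`,
#'   `barcode`, sets `phs`, `shs`, `chs` and their sizes `n_phs`,
#'   `n_shs`, `n_chs`.
#' @export
audit_sample <- function(counts, rx, sample_id = "sample",
                         barcode = "ITS2") {
  present <- names(counts)[counts > 0L]
  if (length(present)) {
    cat_ <- classify_species(present, rx)
    sp <- normalize_taxon(present)
  } else {
    cat_ <- factor(character(0), levels = c("PHS", "SHS", "CHS"))
    sp <- character(0)
  }
  sets <- split(sp, cat_)
  structure(
    list(
      sample_id = sample_id, barcode = match_barcode(barcode),
      phs = sort(unique(sets$PHS)), shs = sort(unique(sets$SHS)),
      chs = sort(unique(sets$CHS)),
      n_phs = length(unique(sets$PHS)),
      n_shs = length(unique(sets$SHS)),
      n_chs = length(unique(sets$CHS))
    ),
    class = "audit_summary"
  )
}

#' @export
print.audit_summary <- function(x, ...) {
  cat(
    sprintf(
      "Audit %s [%s]: %d PHS, %d SHS, %d CHS\n",
      x$sample_id, x$barcode, x$n_phs, x$n_shs, x$n_chs
    )
  )
  invisible(x)
}

#' Audit all rows of an abundance table
#'
#' @param tab an [abundance_table()] (post threshold).
#' @param rx a [prescription()].
#' @return list of [audit_sample()] summaries, one per sample row.
#' @export
audit_table <- function(tab, rx) {
  stopifnot(inherits(tab, "abundance_table"))
  lapply(rownames(tab$counts), function(s) {
    audit_sample(tab$counts[s, ], rx, sample_id = s,
                 barcode = tab$barcode)
  })
}

#' Detected prescribed herbal materials
#'
#' A PHM counts as detected when at least one of its PHS appears in the
#' detected-PHS set of at least one sample of the preparation (union
#' over samples). A PHS shared by several PHMs marks all of them
#' detected.
#'
#' @param summaries list of [audit_sample()] summaries (one
#'   preparation and barcode), or a character vector of detected PHS.
#' @param rx a [prescription()].
#' @return character vector of detected PHM names (subset of
#'   `rx$phms$phm`).
#' @export
detect_phms <- function(summaries, rx) {
  stopifnot(inherits(rx, "prescription"))
  detected_phs <- if (is.character(summaries)) {
    unique(normalize_taxon(summaries))
  } else {
    unique(unlist(lapply(summaries, function(s) s$phs)))
  }
  hit <- vapply(rx$phms$phs, function(p) any(p %in% detected_phs),
                logical(1L))
  rx$phms$phm[hit]
}

# round half-up to `digits` decimals (so 77.75 -> 77.8, unlike the
# banker's rounding of round())
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Detection sensitivity (percent)
#'
#' Sensitivity is the number of detected PHMs over the number of PHMs
#' detectable in theory (all herbal PHMs of the prescription),
#' expressed as a percentage rounded half-up to one decimal.
#'
#' `sensitivity_pct()` is the bare arithmetic on counts;
#' `sensitivity()` takes a detected PHM set and a prescription.
#'
#' @param n_detected,n_total detected and total PHM counts.
#' @return percentage in `[0, 100]`, one decimal.
#' @examples
#' sensitivity_pct(25, 36) # 69.4
#' @export
sensitivity_pct <- function(n_detected, n_total) {
  stopifnot(n_total >= 1L, n_detected >= 0L, n_detected <= n_total)
  round_half_up(100 * n_detected / n_total, 1L)
}

#' @rdname sensitivity_pct
#' @param detected_phms character vector of detected PHM names; must be
#'   a subset of the prescription's PHMs.
#' @param rx a [prescription()].
#' @export
sensitivity <- function(detected_phms, rx) {
  stopifnot(inherits(rx, "prescription"))
  detected_phms <- unique(detected_phms)
  if (!all(detected_phms %in% rx$phms$phm)) {
    stop("detected PHMs outside the prescription: ",
         paste(setdiff(detected_phms, rx$phms$phm), collapse = ", "))
  }
  sensitivity_pct(length(detected_phms), nrow(rx$phms))
}

#' Per-preparation detection report
#'
#' The headline object of the audit: which PHS were detected anywhere
#' in the preparation's samples under one barcode (or the union of
#' barcodes), which PHMs they cover, and the resulting sensitivity.
#'
#' @param detected_phs character vector of detected PHS (union over
#'   samples), or a list of [audit_sample()] summaries.
#' @param rx a [prescription()].
#' @param barcode barcode label, or `"UNION"`.
#' @return object of class `"detection_report"`: list with
#'   `preparation`, `barcode`, `detected_phs`, `detected_phms`,
#'   `n_phms_total`, `sensitivity_pct`.
#' @export
detection_report <- function(detected_phs, rx, barcode = "ITS2") {
  if (!is.character(detected_phs)) {
    detected_phs <- unique(
      unlist(lapply(detected_phs, function(s) s$phs))
    )
  } else {
    detected_phs <- unique(normalize_taxon(detected_phs))
    detected_phs <- detected_phs[!is.na(detected_phs)]
  }
  phms <- detect_phms(detected_phs, rx)
  structure(
    list(
      preparation = rx$preparation,
      barcode = if (identical(barcode, "UNION")) "UNION"
                else match_barcode(barcode),
      detected_phs = sort(detected_phs),
      detected_phms = sort(phms),
      n_phms_total = nrow(rx$phms),
      sensitivity_pct = sensitivity(phms, rx)
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat(
    sprintf(
      "Detection report %s [%s]: %d PHS covering %d/%d PHMs, sensitivity %.1f%%\n",
      x$preparation, x$barcode, length(x$detected_phs),
      length(x$detected_phms), x$n_phms_total, x$sensitivity_pct
    )
  )
  invisible(x)
}

#' Union of per-barcode detection reports
#'
#' Pools the detected PHS of several barcodes of the same preparation
#' and recomputes covered PHMs and sensitivity; combining a short
#' degradation-tolerant barcode with a high-resolution one detects more
#' than either alone.
#'
#' @param reports list of [detection_report()]s sharing a preparation.
#' @param rx the shared [prescription()].
#' @return a [detection_report()] with barcode `"UNION"`.
#' @export
union_barcodes <- function(reports, rx) {
  preps <- unique(vapply(reports, function(r) r$preparation, ""))
  if (length(preps) != 1L || !identical(preps, rx$preparation)) {
    stop("reports must all belong to prescription '", rx$preparation,
         "'")
  }
  phs <- sort(unique(unlist(lapply(reports, function(r) r$detected_phs))))
  detection_report(phs, rx, barcode = "UNION")
}

#' Binary PHS presence matrix
#'
#' Rows are samples, columns the prescription's full PHS universe; an
#' entry is 1 iff that PHS survives threshold filtering in that sample.
#' The companion relative-abundance matrix over the same columns is
#' attached as attribute `"rel"`.
#'
#' @param tab a threshold-filtered [abundance_table()].
#' @param rx a [prescription()].
#' @return integer 0/1 matrix, samples x PHS.
#' @export
presence_matrix <- function(tab, rx) {
  stopifnot(inherits(tab, "abundance_table"),
            inherits(rx, "prescription"))
  species <- rx$phs_universe
  m <- matrix(
    0L, nrow = nrow(tab$counts), ncol = length(species),
    dimnames = list(rownames(tab$counts), species)
  )
  rel <- matrix(
    0, nrow = nrow(tab$counts), ncol = length(species),
    dimnames = list(rownames(tab$counts), species)
  )
  common <- intersect(colnames(tab$counts), species)
  if (length(common)) {
    m[, common] <- (tab$counts[, common, drop = FALSE] > 0L) * 1L
    r <- tab$rel[, common, drop = FALSE]
    r[is.na(r)] <- 0
    rel[, common] <- r
  }
  attr(m, "rel") <- rel
  m
}

#' Serialize a detection report
#'
#' @param report a [detection_report()].
#' @param path output path; `.json` for machine-readable, anything else
#'   gets a human-readable TSV.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(
      unclass(report), path, auto_unbox = TRUE, digits = NA
    )
  } else {
    lines <- c(
      sprintf("preparation\t%s", report$preparation),
      sprintf("barcode\t%s", report$barcode),
      sprintf("sensitivity_pct\t%.1f", report$sensitivity_pct),
      sprintf("n_phms_total\t%d", report$n_phms_total),
      sprintf("detected_phms\t%s",
              paste(report$detected_phms, collapse = "; ")),
      sprintf("detected_phs\t%s",
              paste(report$detected_phs, collapse = "; "))
    )
    writeLines(lines, path)
  }
  invisible(path)
}
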