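#' Build a prescription object
#'
#' A prescription is the reference frame of the audit: the mapping from
#' each prescribed herbal material (PHM) of a preparation to its accepted
#' source species (PHS). A PHM may have several PHS (e.g. licorice has
#' three Glycyrrhiza species) and one PHS may serve several PHMs, so the
#' mapping is many-to-many. The `processed` flag marks materials that are
#' decocted, stir-fried or otherwise heat-treated before formulation;
#' their DNA is expected to be degraded.
#'
#' @param preparation preparation name (e.g. `"YGW"`).
#' @param phm character vector of material names, one per entry; must be
#'   unique.
#' @param phs list of character vectors, the PHS of each material; names
#'   are normalized with [normalize_taxon()]. Every entry must be
#'   non-empty.
#' @param processed logical vector, one flag per material (default all
#'   `FALSE`).
#' @return an object of class `"prescription"`: a list with `preparation`,
#'   `phms` (data.frame of `phm`, `processed` plus a list-column `phs`),
#'   and the derived `phs_universe` and `phs_genera` sets.
#' @examples
#' rx <- prescription(
#'   "DEMO",
#'   phm = c("root A", "bark B"),
#'   phs = list("Paeonia lactiflora", c("Glycyrrhiza uralensis", "Glycyrrhiza glabra"))
#' )
#' rx$phs_universe
#' @export
prescription <- function(preparation, phm, phs, processed = FALSE) {
  stopifnot(is.character(preparation), length(preparation) == 1L)
  phm <- as.character(phm)
  if (length(phm) < 1L) {
    stop("a prescription needs at least one PHM")
  }
  if (anyDuplicated(phm)) {
    stop(
      "duplicate PHM name(s): ",
      paste(unique(phm[duplicated(phm)]), collapse = ", ")
    )
  }
  if (!is.list(phs) || length(phs) != length(phm)) {
    stop("'phs' must be a list with one character vector per PHM")
  }
  phs <- lapply(phs, function(p) {
    p <- unique(normalize_taxon(p))
    p <- p[!is.na(p)]
    p
  })
  if (any(lengths(phs) == 0L)) {
    stop(
      "PHM with empty PHS list: ",
      paste(phm[lengths(phs) == 0L], collapse = ", ")
    )
  }
  processed <- rep_len(as.logical(processed), length(phm))
  phms <- data.frame(phm = phm, processed = processed,
                     stringsAsFactors = FALSE)
  phms$phs <- phs
  universe <- sort(unique(unlist(phs, use.names = FALSE)))
  structure(
    list(
      preparation = preparation,
      phms = phms,
      phs_universe = universe,
      phs_genera = sort(unique(genus_of(universe)))
    ),
    class = "prescription"
  )
}

#' @export
print.prescription <- function(x, ...) {
  cat(
    sprintf(
      "Prescription '%s': %d PHM(s), %d PHS, %d genera (%d processed PHM)\n",
      x$preparation, nrow(x$phms), length(x$phs_universe),
      length(x$phs_genera), sum(x$phms$processed)
    )
  )
  for (i in seq_len(nrow(x$phms))) {
    cat(
      sprintf(
        "  %s%s: %s\n", x$phms$phm[i],
        if (x$phms$processed[i]) " [processed]" else "",
        paste(x$phms$phs[[i]], collapse = "; ")
      )
    )
  }
  invisible(x)
}

#' Read a prescription file
#'
#' Two dialects are accepted, selected by file extension:
#' \describe{
#'   \item{TSV}{columns `preparation`, `phm`, `phs` (semicolon-separated
#'     species list) and optionally `processed` (logical); one row per
#'     PHM. Lines starting with `#` are comments.}
#'   \item{JSON}{an object with fields `preparation` and `phms`, the
#'     latter an array of `{phm, phs (array), processed}` records.}
#' }
#' Species names are normalized on load (see [normalize_taxon()]).
#'
#' @param path path to a `.tsv`/`.txt` or `.json` file.
#' @return a [prescription()] object.
#' @export
load_prescription <- function(path) {
  if (!file.exists(path)) {
    stop("prescription file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$preparation) || is.null(obj$phms)) {
      stop("JSON prescription needs 'preparation' and 'phms' fields")
    }
    phm <- vapply(obj$phms, function(e) as.character(e$phm %||% NA), "")
    if (anyNA(phm)) stop("every PHM record needs a 'phm' name")
    phs <- lapply(obj$phms, function(e) unlist(e$phs, use.names = FALSE))
    processed <- vapply(
      obj$phms, function(e) isTRUE(e$processed), logical(1L)
    )
    return(prescription(obj$preparation, phm, phs, processed))
  }
  df <- utils::read.delim(
    path, comment.char = "#", stringsAsFactors = FALSE,
    colClasses = "character"
  )
  need <- c("preparation", "phm", "phs")
  if (!all(need %in% names(df))) {
    stop(
      "prescription TSV needs columns: ", paste(need, collapse = ", ")
    )
  }
  prep <- unique(df$preparation)
  if (length(prep) != 1L) {
    stop("prescription file must describe exactly one preparation")
  }
  phs <- lapply(strsplit(df$phs, ";", fixed = TRUE), trimws)
  processed <- if ("processed" %in% names(df)) {
    toupper(trimws(df$processed)) %in% c("TRUE", "T", "1", "YES")
  } else {
    FALSE
  }
  prescription(prep, df$phm, phs, processed)
}

#' Classify detected species against a prescription
#'
#' Every species observed in a sample falls into exactly one of three
#' classes relative to a prescription: a prescribed herbal species (PHS)
#' if it is itself prescribed; a substituted herbal species (SHS) if it
#' shares a genus with some PHS without being prescribed; otherwise a
#' contaminated herbal species (CHS).
#'
#' A name without a recognizable epithet (e.g. a bare genus) cannot be a
#' PHS and is classified by its genus alone, with a warning.
#'
#' @param species character vector of species names (normalized
#'   internally).
#' @param rx a [prescription()].
#' @return factor with levels `PHS`, `SHS`, `CHS`, one per input name.
#' @examples
#' rx <- prescription("DEMO", "goji", list("Lycium barbarum"))
#' classify_species(c("Lycium barbarum", "Lycium chinense", "Oryza sativa"), rx)
#' @export
classify_species <- function(species, rx) {
  stopifnot(inherits(rx, "prescription"))
  sp <- normalize_taxon(species)
  if (any(!has_epithet(sp) & !is.na(sp))) {
    warning(
      "genus-only name(s) classified by genus match: ",
      paste(unique(sp[!has_epithet(sp) & !is.na(sp)]), collapse = ", ")
    )
  }
  out <- ifelse(
    sp %in% rx$phs_universe, "PHS",
    ifelse(genus_of(sp) %in% rx$phs_genera, "SHS", "CHS")
  )
  factor(out, levels = c("PHS", "SHS", "CHS"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
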