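#' Normalize botanical names to "Genus epithet"
#'
#' Pharmacopoeia tables and reference databases mix authority strings
#' ("Lycium barbarum L.", "Cornus officinalis Sieb. et Zucc"), infraspecific
#' qualifiers ("var.", "subsp.") and inconsistent case. Matching throughout
#' the package is on the first two tokens after normalization: the genus
#' (capitalized) and the specific epithet (lower case). No synonym
#' resolution is attempted.
#'
#' A token that looks like an authority (capitalized, or containing a
#' period) is not accepted as an epithet, so "Citrus L." normalizes to the
#' bare genus "Citrus". Underscores are treated as spaces so database
#' identifiers like `Lycium_barbarum` parse directly.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names; a bare genus when no
#'   epithet is recognized; `NA` for empty input strings.
#' @examples
#' normalize_taxon("Lycium barbarum L.")
#' normalize_taxon("Aconitum carmichaelii Debx")
#' normalize_taxon("Rheum palmatum var. tanguticum")
#' @export
normalize_taxon <- function(x) {
  x <- as.character(x)
  # names repeat heavily in per-read tables: normalize unique values only
  ux <- unique(x)
  out <- normalize_taxon_1(ux)
  out[match(x, ux)]
}

normalize_taxon_1 <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- trimws(gsub("\\s+", " ", x))
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    if (length(tok) == 0L) {
      return(NA_character_)
    }
    genus <- paste0(
      toupper(substr(tok[1L], 1L, 1L)),
      tolower(substring(tok[1L], 2L))
    )
    if (length(tok) == 1L) {
      return(genus)
    }
    ep <- tok[2L]
    # authority abbreviations are capitalized and/or dotted; qualifiers
    # like "var."/"subsp." also fail this test, dropping the infraspecific
    # part so only the first two tokens are compared
    if (grepl("^[A-Z]", ep) || grepl(".", ep, fixed = TRUE)) {
      return(genus)
    }
    paste(genus, tolower(ep))
  }, character(1L))
}

#' Genus of a normalized name
#'
#' @param x character vector of (normalized) binomials.
#' @return character vector of genera (first token).
#' @export
genus_of <- function(x) {
  sub(" .*$", "", as.character(x))
}

# TRUE when a normalized name carries an epithet
has_epithet <- function(x) {
  grepl(" ", x, fixed = TRUE)
}
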