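#' Load a 12-column tabular alignment hit file
#'
#' Reads the standard 12-column tabular local-alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`, as emitted with `-outfmt 6`). Subjects are
#' resolved to species names either directly (underscores read as
#' spaces, e.g. `Lycium_barbarum`) or through a sidecar id-to-species
#' map. Hits with e-value above `max_evalue` are discarded at load.
#'
#' @param path hit file (TSV, no header; `#` comment lines ignored).
#' @param species_map optional data.frame with columns `subject`,
#'   `species`, or path to such a TSV. Subjects absent from the map are
#'   dropped with a warning.
#' @param max_evalue e-value cutoff (default `1e-10`).
#' @return data.frame of class `"hit_table"` with columns `read_id`,
#'   `species` (normalized), `identity`, `bitscore`, `evalue`.
#' @export
load_hit_table <- function(path, species_map = NULL, max_evalue = 1e-10) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  dt <- if (file.size(path) == 0L) {
    data.frame()
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      data.table = FALSE, showProgress = FALSE)
  }
  if (nrow(dt) == 0L) {
    return(hit_table(character(0), character(0), numeric(0),
                     numeric(0), numeric(0)))
  }
  if (ncol(dt) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(dt))
  }
  names(dt) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  for (col in c("pident", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    if (anyNA(v)) {
      stop(
        "malformed numeric field '", col, "' at line ",
        which(is.na(v))[1L]
      )
    }
    dt[[col]] <- v
  }
  species <- dt$sseqid
  if (!is.null(species_map)) {
    if (is.character(species_map) && length(species_map) == 1L) {
      species_map <- utils::read.delim(species_map,
                                       stringsAsFactors = FALSE)
    }
    idx <- match(species, species_map$subject)
    unresolved <- is.na(idx)
    if (any(unresolved)) {
      warning(
        sum(unresolved), " hit(s) with unresolvable subject id dropped"
      )
    }
    species <- species_map$species[idx]
    dt <- dt[!unresolved, , drop = FALSE]
    species <- species[!unresolved]
  }
  keep <- dt$evalue <= max_evalue
  hit_table(dt$qseqid[keep], species[keep], dt$pident[keep],
            dt$bitscore[keep], dt$evalue[keep])
}

#' Construct a hit table in memory
#'
#' @param read_id,species,identity,bitscore,evalue parallel vectors; one
#'   row per candidate alignment.
#' @return data.frame of class `"hit_table"`.
#' @export
hit_table <- function(read_id, species, identity, bitscore, evalue) {
  stopifnot(all(bitscore >= 0), all(evalue >= 0))
  df <- data.frame(
    read_id = as.character(read_id),
    species = normalize_taxon(species),
    identity = as.numeric(identity),
    bitscore = as.numeric(bitscore),
    evalue = as.numeric(evalue),
    stringsAsFactors = FALSE
  )
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Assign all reads of a sample with the prescribed-species-preferred rule
#'
#' For each read, among its (e-value-filtered) candidate hits: if any
#' candidate species is prescribed (a PHS of `rx`), the PHS hit with the
#' highest score wins; otherwise the overall top-scored hit wins. Ties
#' are broken deterministically: higher species class (PHS > SHS > CHS),
#' then lower e-value, then lexicographically smaller species name.
#' Reads without any hit are `UNASSIGNED`.
#'
#' @param hits a [hit_table()] covering one sample and barcode.
#' @param rx a [prescription()].
#' @param read_ids optional character vector of all read ids in the
#'   sample; ids absent from `hits` are reported as `UNASSIGNED`.
#' @param score which column ranks hits: `"bitscore"` (default) or
#'   `"identity"`.
#' @return list with `assignments` (data.frame `read_id`, `species`
#'   (`NA` = unassigned), `category`, `bitscore`) and `counts` (named
#'   integer vector of reads per winning species) and `n_unassigned`.
#' @export
assign_sample <- function(hits, rx, read_ids = NULL,
                          score = c("bitscore", "identity")) {
  score <- match.arg(score)
  stopifnot(inherits(rx, "prescription"))
  if (nrow(hits) > 0L) {
    cat_ <- classify_species(hits$species, rx)
    rank_cat <- as.integer(cat_) # PHS=1 < SHS=2 < CHS=3
    s <- hits[[score]]
    ord <- order(hits$read_id, rank_cat != 1L, -s, rank_cat,
                 hits$evalue, hits$species, method = "radix")
    first <- !duplicated(hits$read_id[ord])
    win <- ord[first]
    assignments <- data.frame(
      read_id = hits$read_id[win],
      species = hits$species[win],
      category = as.character(cat_[win]),
      bitscore = hits$bitscore[win],
      stringsAsFactors = FALSE
    )
  } else {
    assignments <- data.frame(
      read_id = character(0), species = character(0),
      category = character(0), bitscore = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  n_unassigned <- 0L
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, assignments$read_id)
    n_unassigned <- length(missing)
    if (n_unassigned) {
      assignments <- rbind(assignments, data.frame(
        read_id = missing, species = NA_character_,
        category = NA_character_, bitscore = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
  }
  counts_tab <- table(assignments$species[!is.na(assignments$species)])
  counts <- stats::setNames(as.integer(counts_tab), names(counts_tab))
  list(assignments = assignments, counts = counts,
       n_unassigned = n_unassigned)
}

#' Assign one read
#'
#' Single-read convenience wrapper around the vectorized
#' [assign_sample()] rule (the rule lives in one place).
#'
#' @param hits [hit_table()] rows for one read; may be empty.
#' @param rx a [prescription()].
#' @param score ranking column, see [assign_sample()].
#' @return list with `read_id`, `species` (`NA` when unassigned),
#'   `category` and `bitscore`.
#' @export
assign_read <- function(hits, rx, score = "bitscore") {
  if (nrow(hits) == 0L) {
    return(list(read_id = NA_character_, species = NA_character_,
                category = NA_character_, bitscore = NA_real_))
  }
  if (length(unique(hits$read_id)) != 1L) {
    stop("assign_read expects hits of exactly one read")
  }
  res <- assign_sample(hits, rx, score = score)
  as.list(res$assignments[1L, ])
}

#' Write a hit table in 12-column tabular format
#'
#' Companion to [load_hit_table()]; fields not tracked by the package
#' (alignment coordinates, mismatch/gap counts) are emitted as zeros,
#' alignment length as the rounded identity-weighted placeholder.
#'
#' @param hits a [hit_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$read_id,
    sseqid = gsub(" ", "_", hits$species, fixed = TRUE),
    pident = hits$identity, length = 0L, mismatch = 0L, gapopen = 0L,
    qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = hits$evalue, bitscore = hits$bitscore
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
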