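#' Sample-by-species abundance table
#'
#' Thin S3 container around an integer count matrix (samples in rows,
#' species in columns) tagged with its barcode. Relative abundances are
#' recomputed from counts on construction; all-zero rows keep `NaN`
#' relative abundances and are flagged in the `zero_rows` attribute.
#'
#' @param counts integer matrix, samples x species, with dimnames.
#' @param barcode `"ITS2"` or `"trnL"`.
#' @return object of class `"abundance_table"`: list with `counts`,
#'   `rel`, `barcode`.
#' @export
abundance_table <- function(counts, barcode = "ITS2") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs sample rownames and species colnames")
  }
  tot <- rowSums(counts)
  rel <- counts / tot # rows with tot 0 become NaN, deliberately
  structure(
    list(counts = counts, rel = rel, barcode = match_barcode(barcode)),
    zero_rows = rownames(counts)[tot == 0L],
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(
    sprintf(
      "Abundance table [%s]: %d sample(s) x %d species, %s reads\n",
      x$barcode, nrow(x$counts), ncol(x$counts),
      format(sum(x$counts), big.mark = ",")
    )
  )
  invisible(x)
}

#' Build an abundance table from per-sample assignment counts
#'
#' @param sample_counts named list: per sample, a named integer vector
#'   of reads per species (the `counts` element of [assign_sample()]).
#'   Unassigned reads are not part of these tallies.
#' @param barcode barcode label.
#' @return an [abundance_table()]; species set is the union over
#'   samples, absent species filled with 0.
#' @export
build_table <- function(sample_counts, barcode = "ITS2") {
  stopifnot(is.list(sample_counts), length(sample_counts) > 0L,
            !is.null(names(sample_counts)))
  species <- sort(unique(unlist(lapply(sample_counts, names))))
  m <- matrix(
    0L, nrow = length(sample_counts), ncol = length(species),
    dimnames = list(names(sample_counts), species)
  )
  for (s in names(sample_counts)) {
    v <- sample_counts[[s]]
    if (length(v)) m[s, names(v)] <- as.integer(v)
  }
  abundance_table(m, barcode)
}

#' Default per-barcode relative-abundance thresholds
#'
#' ITS2 species below 0.002 and trnL species below 0.001 relative
#' abundance are discarded per sample; the trnL cutoff is lower because
#' its reference database is smaller.
#'
#' @param barcode barcode label.
#' @return numeric threshold.
#' @export
abundance_threshold <- function(barcode) {
  if (match_barcode(barcode) == "ITS2") 0.002 else 0.001
}

#' Discard low-relative-abundance species per sample
#'
#' Within each sample, species whose relative abundance is strictly
#' below the threshold have their reads removed in that sample (species
#' exactly at the threshold are kept), and relative abundances are
#' recomputed over the retained reads. One pass by default; recomputing
#' can push further species below the threshold, so an optional
#' fixpoint mode iterates until stable.
#'
#' @param tab an [abundance_table()].
#' @param min_rel threshold; default [abundance_threshold()] of the
#'   table's barcode.
#' @param pooled apply the threshold to the pooled (all-sample) relative
#'   abundance instead of per sample (default `FALSE`).
#' @param iterate iterate to fixpoint (default `FALSE`: single pass).
#' @return filtered [abundance_table()].
#' @export
threshold_filter <- function(tab, min_rel = NULL, pooled = FALSE,
                             iterate = FALSE) {
  stopifnot(inherits(tab, "abundance_table"))
  if (is.null(min_rel)) min_rel <- abundance_threshold(tab$barcode)
  counts <- tab$counts
  repeat {
    tot <- rowSums(counts)
    if (pooled) {
      prel <- colSums(counts) / sum(counts)
      drop_mat <- matrix(
        rep(prel < min_rel, each = nrow(counts)), nrow = nrow(counts)
      )
    } else {
      rel <- counts / tot
      drop_mat <- !is.na(rel) & rel < min_rel
    }
    if (!any(drop_mat & counts > 0L)) break
    counts[drop_mat] <- 0L
    if (!iterate) break
  }
  keep_sp <- colSums(counts) > 0L
  # keep at least the matrix shape sane when everything is filtered
  counts <- counts[, keep_sp, drop = FALSE]
  abundance_table(counts, tab$barcode)
}

#' Rarefaction curve of one sample
#'
#' Subsamples the reads of one sample without replacement (exact
#' multivariate hypergeometric draws) at increasing depths and records
#' the mean and standard deviation of the number of distinct species
#' over replicate draws. Within each replicate the draws are nested
#' (one random read permutation, truncated at each depth), so every
#' replicate curve -- and hence the mean curve -- is non-decreasing.
#'
#' @param counts named integer vector of reads per species for one
#'   sample.
#' @param depths increasing subsampling depths; default a 100-read step
#'   grid up to the row total.
#' @param replicates number of replicate draws (default 10).
#' @param seed RNG seed, recorded in the result.
#' @return object of class `"rarefaction_curve"`: data.frame with
#'   `depth`, `mean_richness`, `sd_richness`; attributes `replicates`,
#'   `seed`.
#' @export
rarefy <- function(counts, depths = NULL, replicates = 10L, seed = 1L) {
  counts <- counts[counts > 0L]
  total <- sum(counts)
  stopifnot(total > 0L)
  if (is.null(depths)) {
    depths <- unique(c(seq(100L, total, by = 100L), total))
    depths <- depths[depths >= 1L]
    if (length(depths) == 0L) depths <- total
  }
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1L) || any(depths > total)) {
    stop("depths must lie in [1, total reads] (total = ", total, ")")
  }
  pool <- rep.int(seq_along(counts), counts)
  rich <- matrix(0L, nrow = replicates, ncol = length(depths))
  withr_seed(seed, {
    for (r in seq_len(replicates)) {
      perm <- pool[sample.int(total, total)]
      cum_new <- cumsum(!duplicated(perm))
      rich[r, ] <- cum_new[depths]
    }
  })
  out <- data.frame(
    depth = depths,
    mean_richness = colMeans(rich),
    sd_richness = apply(rich, 2L, stats::sd)
  )
  structure(out, replicates = replicates, seed = seed,
            class = c("rarefaction_curve", "data.frame"))
}

# evaluate `code` under a local RNG seed without disturbing the caller's
# RNG stream
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Write / read abundance tables as TSV
#'
#' The TSV holds the count matrix (first column `sample`); a JSON
#' sidecar (`<path>.json`) records the barcode and threshold
#' provenance.
#'
#' @param tab an [abundance_table()].
#' @param path output TSV path.
#' @param provenance optional list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(tab, path, provenance = list()) {
  df <- data.frame(sample = rownames(tab$counts), tab$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- c(list(barcode = tab$barcode,
                 default_threshold = abundance_threshold(tab$barcode)),
            provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_abundance
#' @param barcode barcode label used when the sidecar is absent.
#' @export
read_abundance <- function(path, barcode = NULL) {
  side_path <- paste0(path, ".json")
  if (is.null(barcode)) {
    if (!file.exists(side_path)) {
      stop("no sidecar found; pass `barcode` explicitly")
    }
    barcode <- jsonlite::read_json(side_path)$barcode
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sample
  abundance_table(m, barcode)
}
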