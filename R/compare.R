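#' Euclidean distances between samples on PHS presence
#'
#' For binary presence rows the squared Euclidean distance equals the
#' Hamming distance (number of PHS present in exactly one of the two
#' samples), so d(i, j) = sqrt(#disagreements).
#'
#' @param pm binary matrix (samples x species), e.g. from
#'   [presence_matrix()]; relative-abundance input is accepted too, in
#'   which case this is plain Euclidean distance.
#' @return a symmetric distance matrix (base `"dist"` object).
#' @export
euclidean_distances <- function(pm) {
  pm <- as.matrix(pm)
  if (nrow(pm) < 2L) stop("need at least 2 samples")
  stats::dist(pm, method = "euclidean")
}

#' Hierarchical clustering of a sample distance matrix
#'
#' @param dm a `"dist"` object or symmetric distance matrix.
#' @param linkage agglomeration method: `"complete"` (default),
#'   `"average"`, `"ward.D2"` or `"single"`.
#' @return an `hclust` tree (deterministic for identical input).
#' @export
hierarchical_cluster <- function(dm, linkage = "complete") {
  linkage <- match.arg(linkage,
                       c("complete", "average", "ward.D2", "single"))
  if (!inherits(dm, "dist")) dm <- stats::as.dist(as.matrix(dm))
  stats::hclust(dm, method = linkage)
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Distance-cutoff network edges
#'
#' Every unordered sample pair with distance at or below the cutoff
#' becomes an edge (the network view of sample similarity; typical
#' cutoffs are 5.0 for ITS2 and 4.2 for trnL presence distances). No
#' self-edges; each pair listed once.
#'
#' @param dm a `"dist"` object or symmetric matrix.
#' @param cutoff positive distance cutoff.
#' @return data.frame with columns `sample_a`, `sample_b`, `distance`,
#'   importable by network-visualization tools.
#' @export
network_edges <- function(dm, cutoff) {
  stopifnot(cutoff > 0)
  m <- as.matrix(dm)
  labs <- rownames(m)
  idx <- which(upper.tri(m) & m <= cutoff, arr.ind = TRUE)
  out <- data.frame(
    sample_a = labs[idx[, 1L]],
    sample_b = labs[idx[, 2L]],
    distance = m[idx],
    stringsAsFactors = FALSE
  )
  out[order(out$sample_a, out$sample_b), , drop = FALSE]
}

#' Principal component analysis with a fixed sign convention
#'
#' Column-centered, unscaled PCA (via [stats::prcomp()]). To make
#' reruns byte-identical, each component's sign is fixed so that its
#' largest-magnitude loading is positive. Works on presence matrices or
#' relative-abundance tables; a constant input yields all-zero scores
#' with a warning.
#'
#' @param x numeric matrix (samples x features) or
#'   [abundance_table()] (its `rel` slot is used).
#' @param n_components number of components to keep.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions, non-increasing) and `rotation`.
#' @export
pca_scores <- function(x, n_components = 2L) {
  if (inherits(x, "abundance_table")) {
    x <- x$rel
    x[is.na(x)] <- 0
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 samples and 2 features")
  }
  if (all(apply(x, 2L, function(col) diff(range(col)) == 0))) {
    warning("constant matrix: returning all-zero scores")
    k <- min(n_components, nrow(x) - 1L, ncol(x))
    return(list(
      scores = matrix(0, nrow(x), k,
                      dimnames = list(rownames(x),
                                      paste0("PC", seq_len(k)))),
      explained = rep(0, k),
      rotation = matrix(0, ncol(x), k)
    ))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sco <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  list(
    scores = sco,
    explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)],
    rotation = rot
  )
}

#' Write a distance matrix as TSV
#'
#' @param dm `"dist"` or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path) {
  m <- as.matrix(dm)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
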