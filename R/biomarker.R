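#' Effect size of a single feature between two groups
#'
#' A simplified one-dimensional analogue of the LDA effect size used in
#' differential-abundance screening: relative abundances are rescaled
#' to counts-per-million and the effect size is `log10` of the absolute
#' difference of the two group means on that scale (floored at 1, so
#' the score is never negative). A score of 4 corresponds to a 1%
#' absolute difference in relative abundance.
#'
#' @param x numeric vector of per-sample relative abundances.
#' @param labels two-level factor/character vector of group labels.
#' @return non-negative effect size (log10 CPM difference).
#' @export
lda_effect_size <- function(x, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L)
  m <- tapply(x * 1e6, labels, mean)
  log10(max(abs(m[1L] - m[2L]), 1))
}

#' Differential-abundance screen for candidate markers
#'
#' A simplified single-factor reimplementation of the LEfSe screening
#' idea: a species is a candidate marker when it passes a
#' Kruskal-Wallis test at `alpha` AND its one-dimensional effect size
#' (see [lda_effect_size()]) is at least `lda_cutoff`. Each candidate
#' is tagged with the group in which its mean abundance is higher. The
#' full LEfSe procedure (subclass Wilcoxon consistency, bootstrapped
#' multivariate LDA) is deliberately not reproduced.
#'
#' @param rel numeric matrix of relative abundances (samples x
#'   species), or an [abundance_table()].
#' @param labels group label per sample (exactly 2 levels, each with
#'   at least 2 samples).
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param lda_cutoff minimum effect size (default 2.0, the customary
#'   screening cutoff; raise it to suppress sampling-noise false
#'   positives).
#' @return data.frame with columns `species`, `group` (level with the
#'   higher mean), `pvalue`, `effect_size`, sorted by decreasing
#'   effect size.
#' @export
differential_screen <- function(rel, labels, alpha = 0.05,
                                lda_cutoff = 2.0) {
  if (inherits(rel, "abundance_table")) {
    rel <- rel$rel
    rel[is.na(rel)] <- 0
  }
  rel <- as.matrix(rel)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || any(table(labels) < 2L)) {
    stop("need two groups with at least 2 samples each")
  }
  res <- lapply(colnames(rel), function(sp) {
    x <- rel[, sp]
    p <- suppressWarnings(stats::kruskal.test(x, labels)$p.value)
    es <- lda_effect_size(x, labels)
    m <- tapply(x, labels, mean)
    data.frame(
      species = sp,
      group = levels(labels)[which.max(m)],
      pvalue = if (is.na(p)) 1 else p,
      effect_size = es,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[out$pvalue < alpha & out$effect_size >= lda_cutoff, ,
             drop = FALSE]
  out <- out[order(-out$effect_size, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mutual information (bits) between two discrete vectors
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# equal-frequency discretization into `bins` bins
discretize_ef <- function(x, bins = 3L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Minimum-redundancy maximum-relevance marker ranking
#'
#' Greedy mRMR of the MID (mutual-information difference) flavour:
#' features are discretized into equal-frequency 3-bin variables;
#' the first pick maximizes relevance I(feature; label) and each
#' further pick maximizes relevance minus mean mutual information with
#' the already-selected features. Deterministic: ties break on species
#' name.
#'
#' @param candidates character vector of candidate feature (species)
#'   names, e.g. from [differential_screen()].
#' @param rel relative-abundance matrix (samples x species) or
#'   [abundance_table()].
#' @param labels group label per sample.
#' @param k maximum number of features to return (`>= 1`).
#' @param bins number of discretization bins (default 3).
#' @return character vector of up to `k` selected features, in rank
#'   order.
#' @export
mrmr_select <- function(candidates, rel, labels, k, bins = 3L) {
  if (k < 1L) stop("k must be >= 1")
  if (length(candidates) == 0L) stop("no candidate features")
  if (inherits(rel, "abundance_table")) {
    rel <- rel$rel
    rel[is.na(rel)] <- 0
  }
  rel <- as.matrix(rel)
  stopifnot(all(candidates %in% colnames(rel)))
  y <- as.integer(as.factor(labels))
  disc <- lapply(candidates, function(sp) discretize_ef(rel[, sp], bins))
  names(disc) <- candidates
  relev <- vapply(disc, mutual_information, numeric(1L), y = y)
  selected <- character(0)
  remaining <- candidates
  while (length(selected) < k && length(remaining) > 0L) {
    score <- vapply(remaining, function(sp) {
      red <- if (length(selected) == 0L) 0 else {
        mean(vapply(selected, function(s2) {
          mutual_information(disc[[sp]], disc[[s2]])
        }, numeric(1L)))
      }
      relev[[sp]] - red
    }, numeric(1L))
    best <- remaining[order(-score, remaining)][1L]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' Marker panel for the MEI score
#'
#' @param group_a,group_b character vectors of marker species for the
#'   two groups (disjoint, both non-empty when used for scoring).
#' @param provenance free-form list (screen statistics, mRMR ranks)
#'   carried along.
#' @return object of class `"marker_panel"`.
#' @export
marker_panel <- function(group_a, group_b, provenance = list()) {
  group_a <- unique(as.character(group_a))
  group_b <- unique(as.character(group_b))
  if (length(intersect(group_a, group_b))) {
    stop("marker lists must be disjoint")
  }
  structure(
    list(group_a = group_a, group_b = group_b,
         provenance = provenance),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel\n  group A:",
      paste(x$group_a, collapse = ", "), "\n  group B:",
      paste(x$group_b, collapse = ", "), "\n")
  invisible(x)
}

#' MEI score of samples under a marker panel
#'
#' The marker-evaluation index of a sample is the ratio of the summed
#' relative abundances of the group-A markers to the summed relative
#' abundances of the group-B markers. A zero denominator is replaced
#' by `epsilon`; a sample in which both sums are zero is scored 1.0
#' and flagged degenerate. The score is invariant to uniform rescaling
#' of the abundances.
#'
#' @param rel relative-abundance matrix (samples x species) or
#'   [abundance_table()]; markers absent from the matrix contribute 0.
#' @param panel a [marker_panel()] with both sides non-empty.
#' @param epsilon replacement for zero denominators (default `1e-6`).
#' @return object of class `"mei_result"`: list with `scores` (named
#'   per-sample vector), `epsilon`, `degenerate` (logical per sample).
#' @export
mei_score <- function(rel, panel, epsilon = 1e-6) {
  stopifnot(inherits(panel, "marker_panel"))
  if (length(panel$group_a) == 0L || length(panel$group_b) == 0L) {
    stop("both panel sides must be non-empty")
  }
  if (inherits(rel, "abundance_table")) {
    rel <- rel$rel
    rel[is.na(rel)] <- 0
  }
  if (is.null(dim(rel))) rel <- matrix(rel, nrow = 1L,
                                       dimnames = list("sample",
                                                       names(rel)))
  rel <- as.matrix(rel)
  sum_side <- function(markers) {
    found <- intersect(markers, colnames(rel))
    if (length(found) == 0L) {
      return(rep(0, nrow(rel)))
    }
    rowSums(rel[, found, drop = FALSE])
  }
  a <- sum_side(panel$group_a)
  b <- sum_side(panel$group_b)
  degenerate <- a == 0 & b == 0
  scores <- ifelse(degenerate, 1, a / pmax(b, epsilon))
  names(scores) <- rownames(rel)
  structure(
    list(scores = scores, epsilon = epsilon, degenerate = degenerate),
    class = "mei_result"
  )
}

#' ROC analysis of a score against binary labels
#'
#' AUC by the rank (Mann-Whitney) formulation with midranks for ties:
#' the probability that a random positive sample scores above a random
#' negative one (ties count half). Accuracy and F1 are evaluated at
#' the Youden-optimal threshold of the rule `score >= t` predicts
#' positive, with the threshold grid being the unique observed scores.
#'
#' @param scores numeric score per sample (e.g. [mei_score()]
#'   `$scores`).
#' @param labels binary labels; `positive` names the positive level.
#' @param positive positive class label (default: first factor level).
#' @return object of class `"roc_result"`: list with `auc`,
#'   `threshold`, `accuracy`, `f1`, and `points` (data.frame of
#'   threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L) stop("both classes must be present")
  if (is.null(positive)) positive <- levels(labels)[1L]
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores) # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  grid <- sort(unique(scores))
  pts <- do.call(rbind, lapply(grid, function(t) {
    pred <- scores >= t
    data.frame(
      threshold = t,
      tpr = sum(pred & pos) / n1,
      fpr = sum(pred & !pos) / n0
    )
  }))
  j <- pts$tpr - pts$fpr
  best <- which.max(j)
  t_star <- pts$threshold[best]
  pred <- scores >= t_star
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  acc <- mean(pred == pos)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(
    list(auc = auc, threshold = t_star, accuracy = acc, f1 = f1,
         points = pts),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(
    sprintf(
      "ROC: AUC %.3f, accuracy %.3f, F1 %.3f at threshold %.4g\n",
      x$auc, x$accuracy, x$f1, x$threshold
    )
  )
  invisible(x)
}

#' Prune weak markers by single-marker AUC
#'
#' Each marker is evaluated alone against the complete opposing panel
#' side: for an A-side marker the score is its abundance over the
#' summed B-panel abundance (and symmetrically for B-side markers,
#' where the MEI orientation keeps group A as the positive class).
#' Markers with AUC strictly below 0.5 (worse than chance for their own
#' side) are removed; AUC exactly 0.5 is retained.
#'
#' @param panel a [marker_panel()].
#' @param rel relative-abundance matrix or [abundance_table()].
#' @param labels group label per sample.
#' @param positive label of the group corresponding to the panel's A
#'   side (default: first factor level).
#' @param epsilon passed to [mei_score()].
#' @return pruned [marker_panel()]; the removed markers are recorded in
#'   `provenance$pruned`.
#' @export
prune_markers <- function(panel, rel, labels, positive = NULL,
                          epsilon = 1e-6) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[1L]
  marker_auc <- function(marker, side) {
    sub <- if (side == "a") {
      marker_panel(marker, panel$group_b)
    } else {
      marker_panel(panel$group_a, marker)
    }
    s <- mei_score(rel, sub, epsilon)$scores
    roc_auc(s, labels, positive = positive)$auc
  }
  auc_a <- vapply(panel$group_a, marker_auc, numeric(1L), side = "a")
  auc_b <- vapply(panel$group_b, marker_auc, numeric(1L), side = "b")
  keep_a <- panel$group_a[auc_a >= 0.5]
  keep_b <- panel$group_b[auc_b >= 0.5]
  pruned <- c(panel$group_a[auc_a < 0.5], panel$group_b[auc_b < 0.5])
  if (length(keep_a) == 0L || length(keep_b) == 0L) {
    stop("pruning emptied one panel side; re-screen with different ",
         "parameters")
  }
  marker_panel(
    keep_a, keep_b,
    provenance = c(panel$provenance,
                   list(pruned = pruned,
                        auc = c(auc_a, auc_b)))
  )
}
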