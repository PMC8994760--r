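# Independent brute-force oracles, kept deliberately naive and separate
# from the package's vectorized implementations.

# species class by direct set membership (no package classify call)
oracle_category <- function(species, rx) {
  g <- sub(" .*$", "", species)
  if (species %in% rx$phs_universe) "PHS"
  else if (g %in% rx$phs_genera) "SHS"
  else "CHS"
}

# assignment rule by explicit pairwise comparison over all hits
oracle_assign <- function(hits, rx) {
  if (nrow(hits) == 0L) return(NA_character_)
  cat_rank <- c(PHS = 1L, SHS = 2L, CHS = 3L)
  best <- NULL
  for (i in seq_len(nrow(hits))) {
    h <- list(
      species = hits$species[i], bitscore = hits$bitscore[i],
      evalue = hits$evalue[i],
      rank = cat_rank[[oracle_category(hits$species[i], rx)]]
    )
    if (is.null(best)) {
      best <- h
      next
    }
    a_phs <- h$rank == 1L
    b_phs <- best$rank == 1L
    better <-
      if (a_phs != b_phs) a_phs
      else if (h$bitscore != best$bitscore) h$bitscore > best$bitscore
      else if (h$rank != best$rank) h$rank < best$rank
      else if (h$evalue != best$evalue) h$evalue < best$evalue
      else h$species < best$species
    if (better) best <- h
  }
  best$species
}

# all length-w substrings, one by one
oracle_window_fail <- function(qual, w = 5L, min_q = 20) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  if (n == 0L) return(FALSE)
  if (n < w) return(mean(q) < min_q)
  for (s in seq_len(n - w + 1L)) {
    if (mean(q[s:(s + w - 1L)]) < min_q) return(TRUE)
  }
  FALSE
}

# expected rarefied richness, multivariate hypergeometric closed form
oracle_rarefied_richness <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

# AUC as concordant-pair fraction (ties count 1/2)
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) {
    for (b in sn) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# naive complete-linkage agglomeration returning sorted merge heights
oracle_complete_heights <- function(d) {
  m <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(m[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# discrete mutual information in bits (independent of the package's)
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total +
          p[i, j] * log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
      }
    }
  }
  total
}
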