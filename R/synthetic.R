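#' Default amplification primers per barcode
#'
#' The standard plant-barcode primer pairs: S2F/ITS4 for ITS2 and the
#' c/h pair for the chloroplast trnL intron.
#'
#' @param barcode barcode label.
#' @return list with `fwd`, `rev`.
#' @export
default_primers <- function(barcode = "ITS2") {
  if (match_barcode(barcode) == "ITS2") {
    list(fwd = "ATGCGATACTTGGTGTGAAT", rev = "TCCTCCGCTTATTGATATGC")
  } else {
    list(fwd = "CGAAATCGGTAGACGCTACG", rev = "CCATTGAGTCTCTGCACCTATC")
  }
}

# re-break homopolymer runs longer than `maxrun` in a base vector
break_runs <- function(b, maxrun = 6L) {
  r <- rle(b)
  while (any(r$lengths > maxrun)) {
    long <- which(r$lengths > maxrun)
    pos <- cumsum(r$lengths)[long] # break each run at its last base
    for (p in pos) {
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    }
    r <- rle(b)
  }
  b
}

# random DNA without homopolymer runs longer than `maxrun`, so reference
# amplicons never trip the read-level homopolymer filter by construction
random_dna <- function(len, maxrun = 6L) {
  paste(break_runs(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   maxrun),
        collapse = "")
}

# substitute a fraction `rate` of positions; runs re-capped afterwards
# (a single substitution can bridge two ancestor runs into one > 8)
mutate_dna <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n_mut <- round(length(b) * rate)
  if (n_mut > 0L) {
    pos <- sample.int(length(b), n_mut)
    for (p in pos) {
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    }
  }
  paste(break_runs(b), collapse = "")
}

#' Generate a synthetic per-barcode reference database
#'
#' Species are organized into genera; congeners are derived from a
#' shared genus ancestor by 2-5% substitution divergence, so
#' within-genus identity (95-98%) far exceeds cross-genus identity
#' (random sequences, ~25%). Reference lengths follow the per-barcode
#' amplicon regimes (ITS2 160-450 bp, trnL 75-250 bp). Fully
#' reproducible from the seed.
#'
#' @param n_genera number of genera.
#' @param species_per_genus species per genus.
#' @param seed RNG seed.
#' @param barcode_absent optional named list (barcode -> species names)
#'   of species lacking a reference under that barcode.
#' @return object of class `"reference_db"`: list with `species`
#'   (data.frame `species`, `genus`), `seqs` (per barcode, named
#'   character vector of reference sequences) and `seed`.
#' @export
make_reference <- function(n_genera = 5L, species_per_genus = 3L,
                           seed = 1L, barcode_absent = list()) {
  stopifnot(n_genera >= 1L, species_per_genus >= 1L)
  len_range <- list(ITS2 = c(160L, 450L), trnL = c(75L, 250L))
  withr_seed(seed, {
    genera <- sprintf("Genus%02d", seq_len(n_genera))
    species <- unlist(lapply(genera, function(g) {
      paste(g, sprintf("sp%02d", seq_len(species_per_genus)))
    }))
    species <- normalize_taxon(species)
    genus <- genus_of(species)
    seqs <- lapply(names(len_range), function(bc) {
      out <- character(length(species))
      names(out) <- species
      for (gi in seq_along(genera)) {
        lr <- len_range[[bc]]
        len <- sample(lr[1L]:lr[2L], 1L)
        ancestor <- random_dna(len)
        idx <- which(genus == genera[gi])
        for (i in idx) {
          out[i] <- mutate_dna(ancestor, stats::runif(1L, 0.02, 0.05))
        }
      }
      absent <- normalize_taxon(barcode_absent[[bc]] %||% character(0))
      out[setdiff(names(out), absent)] -> out
      out
    })
    names(seqs) <- names(len_range)
  })
  structure(
    list(
      species = data.frame(species = species, genus = genus,
                           stringsAsFactors = FALSE),
      seqs = seqs, seed = seed
    ),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat(
    sprintf(
      "Reference DB: %d species in %d genera (seed %d)\n",
      nrow(x$species), length(unique(x$species$genus)), x$seed
    )
  )
  invisible(x)
}

#' Write one barcode of a reference database as FASTA
#'
#' @param db a [make_reference()] database.
#' @param barcode barcode label.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, barcode, path) {
  seqs <- db$seqs[[match_barcode(barcode)]]
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- gsub(" ", "_", names(seqs), fixed = TRUE)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Sample-name grid of a two-manufacturer, three-batch design
#'
#' @param preparation preparation name.
#' @param manufacturers,batches,replicates grid dimensions (defaults:
#'   manufacturers A/B, batches I-III, 3 biological replicates; 18
#'   samples per preparation and barcode).
#' @return character vector like `"DHW.A.I1"`.
#' @export
sample_grid <- function(preparation, manufacturers = c("A", "B"),
                        batches = c("I", "II", "III"),
                        replicates = 3L) {
  unlist(lapply(manufacturers, function(m) {
    unlist(lapply(batches, function(b) {
      sprintf("%s.%s.%s%d", preparation, m, b, seq_len(replicates))
    }))
  }))
}

#' Simulation parameters for synthetic amplicon reads
#'
#' @param composition named numeric vector: species relative abundances
#'   per sample (normalized to sum 1). Contaminant species are simply
#'   part of the composition.
#' @param depth reads per sample before degradation losses (default
#'   10,000, the depth at which rarefaction saturates).
#' @param error_rate per-base substitution error rate (default 0.001).
#' @param substitution_rate fraction of each species' reads reassigned
#'   to a random congener present in the database (emulates congeneric
#'   substitution; default 0).
#' @param degradation named numeric vector: dropout fraction in `[0,1]`
#'   per processed PHM name (its PHS contribute `1 - dropout` of their
#'   nominal reads).
#' @param qual_mean,qual_sd per-base Phred quality distribution
#'   (truncated normal, clipped to `[2, 40]`).
#' @param degraded_tail_frac fraction of reads given a low-quality
#'   (mean Phred 12) 50-base tail, to exercise the window filter.
#' @param exact_counts allocate reads deterministically
#'   (`round(composition * depth)`) instead of multinomially; used when
#'   a test isolates downstream rules from sampling noise.
#' @param seed RNG seed.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(composition, depth = 10000L,
                       error_rate = 0.001, substitution_rate = 0,
                       degradation = numeric(0),
                       qual_mean = 34, qual_sd = 3,
                       degraded_tail_frac = 0,
                       exact_counts = FALSE, seed = 1L) {
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 0), sum(composition) > 0,
            depth >= 1L, error_rate >= 0, error_rate <= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            all(degradation >= 0), all(degradation <= 1))
  structure(
    list(
      composition = composition / sum(composition),
      depth = as.integer(depth), error_rate = error_rate,
      substitution_rate = substitution_rate, degradation = degradation,
      qual_mean = qual_mean, qual_sd = qual_sd,
      degraded_tail_frac = degraded_tail_frac,
      exact_counts = exact_counts, seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# per-sample species read counts under the stated composition,
# degradation and congeneric substitution
sim_sample_counts <- function(rx, db, params) {
  w <- params$composition
  missing <- setdiff(names(w), db$species$species)
  if (length(missing)) {
    stop("composition references species absent from the database: ",
         paste(missing, collapse = ", "))
  }
  counts <- if (params$exact_counts) {
    round(w * params$depth)
  } else {
    as.vector(stats::rmultinom(1L, params$depth, w))
  }
  names(counts) <- names(w)
  if (length(params$degradation)) {
    stopifnot(inherits(rx, "prescription"))
    for (phm in names(params$degradation)) {
      drop <- params$degradation[[phm]]
      sp <- rx$phms$phs[[match(phm, rx$phms$phm)]]
      sp <- intersect(sp, names(counts))
      if (params$exact_counts) {
        counts[sp] <- round(counts[sp] * (1 - drop))
      } else {
        counts[sp] <- stats::rbinom(length(sp), counts[sp], 1 - drop)
      }
    }
  }
  if (params$substitution_rate > 0) {
    for (sp in names(counts)) {
      g <- db$species$genus[match(sp, db$species$species)]
      congeners <- setdiff(
        db$species$species[db$species$genus == g], sp
      )
      if (length(congeners) == 0L || counts[[sp]] == 0L) next
      moved <- round(counts[[sp]] * params$substitution_rate)
      if (moved == 0L) next
      target <- congeners[1L]
      if (!target %in% names(counts)) {
        counts[target] <- 0L
      }
      counts[sp] <- counts[sp] - moved
      counts[target] <- counts[target] + moved
    }
  }
  counts[counts > 0L]
}

#' Simulate multiplexed amplicon reads with a ground-truth manifest
#'
#' Each read is `MID_fwd + primer_fwd + reference + revcomp(primer_rev)
#' + revcomp(MID_rev)`, with per-base substitution errors at
#' `error_rate` and per-base Phred qualities from a truncated normal.
#' Reads of all samples are pooled (as on a multiplexed run) and the
#' MID sheet required to demultiplex them is returned alongside a
#' manifest naming the true origin species of every read id.
#'
#' @param rx a [prescription()] (used to resolve degraded PHMs to their
#'   species); may be `NULL` when `params$degradation` is empty.
#' @param db a [make_reference()] database.
#' @param params a [sim_params()].
#' @param samples character vector of sample names (default an 18-
#'   sample two-manufacturer grid for the prescription).
#' @param barcode barcode label (selects reference set and primers).
#' @return object of class `"sim_reads"`: list with `reads` (pooled
#'   read set), `sheet` ([barcode_sheet()]), `manifest` (data.frame
#'   `read_id`, `sample`, `species`), `truth` (per-sample true counts
#'   matrix), `barcode`, `params`.
#' @export
simulate_reads <- function(rx, db, params, samples = NULL,
                           barcode = "ITS2") {
  barcode <- match_barcode(barcode)
  refs <- db$seqs[[barcode]]
  if (is.null(samples)) {
    samples <- sample_grid(if (is.null(rx)) "SYN" else rx$preparation)
  }
  primers <- default_primers(barcode)
  pr_rc <- revcomp(primers$rev)
  withr_seed(params$seed, {
    # unique 7-base MIDs per sample
    mids <- character(0L)
    while (length(mids) < 2L * length(samples)) {
      cand <- paste(
        sample(c("A", "C", "G", "T"), 7L, replace = TRUE),
        collapse = ""
      )
      if (!cand %in% mids) mids <- c(mids, cand)
    }
    mid_fwd <- mids[seq_along(samples)]
    mid_rev <- mids[length(samples) + seq_along(samples)]
    sheet <- barcode_sheet(samples, mid_fwd, mid_rev,
                           primers$fwd, primers$rev, barcode)
    all_ids <- list()
    all_seq <- list()
    all_species <- list()
    truth <- list()
    for (si in seq_along(samples)) {
      counts <- sim_sample_counts(rx, db, params)
      absent <- setdiff(names(counts), names(refs))
      if (length(absent)) {
        stop("no ", barcode, " reference for: ",
             paste(absent, collapse = ", "))
      }
      truth[[samples[si]]] <- counts
      sp_vec <- rep.int(names(counts), counts)
      n <- length(sp_vec)
      if (n == 0L) next
      template <- paste0(mid_fwd[si], primers$fwd, refs[names(counts)],
                         pr_rc, revcomp(mid_rev[si]))
      seqs <- rep.int(template, counts)
      if (params$error_rate > 0) {
        len <- nchar(seqs)
        n_err <- stats::rbinom(n, len, params$error_rate)
        bases <- c("A", "C", "G", "T")
        # vectorized passes: the k-th error of every read at once
        for (k in seq_len(max(n_err, 0L))) {
          sel <- which(n_err >= k)
          if (length(sel) == 0L) break
          pos <- 1L + as.integer(floor(stats::runif(length(sel)) *
                                         len[sel]))
          old <- substr(seqs[sel], pos, pos)
          shift <- sample.int(3L, length(sel), replace = TRUE)
          new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
          substr(seqs[sel], pos, pos) <- new
        }
      }
      all_ids[[si]] <- sprintf("%s_r%06d", samples[si], seq_len(n))
      all_seq[[si]] <- seqs
      all_species[[si]] <- sp_vec
    }
    ids <- unlist(all_ids, use.names = FALSE)
    seqs <- unlist(all_seq, use.names = FALSE)
    species <- unlist(all_species, use.names = FALSE)
    # per-base qualities from the discretized truncated normal,
    # generated in one block for speed
    len <- nchar(seqs)
    qlv <- 2:40
    qp <- stats::dnorm(qlv, params$qual_mean, params$qual_sd)
    q <- qlv[sample.int(length(qlv), sum(len), replace = TRUE,
                        prob = qp / sum(qp))]
    ends <- cumsum(len)
    starts <- ends - len + 1L
    if (params$degraded_tail_frac > 0) {
      # 50 bp so the degraded stretch survives MID/primer trimming
      bad <- which(stats::runif(length(seqs)) <
                     params$degraded_tail_frac & len > 50L)
      for (i in bad) {
        tail_idx <- (ends[i] - 49L):ends[i]
        q[tail_idx] <- pmax(
          2L, as.integer(round(stats::rnorm(50L, 12, 3)))
        )
      }
    }
    qall <- int_to_qual_string(q)
    quals <- substring(qall, starts, ends)
  })
  reads <- read_set(ids, seqs, quals)
  manifest <- data.frame(
    read_id = ids,
    sample = sub("_r[0-9]+$", "", ids),
    species = species,
    stringsAsFactors = FALSE
  )
  structure(
    list(reads = reads, sheet = sheet, manifest = manifest,
         truth = truth, barcode = barcode, params = params),
    class = "sim_reads"
  )
}

#' Simulate an alignment hit table from a read manifest
#'
#' Bypasses the external aligner for hermetic tests: every read gets a
#' top hit to its true species, hits to all congeners of the true
#' species at ~90% of the top bitscore, and (at rate `fp_rate`) one
#' false hit to a random unrelated species at a still lower score.
#' Scores are perturbed by Gaussian noise of sd `score_noise`; e-values
#' are a fixed monotone-decreasing map of the bitscore.
#'
#' @param sim a [simulate_reads()] result (its manifest and barcode are
#'   used), or a manifest data.frame plus `barcode`.
#' @param db the [make_reference()] database.
#' @param score_noise sd of the bitscore perturbation (default 0).
#' @param fp_rate probability of an extra random false hit per read.
#' @param seed RNG seed.
#' @param barcode barcode label when `sim` is a bare manifest.
#' @return a [hit_table()].
#' @export
simulate_hits <- function(sim, db, score_noise = 0, fp_rate = 0,
                          seed = 1L, barcode = NULL) {
  if (inherits(sim, "sim_reads")) {
    manifest <- sim$manifest
    barcode <- sim$barcode
  } else {
    manifest <- sim
    barcode <- match_barcode(barcode)
  }
  refs <- db$seqs[[barcode]]
  reflen <- nchar(refs)
  genus_map <- split(db$species$species, db$species$genus)
  withr_seed(seed, {
    base <- 2 * reflen[manifest$species] +
      if (score_noise > 0) {
        stats::rnorm(nrow(manifest), 0, score_noise)
      } else {
        0
      }
    top <- data.frame(
      read_id = manifest$read_id, species = manifest$species,
      identity = 100, bitscore = pmax(base, 30),
      stringsAsFactors = FALSE
    )
    cong_by_species <- lapply(seq_len(nrow(db$species)), function(i) {
      setdiff(genus_map[[db$species$genus[i]]], db$species$species[i])
    })
    names(cong_by_species) <- db$species$species
    cong_list <- cong_by_species[manifest$species]
    ncong <- lengths(cong_list)
    cong <- data.frame(
      read_id = rep.int(manifest$read_id, ncong),
      species = unlist(cong_list, use.names = FALSE),
      identity = 96,
      bitscore = pmax(rep.int(base, ncong) * 0.9 +
                        if (score_noise > 0) {
                          stats::rnorm(sum(ncong), 0, score_noise)
                        } else {
                          0
                        }, 25),
      stringsAsFactors = FALSE
    )
    # drop congener hits to species without a reference in this barcode
    cong <- cong[cong$species %in% names(refs), , drop = FALSE]
    fp <- NULL
    if (fp_rate > 0) {
      is_fp <- stats::runif(nrow(manifest)) < fp_rate
      if (any(is_fp)) {
        fp <- data.frame(
          read_id = manifest$read_id[is_fp],
          species = sample(names(refs), sum(is_fp), replace = TRUE),
          identity = 85,
          bitscore = pmax(base[is_fp] * 0.75, 20),
          stringsAsFactors = FALSE
        )
      }
    }
    hits <- rbind(top, cong, fp)
  })
  hit_table(
    hits$read_id, hits$species, hits$identity, hits$bitscore,
    evalue = pmax(10^(-hits$bitscore / 4), 1e-180)
  )
}

#' Planted two-group marker design at the abundance-table level
#'
#' Emulates two manufacturers whose products differ in a few planted
#' discriminative species: a shared baseline composition, with
#' `n_markers` species boosted by `effect` (absolute relative
#' abundance) in group A only and `n_markers` others boosted in group B
#' only; per-sample counts are multinomial at `depth` (sequencing
#' noise only; no additional biological overdispersion).
#'
#' An `effect` of 0.01 corresponds to an effect size of 4 on the
#' [lda_effect_size()] scale.
#'
#' @param n_per_group samples per group (default 9: three batches of
#'   three replicates).
#' @param n_species total species in the table (default 30).
#' @param n_markers planted markers per group (default 3).
#' @param effect absolute relative-abundance boost (default 0.01).
#' @param depth multinomial read depth per sample (default 10,000).
#' @param seed RNG seed.
#' @return list with `table` (an [abundance_table()]), `labels`
#'   (factor A/B per sample), `markers_a`, `markers_b` (planted truth).
#' @export
simulate_marker_design <- function(n_per_group = 9L, n_species = 30L,
                                   n_markers = 3L, effect = 0.01,
                                   depth = 10000L, seed = 1L) {
  stopifnot(n_species > 2L * n_markers)
  species <- normalize_taxon(
    sprintf("Genus%02d sp%02d", seq_len(n_species), seq_len(n_species))
  )
  markers_a <- species[seq_len(n_markers)]
  markers_b <- species[n_markers + seq_len(n_markers)]
  base <- rep(1 / n_species, n_species)
  names(base) <- species
  wa <- base
  wa[markers_a] <- wa[markers_a] + effect
  wb <- base
  wb[markers_b] <- wb[markers_b] + effect
  wa <- wa / sum(wa)
  wb <- wb / sum(wb)
  samples <- c(sprintf("A.S%d", seq_len(n_per_group)),
               sprintf("B.S%d", seq_len(n_per_group)))
  labels <- factor(rep(c("A", "B"), each = n_per_group))
  withr_seed(seed, {
    counts <- t(vapply(seq_along(samples), function(i) {
      w <- if (labels[i] == "A") wa else wb
      as.vector(stats::rmultinom(1L, depth, w))
    }, integer(n_species)))
  })
  dimnames(counts) <- list(samples, species)
  list(
    table = abundance_table(counts, "ITS2"),
    labels = labels,
    markers_a = markers_a,
    markers_b = markers_b
  )
}
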