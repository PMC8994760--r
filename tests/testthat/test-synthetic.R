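test_that("reference databases are structured and reproducible", {
  db <- make_reference(5L, 3L, seed = 1L)
  expect_equal(nrow(db$species), 15L)
  expect_length(unique(db$species$genus), 5L)
  expect_length(db$seqs$ITS2, 15L)
  lens_its2 <- nchar(db$seqs$ITS2)
  lens_trnl <- nchar(db$seqs$trnL)
  expect_true(all(lens_its2 >= 160 & lens_its2 <= 450))
  expect_true(all(lens_trnl >= 75 & lens_trnl <= 250))
  # byte-identical FASTA from the same seed
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(db, "ITS2", f1)
  write_reference_fasta(make_reference(5L, 3L, seed = 1L), "ITS2", f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # no reference carries a >8 bp homopolymer (QC safety)
  expect_false(any(grepl("A{9,}|C{9,}|G{9,}|T{9,}", db$seqs$ITS2)))
  # barcode-absent species are dropped from that barcode only
  db2 <- make_reference(
    2L, 2L, seed = 2L,
    barcode_absent = list(trnL = "Genus01 sp01")
  )
  expect_false("Genus01 sp01" %in% names(db2$seqs$trnL))
  expect_true("Genus01 sp01" %in% names(db2$seqs$ITS2))
})

test_that("congeners are closer than cross-genus pairs", {
  db <- make_reference(4L, 2L, seed = 3L)
  ident <- function(a, b) {
    # positional identity over the shorter sequence; congeners share an
    # ancestor (equal length), cross-genus pairs are unrelated
    n <- min(nchar(a), nchar(b))
    av <- strsplit(substr(a, 1, n), "")[[1L]]
    bv <- strsplit(substr(b, 1, n), "")[[1L]]
    mean(av == bv)
  }
  for (bc in c("ITS2", "trnL")) {
    seqs <- db$seqs[[bc]]
    within <- outer_within <- c()
    for (g in unique(db$species$genus)) {
      sp <- db$species$species[db$species$genus == g]
      within <- c(within, ident(seqs[[sp[1]]], seqs[[sp[2]]]))
    }
    cross <- ident(seqs[["Genus01 sp01"]], seqs[["Genus02 sp01"]])
    expect_true(all(within > 0.9))
    expect_lt(cross, 0.8)
    expect_true(min(within) > cross)
  }
})

test_that("read simulation respects composition, dropout and structure", {
  db <- make_reference(3L, 2L, seed = 4L)
  rx <- prescription(
    "SIM", c("m1", "m2"),
    list("Genus01 sp01", "Genus02 sp01"),
    processed = c(FALSE, TRUE)
  )
  comp <- c("Genus01 sp01" = 0.6, "Genus02 sp01" = 0.3,
            "Genus03 sp01" = 0.1)
  # error rate 0: every read is the exact template construction
  pars0 <- sim_params(comp, depth = 300L, error_rate = 0,
                      seed = 5L)
  sim0 <- simulate_reads(rx, db, pars0,
                         samples = c("SIM.A.I1", "SIM.A.I2"))
  expect_equal(nrow(sim0$reads), nrow(sim0$manifest)) # conservation
  expect_equal(nrow(sim0$reads), 600L)
  i <- 17L
  sp <- sim0$manifest$species[i]
  smp <- sim0$manifest$sample[i]
  row <- match(smp, sim0$sheet$sample_id)
  p <- default_primers("ITS2")
  expect_equal(
    sim0$reads$seq[i],
    paste0(sim0$sheet$mid_fwd[row], p$fwd, db$seqs$ITS2[[sp]],
           herbaudit:::revcomp(p$rev),
           herbaudit:::revcomp(sim0$sheet$mid_rev[row]))
  )
  # full dropout of a processed PHM leaves zero reads of its species
  pars1 <- sim_params(comp, depth = 300L, degradation = c(m2 = 1.0),
                      seed = 6L)
  sim1 <- simulate_reads(rx, db, pars1, samples = "SIM.A.I1")
  expect_false("Genus02 sp01" %in% sim1$manifest$species)
  # composition recovered within multinomial error at depth 10,000
  pars2 <- sim_params(comp, depth = 10000L, seed = 7L)
  sim2 <- simulate_reads(rx, db, pars2, samples = "SIM.A.I1")
  frac <- mean(sim2$manifest$species == "Genus01 sp01")
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 10000)) # ~99.7% CI
  # unknown species refuse to simulate
  expect_error(
    simulate_reads(rx, db,
                   sim_params(c("Nope nope" = 1), depth = 10L),
                   samples = "s"),
    "absent"
  )
})

test_that("congeneric substitution moves the stated read fraction", {
  db <- make_reference(2L, 2L, seed = 8L)
  rx <- prescription("SIM", "m1", list("Genus01 sp01"))
  pars <- sim_params(
    c("Genus01 sp01" = 1), depth = 1000L,
    substitution_rate = 0.1, exact_counts = TRUE, seed = 9L
  )
  sim <- simulate_reads(rx, db, pars, samples = "s1")
  tab <- table(sim$manifest$species)
  expect_equal(unname(tab[["Genus01 sp02"]]), 100L)
  expect_equal(unname(tab[["Genus01 sp01"]]), 900L)
})

test_that("simulated hits are exactly recoverable without noise", {
  db <- make_reference(3L, 2L, seed = 10L)
  rx <- prescription("SIM", "m1", list("Genus01 sp01"))
  comp <- c("Genus01 sp01" = 0.5, "Genus02 sp01" = 0.5)
  sim <- simulate_reads(rx, db, sim_params(comp, depth = 200L, seed = 11L),
                        samples = "s1")
  hits <- simulate_hits(sim, db, score_noise = 0, fp_rate = 0,
                        seed = 12L)
  res <- assign_sample(hits, rx, read_ids = sim$manifest$read_id)
  got <- res$assignments
  truth <- sim$manifest$species[match(got$read_id,
                                      sim$manifest$read_id)]
  expect_equal(got$species, truth) # 100% recovery
  expect_equal(res$n_unassigned, 0L)
  # e-values are monotone decreasing in bitscore
  o <- order(hits$bitscore)
  expect_true(all(diff(hits$evalue[o]) <= 0))
})

test_that("false-positive hits appear at the stated rate", {
  db <- make_reference(3L, 2L, seed = 13L)
  rx <- prescription("SIM", "m1", list("Genus01 sp01"))
  sim <- simulate_reads(
    rx, db, sim_params(c("Genus01 sp01" = 1), depth = 4000L, seed = 14L),
    samples = "s1"
  )
  hits <- simulate_hits(sim, db, fp_rate = 0.05, seed = 15L)
  n_fp <- sum(hits$identity == 85)
  # binomial 99.7% band around 5% of 4000
  expect_lt(abs(n_fp / 4000 - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("degraded-tail reads trip the window filter", {
  db <- make_reference(2L, 1L, seed = 16L)
  rx <- prescription("SIM", "m1", list("Genus01 sp01"))
  pars <- sim_params(c("Genus01 sp01" = 1), depth = 400L,
                     degraded_tail_frac = 0.5, seed = 17L)
  sim <- simulate_reads(rx, db, pars, samples = "s1")
  dmx <- demultiplex(sim$reads, sim$sheet)
  qc <- qc_reads(dmx$samples$s1, sim$sheet[1, ],
                 qc_params("ITS2", min_len = 10L))
  frac_q <- sum(qc$rejects$reason == "quality") / 400
  expect_gt(frac_q, 0.3) # most planted tails fail the Q20 window
})

test_that("the planted marker design carries its stated truth", {
  d <- simulate_marker_design(n_per_group = 5L, seed = 18L)
  expect_equal(nrow(d$table$counts), 10L)
  expect_length(intersect(d$markers_a, d$markers_b), 0L)
  rel <- d$table$rel
  gap_a <- colMeans(rel[d$labels == "A", d$markers_a]) -
    colMeans(rel[d$labels == "B", d$markers_a])
  expect_true(all(gap_a > 0.005)) # planted ~0.01 boost
})
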