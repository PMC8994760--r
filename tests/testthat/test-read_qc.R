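make_sheet <- function(n = 2L, barcode = "ITS2") {
  mids <- c("AAACCCG", "TTTGGGA", "CCCAAAT", "GGGTTTC",
            "ACACACA", "GTGTGTG")
  p <- default_primers(barcode)
  barcode_sheet(
    paste0("S", seq_len(n)),
    mid_fwd = mids[seq_len(n)], mid_rev = mids[n + seq_len(n)],
    primer_fwd = p$fwd, primer_rev = p$rev, barcode = barcode
  )
}

# a read carrying sample `i`'s MIDs around `insert`
tagged_read <- function(sheet, i, insert) {
  paste0(sheet$mid_fwd[i], insert,
         herbaudit:::revcomp(sheet$mid_rev[i]))
}

test_that("demultiplexing is exact dual-MID with zero mismatches", {
  sheet <- make_sheet()
  insert <- random_seq(40)
  reads <- reads_with_qual(c(
    tagged_read(sheet, 1, insert),
    tagged_read(sheet, 2, insert),
    paste0("T", substring(tagged_read(sheet, 1, insert), 2)) # 1 mismatch
  ))
  res <- demultiplex(reads, sheet)
  expect_equal(nrow(res$samples$S1), 1L)
  expect_equal(nrow(res$samples$S2), 1L)
  # both 7 bp MIDs removed: 14 bases total
  expect_equal(nchar(res$samples$S1$seq), nchar(insert))
  expect_equal(res$samples$S1$seq, insert)
  expect_equal(res$rejects$reason, "barcode")
})

test_that("demultiplexing an empty stream yields empty outputs", {
  sheet <- make_sheet()
  res <- demultiplex(reads_with_qual(character(0)), sheet)
  expect_true(all(vapply(res$samples, nrow, 1L) == 0L))
  expect_equal(nrow(res$rejects), 0L)
})

test_that("duplicate MID pairs are a configuration error", {
  p <- default_primers("ITS2")
  expect_error(
    barcode_sheet(c("a", "b"), c("AAAAAAA", "AAAAAAA"),
                  c("CCCCCCC", "CCCCCCC"), p$fwd, p$rev),
    "duplicate"
  )
})

test_that("reverse-complemented reads are recovered only when asked", {
  sheet <- make_sheet()
  insert <- random_seq(40)
  fwd <- tagged_read(sheet, 1, insert)
  reads <- reads_with_qual(herbaudit:::revcomp(fwd))
  expect_equal(nrow(demultiplex(reads, sheet)$samples$S1), 0L)
  res <- demultiplex(reads, sheet, both_orientations = TRUE)
  expect_equal(res$samples$S1$seq, insert)
})

test_that("primer trimming excises anchored primers", {
  sheet <- make_sheet()
  p <- default_primers("ITS2")
  insert <- random_seq(60)
  good <- paste0(p$fwd, insert, herbaudit:::revcomp(p$rev))
  res <- trim_primers(reads_with_qual(c(good, insert)), sheet[1, ])
  expect_equal(res$kept$seq, insert)
  expect_equal(nchar(res$kept$qual), nchar(insert))
  expect_equal(res$rejects$reason, "primer")
  # primer longer than the read
  res2 <- trim_primers(reads_with_qual("ACGT"), sheet[1, ])
  expect_equal(res2$rejects$reason, "primer")
})

test_that("IUPAC codes in primers match their expansions", {
  # brute-force oracle: expand Y over the 4-letter alphabet
  expansions <- c(A = FALSE, C = TRUE, G = FALSE, T = TRUE)
  sheet <- barcode_sheet("S1", "AAACCCG", "TTTGGGA",
                         primer_fwd = "ACGTY", primer_rev = "ACGTA")
  insert <- random_seq(30)
  for (base in names(expansions)) {
    read <- paste0("ACGT", base, insert,
                   herbaudit:::revcomp("ACGTA"))
    res <- trim_primers(reads_with_qual(read), sheet[1, ])
    expect_equal(nrow(res$kept) == 1L, unname(expansions[base]),
                 label = paste("Y vs", base))
  }
  # and mismatch budget: one mismatch allowed recovers the reject
  bad <- paste0("ACGTC", insert, herbaudit:::revcomp("ACGTT"))
  strict <- trim_primers(reads_with_qual(bad), sheet[1, ])
  lax <- trim_primers(reads_with_qual(bad), sheet[1, ],
                      qc_params(max_primer_mismatches = 1L))
  expect_equal(nrow(strict$kept), 0L)
  expect_equal(nrow(lax$kept), 1L)
})

test_that("length bounds follow the per-barcode regimes", {
  its2 <- qc_params("ITS2")
  trnl <- qc_params("trnL")
  r149 <- reads_with_qual(random_seq(149), q = 38)
  r150 <- reads_with_qual(random_seq(150), q = 38)
  r511 <- reads_with_qual(random_seq(511), q = 38)
  r75 <- reads_with_qual(random_seq(75), q = 30)
  expect_equal(qc_filter(r149, its2)$rejects$reason, "length")
  expect_equal(nrow(qc_filter(r150, its2)$kept), 1L)
  expect_equal(qc_filter(r511, its2)$rejects$reason, "length")
  expect_equal(nrow(qc_filter(r75, trnl)$kept), 1L)
  expect_equal(qc_filter(reads_with_qual(random_seq(74), q = 30),
                         trnl)$rejects$reason, "length")
})

test_that("N bases and >8 bp homopolymers are rejected", {
  its2 <- qc_params("ITS2")
  base <- random_seq(150)
  withN <- paste0(substr(base, 1, 100), "N", substr(base, 102, 150))
  expect_equal(qc_filter(reads_with_qual(withN), its2)$rejects$reason,
               "ambiguous")
  # plant a run of nine A's (run of 8 must pass)
  plant <- function(run) {
    paste0("CT", run, substr(random_seq(150), 1, 139), "TC")
  }
  r9 <- reads_with_qual(plant(strrep("A", 9)))
  r8 <- reads_with_qual(plant(paste0(strrep("A", 8), "C")))
  expect_equal(qc_filter(r9, its2)$rejects$reason, "homopolymer")
  expect_equal(nrow(qc_filter(r8, its2)$kept), 1L)
})

test_that("one low-quality window rejects the read", {
  its2 <- qc_params("ITS2")
  seq <- random_seq(150)
  good <- rep(30L, 150L)
  bad <- good
  bad[71:75] <- c(19L, 19L, 19L, 19L, 23L) # mean 19.8 < 20
  borderline <- good
  borderline[71:75] <- c(19L, 19L, 19L, 19L, 24L) # mean 20.0
  mk <- function(q) {
    herbaudit:::read_set("r", seq, herbaudit:::int_to_qual_string(q))
  }
  expect_equal(qc_filter(mk(bad), its2)$rejects$reason, "quality")
  expect_equal(nrow(qc_filter(mk(borderline), its2)$kept), 1L)
  expect_equal(nrow(qc_filter(mk(good), its2)$kept), 1L)
})

test_that("window rule matches brute force on 1000 random reads", {
  set.seed(7)
  n <- 1000L
  lens <- sample(3:60, n, replace = TRUE)
  quals <- vapply(lens, function(l) {
    herbaudit:::int_to_qual_string(sample(15:32, l, replace = TRUE))
  }, character(1L))
  got <- herbaudit:::window_quality_fail(quals, 5L, 20)
  want <- vapply(quals, oracle_window_fail, logical(1L),
                 USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("QC conserves reads and is order-independent", {
  set.seed(21)
  sheet <- make_sheet()
  p <- default_primers("ITS2")
  n <- 200L
  short <- seq_len(40L) # planted too-short inserts -> length rejects
  seqs <- vapply(seq_len(n), function(i) {
    insert <- random_seq(if (i %in% short) 120 else 250)
    tagged_read(sheet, sample(1:2, 1),
                paste0(p$fwd, insert, herbaudit:::revcomp(p$rev)))
  }, character(1L))
  # corrupt 5% of the long reads with a 9 bp homopolymer in the insert
  hp <- sample(setdiff(seq_len(n), short), 10L)
  seqs[hp] <- sub("^(.{40})(.{9})", "\\1AAAAAAAAA", seqs[hp])
  reads <- reads_with_qual(seqs)
  dmx <- demultiplex(reads, sheet)
  qc <- lapply(dmx$samples, qc_reads, spec = sheet[1, ],
               params = qc_params("ITS2"))
  st <- qc_stats(qc)
  expect_equal(sum(st$input) + nrow(dmx$rejects), n)
  expect_equal(st$input,
               st$kept + rowSums(st[, c("primer", "length", "ambiguous",
                                        "homopolymer", "quality")]))
  # every read id appears exactly once across all streams
  ids <- c(
    dmx$rejects$id,
    unlist(lapply(qc, function(x) c(x$kept$id, x$rejects$id)))
  )
  expect_setequal(ids, reads$id)
  expect_equal(anyDuplicated(ids), 0L)
  # all planted homopolymer reads show up as homopolymer rejects
  hp_rejected <- unlist(lapply(qc, function(x) {
    x$rejects$id[x$rejects$reason == "homopolymer"]
  }))
  expect_true(all(reads$id[hp] %in% hp_rejected))
  expect_gte(sum(st$length), length(short))
  # shuffling input leaves per-sample kept sets identical
  perm <- sample(n)
  dmx2 <- demultiplex(reads[perm, ], sheet)
  qc2 <- lapply(dmx2$samples, qc_reads, spec = sheet[1, ],
                params = qc_params("ITS2"))
  for (s in names(qc)) {
    expect_setequal(qc2[[s]]$kept$id, qc[[s]]$kept$id)
  }
})

test_that("FASTQ round-trips through Biostrings", {
  reads <- reads_with_qual(c(random_seq(50), random_seq(60)), q = 33)
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  expect_equal(back$id, reads$id)
})
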