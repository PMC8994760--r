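# shared in-code fixtures

# toy two-genus prescription used across assignment/audit tests
toy_rx <- function() {
  prescription(
    "TOY",
    phm = c("root", "bark", "seed"),
    phs = list(
      c("Paeonia lactiflora", "Paeonia veitchii"),
      "Glycyrrhiza uralensis",
      "Cuscuta australis"
    )
  )
}

ygw_rx <- function() {
  load_prescription(herbaudit_extdata("ygw_prescription.tsv"))
}

# random hit set over a universe containing PHS, congeners and strangers
random_hits <- function(rx, n_max = 6L) {
  pool <- c(
    rx$phs_universe,
    paste(rx$phs_genera, "randomsp"),
    c("Oryza sativa", "Zea mays", "Solanum lycopersicum")
  )
  n <- sample(0:n_max, 1L)
  if (n == 0L) {
    return(hit_table(character(0), character(0), numeric(0),
                     numeric(0), numeric(0)))
  }
  hit_table(
    read_id = rep("r1", n),
    species = sample(pool, n, replace = TRUE),
    identity = round(runif(n, 90, 100), 1),
    bitscore = sample(80:95, n, replace = TRUE), # coarse: ties frequent
    evalue = 10^-sample(20:40, n, replace = TRUE)
  )
}

# read set built from explicit sequences with constant quality
reads_with_qual <- function(seqs, q = 35L, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (length(seqs)) paste0("r", seq_along(seqs)) else character(0)
  }
  herbaudit:::read_set(
    ids, seqs,
    vapply(nchar(seqs), function(n) {
      paste(rep(intToUtf8(q + 33L), n), collapse = "")
    }, character(1L))
  )
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# the end-to-end synthetic world of the acceptance suite: a 6-PHM
# prescription over an 8-genus reference, one fully degraded processed
# material and one contaminant planted at rel 0.0015
e2e_world <- function(seed) {
  db <- make_reference(n_genera = 8L, species_per_genus = 2L,
                       seed = seed)
  sp <- function(g) sprintf("Genus%02d sp01", g)
  rx <- prescription(
    "SYN",
    phm = paste0("PHM", 1:6),
    phs = lapply(1:6, function(g) sp(g)),
    processed = c(rep(FALSE, 5L), TRUE)
  )
  comp <- stats::setNames(
    c(0.30, 0.20, 0.15, 0.15, 0.0985, 0.10, 0.0015),
    vapply(1:7, sp, "")
  )
  list(db = db, rx = rx, composition = comp,
       planted = sp(7), degraded_phm = "PHM6",
       normal_phms = paste0("PHM", 1:5))
}

# run the full read-level pipeline in memory for one barcode
e2e_run <- function(world, barcode, seed, depth = 10000L) {
  pars <- sim_params(
    world$composition, depth = depth,
    degradation = stats::setNames(1.0, world$degraded_phm),
    exact_counts = TRUE, seed = seed
  )
  sim <- simulate_reads(world$rx, world$db, pars, barcode = barcode)
  dmx <- demultiplex(sim$reads, sim$sheet)
  qc <- lapply(dmx$samples, qc_reads, spec = sim$sheet[1L, ],
               params = qc_params(barcode))
  hits <- simulate_hits(sim, world$db, score_noise = 5, seed = seed + 1L)
  kept_ids <- unlist(lapply(qc, function(x) x$kept$id),
                     use.names = FALSE)
  hits <- hits[hits$read_id %in% kept_ids, , drop = FALSE]
  class(hits) <- c("hit_table", "data.frame")
  smp <- sub("_r[0-9]+$", "", hits$read_id)
  counts <- lapply(split(hits, smp), function(h) {
    class(h) <- c("hit_table", "data.frame")
    assign_sample(h, world$rx)$counts
  })
  tab <- threshold_filter(build_table(counts, barcode))
  report <- detection_report(audit_table(tab, world$rx), world$rx,
                             barcode = barcode)
  list(table = tab, report = report)
}
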