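#' Pipeline run configuration
#'
#' Bundles every tunable of the audit pipeline with the package's
#' default thresholds: ITS2 length 150-510 bp / trnL >= 75 bp, Q20 over
#' 5 bp rolling windows, homopolymer limit 8, e-value 1e-10, relative
#' abundance 0.002 (ITS2) / 0.001 (trnL), network cutoffs 5.0 (ITS2) /
#' 4.2 (trnL).
#'
#' @param prescription path to a prescription file, or a
#'   [prescription()] object.
#' @param out_dir output directory (created if missing).
#' @param barcodes barcode labels to process.
#' @param simulate `NULL`, or a list of arguments for the synthetic
#'   preset (see [run_pipeline()]): `n_genera`, `species_per_genus`,
#'   `depth`, `error_rate`, `seed`, ...
#' @param reads,hits named lists (by barcode) of input paths: pooled
#'   FASTQ plus MID sheet TSV (`reads$ITS2$fastq`, `reads$ITS2$mids`),
#'   or pre-computed hit tables. Ignored when `simulate` is given.
#' @param evalue_max alignment e-value cutoff.
#' @param min_rel named per-barcode abundance thresholds (defaults
#'   [abundance_threshold()]).
#' @param network_cutoff named per-barcode distance cutoffs.
#' @param linkage clustering linkage.
#' @param seed master RNG seed.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(prescription, out_dir,
                       barcodes = c("ITS2", "trnL"),
                       simulate = NULL, reads = NULL, hits = NULL,
                       evalue_max = 1e-10,
                       min_rel = c(ITS2 = 0.002, trnL = 0.001),
                       network_cutoff = c(ITS2 = 5.0, trnL = 4.2),
                       linkage = "complete", seed = 1L) {
  if (is.character(prescription)) {
    if (!file.exists(prescription)) {
      stop("prescription file not found: ", prescription)
    }
    prescription <- load_prescription(prescription)
  }
  stopifnot(inherits(prescription, "prescription"))
  barcodes <- vapply(barcodes, match_barcode, "")
  if (is.null(simulate) && is.null(reads) && is.null(hits)) {
    stop("one of `simulate`, `reads` or `hits` must be provided")
  }
  structure(
    list(
      prescription = prescription, out_dir = out_dir,
      barcodes = barcodes, simulate = simulate, reads = reads,
      hits = hits, evalue_max = evalue_max, min_rel = min_rel,
      network_cutoff = network_cutoff, linkage = linkage,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields mirror the [run_config()]
#'   arguments.
#' @return a [run_config()].
#' @export
load_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  args <- obj[intersect(names(obj), names(formals(run_config)))]
  do.call(run_config, args)
}

#' Run the full audit pipeline
#'
#' Orchestrates, per barcode: read simulation (or loading), MID
#' demultiplexing, primer trimming and QC filtering, alignment-hit
#' simulation (or loading), prescribed-species-preferred assignment,
#' abundance tabulation and threshold filtering, the per-sample
#' species audit, PHM detection with sensitivity, presence-based
#' distances/clustering/network edges; then the multi-barcode union
#' report. All stage outputs are written under `config$out_dir`
#' together with a JSON run report listing the thresholds applied,
#' seeds, and md5 checksums of every artifact; a rerun with the same
#' config is bit-identical.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rx <- config$prescription
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    preparation = rx$preparation,
    seed = config$seed,
    thresholds = list(
      evalue_max = config$evalue_max,
      min_rel = as.list(config$min_rel),
      network_cutoff = as.list(config$network_cutoff),
      qc = lapply(config$barcodes, function(b) {
        p <- qc_params(b)
        p[c("min_len", "max_len", "window", "min_window_q",
            "max_homopolymer")]
      })
    ),
    barcodes = list()
  )
  reports <- list()
  db <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    db <- make_reference(
      n_genera = sim_args$n_genera %||% 6L,
      species_per_genus = sim_args$species_per_genus %||% 2L,
      seed = config$seed
    )
  }
  for (bc in config$barcodes) {
    stage_out <- file.path(config$out_dir, bc)
    dir.create(stage_out, showWarnings = FALSE)
    params <- qc_params(bc)
    if (!is.null(config$simulate)) {
      comp <- config$simulate$composition
      if (is.null(comp)) {
        # equal-abundance composition over the prescription's species
        # that exist in the synthetic reference
        sp <- intersect(rx$phs_universe, db$species$species)
        if (length(sp) == 0L) {
          stop("no prescription species present in the synthetic ",
               "reference; supply simulate$composition")
        }
        comp <- stats::setNames(rep(1 / length(sp), length(sp)), sp)
      }
      sp <- sim_params(
        comp,
        depth = config$simulate$depth %||% 2000L,
        error_rate = config$simulate$error_rate %||% 0.001,
        degradation = unlist(config$simulate$degradation) %||%
          numeric(0),
        seed = config$seed + match(bc, config$barcodes)
      )
      sim <- simulate_reads(rx, db, sp, barcode = bc,
                            samples = config$simulate$samples)
      write_fastq(sim$reads, file.path(stage_out, "reads.fastq"))
      reads <- sim$reads
      sheet <- sim$sheet
      hits_all <- simulate_hits(sim, db, seed = sp$seed)
    } else if (!is.null(config$reads)) {
      reads <- read_fastq(config$reads[[bc]]$fastq)
      sheet <- read_barcode_sheet(config$reads[[bc]]$mids, barcode = bc)
      hits_all <- load_hit_table(
        config$reads[[bc]]$hits,
        species_map = config$reads[[bc]]$species_map,
        max_evalue = config$evalue_max
      )
    } else {
      reads <- NULL
      sheet <- NULL
      hits_all <- load_hit_table(
        config$hits[[bc]]$path,
        species_map = config$hits[[bc]]$species_map,
        max_evalue = config$evalue_max
      )
    }
    if (!is.null(reads)) {
      dmx <- demultiplex(reads, sheet)
      qc <- lapply(dmx$samples, qc_reads, spec = sheet[1L, ],
                   params = params)
      utils::write.table(
        qc_stats(qc), file.path(stage_out, "qc_stats.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      kept_ids <- unlist(lapply(qc, function(x) x$kept$id),
                         use.names = FALSE)
      hits_all <- hits_all[hits_all$read_id %in% kept_ids, ,
                           drop = FALSE]
      sample_of <- unlist(lapply(names(qc), function(s) {
        stats::setNames(rep(s, nrow(qc[[s]]$kept)), qc[[s]]$kept$id)
      }))
    } else {
      sample_of <- NULL
    }
    # per-sample assignment and abundance
    if (is.null(sample_of)) {
      sample_of <- stats::setNames(
        sub("_r[0-9]+$", "", hits_all$read_id), hits_all$read_id
      )
      sample_of <- sample_of[!duplicated(names(sample_of))]
    }
    hits_by_sample <- split(
      hits_all, sample_of[hits_all$read_id]
    )
    counts <- lapply(hits_by_sample, function(h) {
      class(h) <- c("hit_table", "data.frame")
      assign_sample(h, rx)$counts
    })
    tab <- build_table(counts, barcode = bc)
    tab_f <- threshold_filter(tab, min_rel = config$min_rel[[bc]])
    write_abundance(
      tab_f, file.path(stage_out, "abundance_filtered.tsv"),
      provenance = list(min_rel = config$min_rel[[bc]])
    )
    summaries <- audit_table(tab_f, rx)
    rep_bc <- detection_report(summaries, rx, barcode = bc)
    write_detection_report(
      rep_bc, file.path(stage_out, "detection_report.json")
    )
    pm <- presence_matrix(tab_f, rx)
    if (nrow(pm) >= 2L) {
      dm <- euclidean_distances(pm)
      write_distances(dm, file.path(stage_out, "distances.tsv"))
      if (nrow(pm) >= 3L) {
        write_newick(
          hierarchical_cluster(dm, config$linkage),
          file.path(stage_out, "dendrogram.nwk")
        )
      }
      edges <- network_edges(dm, config$network_cutoff[[bc]])
      utils::write.table(
        edges, file.path(stage_out, "network_edges.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    reports[[bc]] <- rep_bc
    report$barcodes[[bc]] <- list(
      n_samples = nrow(tab_f$counts),
      n_species = ncol(tab_f$counts),
      sensitivity_pct = rep_bc$sensitivity_pct,
      detected_phms = rep_bc$detected_phms
    )
  }
  if (length(reports) > 1L) {
    uni <- union_barcodes(reports, rx)
    write_detection_report(
      uni, file.path(config$out_dir, "detection_report_union.json")
    )
    report$union <- list(
      sensitivity_pct = uni$sensitivity_pct,
      detected_phms = uni$detected_phms
    )
  }
  files <- list.files(config$out_dir, recursive = TRUE,
                      full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "report.json"))
  report$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)),
    sub(paste0("^", config$out_dir, "/?"), "", files)
  ))
  jsonlite::write_json(
    report, file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(report)
}
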