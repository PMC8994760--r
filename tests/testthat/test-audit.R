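test_that("per-sample audits partition detected species", {
  rx <- ygw_rx()
  row <- c("Lycium barbarum" = 50L, "Cuscuta japonica" = 5L,
           "Oryza sativa" = 3L)
  a <- audit_sample(row, rx, "s1")
  expect_equal(c(a$n_phs, a$n_shs, a$n_chs), c(1L, 1L, 1L))
  empty <- audit_sample(integer(0), rx)
  expect_equal(c(empty$n_phs, empty$n_shs, empty$n_chs), c(0L, 0L, 0L))
  expect_length(intersect(a$phs, a$shs), 0L)
})

test_that("random rows tally like the classification oracle", {
  rx <- toy_rx()
  set.seed(71)
  pool <- c(rx$phs_universe, "Paeonia obovata", "Glycyrrhiza glabra",
            "Oryza sativa", "Zea mays", "Cuscuta chinensis",
            paste("Genus", letters[1:12]))
  pool <- pool[has_ep <- grepl(" ", pool)]
  for (i in 1:20) {
    sp <- sample(pool, 20L, replace = FALSE)
    row <- stats::setNames(sample(0:50, 20L, replace = TRUE), sp)
    a <- audit_sample(row, rx)
    want <- table(factor(
      vapply(names(row)[row > 0], function(s) {
        oracle_category(normalize_taxon(s), rx)
      }, ""),
      levels = c("PHS", "SHS", "CHS")
    ))
    expect_equal(c(a$n_phs, a$n_shs, a$n_chs), unname(as.integer(want)))
  }
})

test_that("PHM detection pools samples and honours shared PHS", {
  rx <- prescription(
    "P", c("m1", "m2", "m3"),
    list("Aa bb", c("Aa bb", "Cc dd"), "Ee ff")
  )
  s1 <- audit_sample(c("Aa bb" = 3L), rx, "s1")
  s2 <- audit_sample(c("Gg hh" = 2L), rx, "s2")
  # one PHS shared by two PHMs marks both detected
  expect_setequal(detect_phms(list(s1, s2), rx), c("m1", "m2"))
  # order of samples is irrelevant
  expect_setequal(detect_phms(list(s2, s1), rx), c("m1", "m2"))
  # nothing detected -> empty set
  expect_length(detect_phms(list(s2), rx), 0L)
})

test_that("sensitivity is the rounded detected-over-total percentage", {
  expect_equal(sensitivity_pct(25, 36), 69.4)
  expect_equal(sensitivity_pct(0, 9), 0)
  expect_equal(sensitivity_pct(8, 8), 100)
  # half-up at the boundary: 28/36 = 77.77..; 7/9 = 77.77..; 5/8 = 62.5
  expect_equal(sensitivity_pct(28, 36), 77.8)
  expect_equal(sensitivity_pct(5, 8), 62.5)
  rx <- ygw_rx()
  expect_equal(sensitivity(rx$phms$phm[1:6], rx), 66.7)
  expect_error(sensitivity("not a phm", rx), "outside")
})

test_that("union reports merge PHS and recompute sensitivity", {
  rx <- ygw_rx()
  # detected sets consistent with the printed YGW counts: 6 PHMs by
  # ITS2, 4 by trnL, 7 in union
  its2 <- detection_report(
    c("Aconitum carmichaeli", "Angelica sinensis", "Cinnamomum cassia",
      "Cornus officinalis", "Eucommia ulmoides", "Lycium barbarum"),
    rx, "ITS2"
  )
  trnl <- detection_report(
    c("Lycium barbarum", "Eucommia ulmoides", "Cornus officinalis",
      "Rehmannia glutinosa"),
    rx, "trnL"
  )
  expect_equal(length(its2$detected_phms), 6L)
  expect_equal(its2$sensitivity_pct, 66.7)
  expect_equal(length(trnl$detected_phms), 4L)
  uni <- union_barcodes(list(its2, trnl), rx)
  expect_equal(uni$barcode, "UNION")
  expect_equal(length(uni$detected_phms), 7L)
  expect_equal(uni$sensitivity_pct, 77.8)
  # union with an empty report is the identity
  none <- detection_report(character(0), rx, "trnL")
  uni2 <- union_barcodes(list(its2, none), rx)
  expect_equal(uni2$detected_phms, its2$detected_phms)
  expect_equal(uni2$sensitivity_pct, its2$sensitivity_pct)
  # mismatched preparations refuse to combine
  other <- detection_report("Aa bb", prescription("Q", "m", list("Aa bb")),
                            "ITS2")
  expect_error(union_barcodes(list(its2, other), rx), "belong")
})

test_that("union sensitivity dominates the per-barcode maxima", {
  set.seed(53)
  universe <- as.vector(outer(paste0("Genus", letters[1:8]),
                              paste0("sp", 1:4), paste))
  for (i in 1:1000) {
    n_phm <- sample(2:8, 1)
    phs <- replicate(n_phm, sample(universe, sample(1:2, 1)),
                     simplify = FALSE)
    rx <- prescription("R", paste0("m", seq_len(n_phm)), phs)
    d1 <- sample(rx$phs_universe, sample(0:length(rx$phs_universe), 1))
    d2 <- sample(rx$phs_universe, sample(0:length(rx$phs_universe), 1))
    r1 <- detection_report(d1, rx, "ITS2")
    r2 <- detection_report(d2, rx, "trnL")
    u <- union_barcodes(list(r1, r2), rx)
    expect_gte(u$sensitivity_pct,
               max(r1$sensitivity_pct, r2$sensitivity_pct))
  }
})

test_that("presence matrices cover the PHS universe", {
  rx <- toy_rx()
  tab <- build_table(
    list(
      s1 = c("Paeonia lactiflora" = 10L, "Oryza sativa" = 500L,
             "Cuscuta australis" = 8L),
      s2 = c("Glycyrrhiza uralensis" = 4L)
    ),
    "ITS2"
  )
  pm <- presence_matrix(tab, rx)
  expect_equal(colnames(pm), rx$phs_universe)
  expect_equal(unname(rowSums(pm)), c(2, 1))
  expect_true(all(pm %in% c(0L, 1L)))
  rel <- attr(pm, "rel")
  expect_equal(dim(rel), dim(pm))
  # all-zero table -> zero matrix
  m0 <- matrix(0L, 1, 1, dimnames = list("s1", "Paeonia lactiflora"))
  pm0 <- presence_matrix(abundance_table(m0, "ITS2"), rx)
  expect_true(all(pm0 == 0L))
})

test_that("fixture row totals match the transcribed tick counts", {
  m <- load_detection_fixture("NJW", "ITS2")
  want <- c(
    "Astragalus membranaceus" = 18, "Codonopsis pilosula" = 16,
    "Curcuma kwangsiensis" = 2, "Curcuma longa" = 1,
    "Curcuma wenyujin" = 1, "Ligusticum chuanxiong" = 18,
    "Mentha haplocalyx" = 8, "Nardostachys jatamansi" = 6,
    "Paeonia lactiflora" = 18, "Scutellaria baicalensis" = 7,
    "Senna obtusifolia" = 18, "Senna tora" = 18
  )
  expect_equal(rowSums(m)[names(want)], want)
  # the trnL table has 17 sample columns (one sample absent at source)
  expect_equal(ncol(load_detection_fixture("NJW", "trnL")), 17L)
})

test_that("detection reports serialize to JSON and TSV", {
  rx <- toy_rx()
  rep <- detection_report("Paeonia lactiflora", rx, "ITS2")
  fj <- tempfile(fileext = ".json")
  ft <- tempfile(fileext = ".tsv")
  write_detection_report(rep, fj)
  write_detection_report(rep, ft)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$sensitivity_pct, rep$sensitivity_pct)
  expect_true(any(grepl("sensitivity", readLines(ft))))
})
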