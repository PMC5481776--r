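test_that("detection rule is strict at the limit of detection", {
  expect_true(detect(20, lod_ct = 24))
  expect_false(detect(NA_real_, lod_ct = 24))
  # Ct exactly at the LoD would transform to 2^0 = 1; it is censored, so the
  # detection rule must agree and call it undetected
  expect_false(detect(24, lod_ct = 24))
  expect_false(detect(30, lod_ct = 24))
  expect_equal(detect(c(10, NA, 24, 23.999), 24), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("classify_cell applies the marker rules in order", {
  cfg <- gating_config()
  qc <- c("Gapdh", "Hprt")
  expect_equal(classify_cell(cell_row(c(qc, "Cdh5")), cfg), "cdh5_only")
  expect_equal(classify_cell(cell_row(c(qc, "Myh11")), cfg), "myh11_only")
  expect_equal(classify_cell(cell_row(c(qc, "Cdh5", "Ptprc")), cfg),
               "other_markers")
  expect_equal(classify_cell(cell_row(c("Hprt", "Cdh5")), cfg), "qc_fail")
  expect_equal(classify_cell(cell_row(qc), cfg), "no_marker")
  # double target-positive without an exception is excluded
  expect_equal(classify_cell(cell_row(c(qc, "Cdh5", "Myh11")), cfg),
               "other_markers")
  expect_error(classify_cell(c(Gapdh = 12), cfg),
               class = "scgpcr_config_error")
})

test_that("the low-cross-marker exception admits Cdh5+/Myh11-low cells only", {
  cfg <- gating_config(allow_low_cross_marker =
                         list(marker = "Myh11", max_expression = 16))
  row <- cell_row(c("Gapdh", "Hprt", "Cdh5"))
  row["Myh11"] <- 21   # expression 2^3 = 8 <= 16: tolerated
  expect_equal(classify_cell(row, cfg), "cdh5_only")
  row["Myh11"] <- 15   # expression 2^9: genuine double positive
  expect_equal(classify_cell(row, cfg), "other_markers")
})

test_that("gating labels partition the input and percentages sum to 100", {
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = list(n_cells = 120L, target = "smc"),
                   b = list(n_cells = 80L, target = "smc")),
    n_gpcr = 20L, contamination_fraction = 0.2, seed = 5))
  gr <- gate_cells(sim$ct, sim$panel, target = "smc")
  expect_length(gr$labels, 200L)
  expect_equal(sum(table(gr$labels)), 200L)
  pct_cols <- c("cdh5_only", "myh11_only", "other_markers", "no_marker")
  sums <- rowSums(gr$contamination[, pct_cols])
  expect_true(all(abs(sums - 100) < 0.1))
})

test_that("planted contamination is recovered within its 99% binomial interval", {
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = list(n_cells = 250L, target = "smc")),
    n_gpcr = 30L, contamination_fraction = 0.15, seed = 23))
  gr <- gate_cells(sim$ct, sim$panel, target = "smc")
  est <- sum(gr$contamination[, c("other_markers", "no_marker")]) / 100
  ci <- stats::qbinom(c(0.005, 0.995), 250L, 0.15) / 250L
  expect_gte(est, ci[1])
  expect_lte(est, ci[2])
  # the gated contaminants are exactly the planted ones
  flagged <- names(gr$labels)[gr$labels %in% c("other_markers", "no_marker")]
  planted <- names(sim$truth$contaminant)[sim$truth$contaminant != "target"]
  expect_setequal(flagged, planted)
})

test_that("a detected lineage marker always removes a cell from the retained set", {
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = list(n_cells = 30L, target = "smc")),
    n_gpcr = 10L, seed = 2))
  gr <- gate_cells(sim$ct, sim$panel, target = "smc")
  retained <- cell_ids(gr$retained)
  spiked <- sim$ct
  spiked$ct[retained, "Ptprc"] <- 15          # contaminate every retained cell
  gr2 <- suppressWarnings(gate_cells(ct_matrix(spiked$ct, spiked$metadata),
                                     sim$panel, target = "smc"))
  expect_true(all(gr2$labels[retained] == "other_markers"))
  expect_true(is.null(gr2$retained) ||
                !any(retained %in% cell_ids(gr2$retained)))
})

test_that("pure target populations give a 100% single-label column", {
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = list(n_cells = 40L, target = "ec")),
    n_gpcr = 10L, contamination_fraction = 0, seed = 9))
  gr <- gate_cells(sim$ct, sim$panel, target = "ec")
  expect_equal(gr$contamination$cdh5_only, 100)
  expect_equal(nrow(gr$retained$ct), 40L)
})

test_that("an empty retained set warns rather than errors", {
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = list(n_cells = 10L, target = "smc")),
    n_gpcr = 5L, seed = 4))
  expect_warning(gr <- gate_cells(sim$ct, sim$panel, target = "ec"),
                 "no cells retained")
  expect_null(gr$retained)
})
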