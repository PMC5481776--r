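make_lanes <- function(endo, pos, neg) {
  lanes <- paste0("L", seq_len(ncol(endo)))
  nanostring_lanes(
    matrix(endo, ncol = ncol(endo),
           dimnames = list(paste0("e", seq_len(nrow(endo))), lanes)),
    matrix(pos, ncol = ncol(pos),
           dimnames = list(paste0("p", seq_len(nrow(pos))), lanes)),
    matrix(neg, ncol = ncol(neg),
           dimnames = list(paste0("n", seq_len(nrow(neg))), lanes)))
}

test_that("positive-spike normalization equalizes geometric means", {
  # identical lanes: both factors 1
  endo <- cbind(c(100, 50), c(100, 50))
  pos <- cbind(c(1000, 100, 10), c(1000, 100, 10))
  neg <- matrix(10, 8, 2)
  same <- positive_spike_normalize(make_lanes(endo, pos, neg))
  expect_equal(unname(same$factors), c(1, 1))
  # lane B exactly doubles lane A: factors (3/2, 3/4), equal geomeans after
  dbl <- positive_spike_normalize(make_lanes(cbind(c(100, 50), c(200, 100)),
                                             cbind(c(1000, 10), c(2000, 20)),
                                             cbind(matrix(10, 8, 1),
                                                   matrix(20, 8, 1))))
  expect_equal(unname(dbl$factors), c(1.5, 0.75))
  gm <- apply(dbl$positive, 2, function(x) exp(mean(log(x))))
  expect_equal(gm[[1]], gm[[2]], tolerance = 1e-12)
  expect_error(positive_spike_normalize(make_lanes(endo, cbind(c(0, 1), c(1, 1)),
                                                   neg)),
               class = "scgpcr_input_error")
})

test_that("background correction implements mean + 2 s.d. of the negatives", {
  negs <- c(8, 10, 12, 10, 9, 11, 10, 10)
  lanes <- make_lanes(matrix(c(30, 5), 2, 1), matrix(100, 1, 1),
                      matrix(negs, 8, 1))
  bc <- background_correct(lanes)
  expected_bg <- mean(negs) + 2 * stats::sd(negs)
  expect_equal(unname(bc$background), expected_bg)
  expect_equal(unname(bc$endogenous[, 1]), pmax(c(30, 5) - expected_bg, 0))
  # zero-variance negatives: background equals their common value
  flat <- background_correct(make_lanes(matrix(30, 1, 1), matrix(100, 1, 1),
                                        matrix(10, 8, 1)))
  expect_equal(unname(flat$background), 10)
  expect_equal(unname(flat$endogenous[1, 1]), 20)
  # wrong negative count warns (or errors in strict mode)
  bad <- make_lanes(matrix(30, 1, 1), matrix(100, 1, 1), matrix(10, 6, 1))
  expect_warning(background_correct(bad), "8 negative")
  expect_error(background_correct(bad, strict = TRUE),
               class = "scgpcr_input_error")
})

test_that("values below the floor are fixed and flagged", {
  lanes <- make_lanes(matrix(c(5, 20, 500), 3, 1), matrix(100, 1, 1),
                      matrix(10, 8, 1))
  fl <- floor_low_values(lanes, floor = 20)
  expect_equal(unname(fl$endogenous[, 1]), c(20, 20, 500))
  expect_equal(unname(fl$below_floor[, 1]), c(TRUE, FALSE, FALSE))
  lanes$background <- c(L1 = 12.5)
  alt <- floor_low_values(lanes, floor = 20, mode = "lane_background")
  expect_equal(unname(alt$endogenous[1, 1]), 12.5)
})

test_that("planted lane factors are recovered exactly without noise", {
  sim <- simulate_nanostring(3, factors = c(1, 0.5, 2), seed = 7, noise = FALSE)
  norm <- positive_spike_normalize(sim$lanes)
  rec <- norm$factors / mean(norm$factors)
  planted <- sim$truth$factors / mean(sim$truth$factors)
  expect_equal(unname(rec), planted, tolerance = 1e-9)
  gm <- apply(norm$positive, 2, function(x) exp(mean(log(x))))
  expect_lt(diff(range(gm)) / mean(gm), 1e-12)
})

test_that("the normalization chain is equivariant under lane permutation", {
  sim <- simulate_nanostring(4, factors = c(1, 0.5, 2, 1.5), seed = 13)
  full <- normalize_nanostring(sim$lanes)
  perm <- c(3, 1, 4, 2)
  permuted <- sim$lanes
  for (nm in c("endogenous", "positive", "negative")) {
    permuted[[nm]] <- permuted[[nm]][, perm]
  }
  full_p <- normalize_nanostring(permuted)
  expect_equal(full_p$endogenous, full$endogenous[, perm])
  expect_equal(full_p$factors, full$factors[perm])
})

test_that("geNorm M values follow the published pairwise-variation formula", {
  # proportional genes have pairwise variation zero
  counts <- rbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16), C = c(5, 5, 2, 9))
  M <- genorm_stability(counts)
  V <- attr(M, "V")
  expect_equal(V["A", "B"], 0)
  # direct computation of the formula for the hand instance
  v_ac <- stats::sd(log2(counts["A", ] / counts["C", ]))
  expect_equal(V["A", "C"], v_ac)
  expect_equal(unname(M["A"]), (0 + v_ac) / 2)
  expect_false(is.unsorted(M))
  # a planted unstable gene gets the largest M
  withr::local_seed(103)
  stable <- matrix(rep(c(100, 120, 90, 110), each = 3), 3, byrow = FALSE) *
    matrix(stats::runif(12, 0.97, 1.03), 3)
  noisy <- rbind(stable, unstable = c(10, 400, 50, 900))
  rownames(noisy) <- c("r1", "r2", "r3", "unstable")
  M2 <- genorm_stability(noisy)
  expect_equal(names(which.max(M2)), "unstable")
  # ratio-based: multiplying one sample's counts leaves M unchanged
  scaled <- noisy
  scaled[, 2] <- scaled[, 2] * 7.5
  expect_equal(genorm_stability(scaled), M2, tolerance = 1e-12)
  expect_error(genorm_stability(rbind(c(1, 0), c(1, 1), c(2, 2))),
               class = "scgpcr_input_error")
})
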