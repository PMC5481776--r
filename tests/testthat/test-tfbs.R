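test_that("log-odds scoring matches hand computation", {
  # uniform motif against uniform background scores zero everywhere
  uni <- pwm("U", matrix(1, 4, 3), pseudocount = 0.01)
  expect_equal(unname(pwm_log_odds(uni)), matrix(0, 4, 3))
  # two-column hand instance
  p <- pwm("H", matrix(c(3, 1, 0, 0,
                         0, 0, 2, 2), 4), pseudocount = 0.5)
  S <- pwm_log_odds(p, c(A = 0.4, C = 0.2, G = 0.2, T = 0.2))
  expect_equal(unname(S["A", 1]), log2(((3 + 0.5) / (4 + 2)) / 0.4))
  expect_equal(unname(S["G", 2]), log2(((2 + 0.5) / (4 + 2)) / 0.2))
  # a near-pure column approaches log2(4) for its base
  pure <- pwm("P", matrix(c(1e6, 0, 0, 0), 4, 1), pseudocount = 0.01)
  Sp <- pwm_log_odds(pure)
  expect_equal(unname(Sp["A", 1]), 2, tolerance = 1e-4)
  expect_lt(Sp["C", 1], -10)
})

test_that("best_hit_score attains its extremes and equals brute-force scanning", {
  p <- informative_pwm("TGACG")
  bg <- rep(0.25, 4); names(bg) <- c("A", "C", "G", "T")
  withr::local_seed(83)
  hit <- paste0(random_seq(12), "TGACG", random_seq(13))
  expect_equal(best_hit_score(hit, p, bg), 1, tolerance = 1e-6)
  # all-A sequence against a G-consensus motif scores the minimum everywhere
  # (and so does its reverse complement, all-T)
  p0 <- informative_pwm("GGGGG")
  expect_equal(best_hit_score(strrep("A", 30), p0, bg), 0)
  # brute-force oracle: enumerate 2 strands x all offsets explicitly
  brute <- function(seq, p, bg) {
    S <- pwm_log_odds(p, bg)
    L <- ncol(S)
    score_one <- function(s) {
      chars <- strsplit(s, "")[[1]]
      if (any(!chars %in% c("A", "C", "G", "T"))) return(NA_real_)
      sum(vapply(seq_len(L), function(j) S[chars[j], j], numeric(1)))
    }
    cand <- c()
    for (strand_seq in c(seq, reverse_complement(seq))) {
      for (i in seq_len(nchar(strand_seq) - L + 1)) {
        cand <- c(cand, score_one(substr(strand_seq, i, i + L - 1)))
      }
    }
    if (all(is.na(cand))) return(NA_real_)
    smin <- sum(apply(S, 2, min)); smax <- sum(apply(S, 2, max))
    (max(cand, na.rm = TRUE) - smin) / (smax - smin)
  }
  for (i in 1:25) {
    sq <- random_seq(30, bases = c("A", "C", "G", "T", if (i %% 5 == 0) "N"))
    pw <- random_pwm(5)
    expect_equal(best_hit_score(sq, pw, bg), brute(sq, pw, bg),
                 tolerance = 1e-12)
  }
  # invariance under reverse complement of the input
  for (i in 1:10) {
    sq <- random_seq(40)
    pw <- random_pwm(6)
    expect_equal(best_hit_score(sq, pw, bg),
                 best_hit_score(reverse_complement(sq), pw, bg),
                 tolerance = 1e-12)
  }
  # shorter than the motif: missing
  expect_true(is.na(best_hit_score("ACG", p, bg)))
})

test_that("set enrichment is null for the full set and detects planted motifs", {
  withr::local_seed(89)
  scores <- stats::setNames(stats::runif(100), sprintf("g%03d", 1:100))
  full <- set_enrichment(names(scores), scores)
  expect_equal(full$z, 0)
  expect_equal(full$p_value, 1)
  # zero-variance background degenerates to z = 0, p = 1
  flat <- stats::setNames(rep(0.4, 50), sprintf("g%03d", 1:50))
  r0 <- set_enrichment(names(flat)[1:5], flat)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # planted motif: every set promoter carries an instance, background none
  motif <- informative_pwm("TGACGTCA")
  sim <- simulate_promoters(120, length = 400, motif = motif,
                            planted_set = sprintf("g%03d", 1:20), seed = 3)
  sc <- best_hit_scores(sim$seqs, list(motif))[, 1]
  r <- set_enrichment(sprintf("g%03d", 1:20), sc, tf = "PLANTED")
  expect_lt(r$p_value, 0.05)
  expect_equal(r$direction, "over")
  # complement has the opposite sign when the background is the union
  rc <- set_enrichment(sprintf("g%03d", 21:120), sc)
  expect_lt(rc$z, 0)
  expect_gt(r$z, 0)
})

test_that("z transformation maps p-values to signed normal quantiles", {
  expect_equal(scgpcr:::z_transform_p(1, "over"), 0)
  expect_equal(scgpcr:::z_transform_p(0.05, "over"), 1.959964, tolerance = 1e-6)
  expect_equal(scgpcr:::z_transform_p(0.05, "under"), -1.959964,
               tolerance = 1e-6)
  expect_equal(scgpcr:::z_transform_p(1e-300, "over"), 8)   # clipped
  tab <- data.frame(tf = c("A", "A", "B", "B"),
                    gene_set = c("s1", "s2", "s1", "s2"),
                    p_value = c(0.05, 1, 0.01, 0.5),
                    direction = c("over", "over", "under", "under"))
  zm <- z_transform_table(tab)
  expect_equal(dim(zm), c(2L, 2L))
  expect_gt(zm["A", "s1"], 0)
  expect_lt(zm["B", "s1"], 0)
  expect_equal(zm["A", "s2"], 0)
})

test_that("promoter extraction is strand-aware and half-open", {
  genome <- c(chr1 = "AAAACGTTTTGGGCCCAT")
  tss <- data.frame(gene = c("plus", "minus"), chrom = "chr1",
                    tss = c(11, 8), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  pr <- extract_promoters(genome, tss, upstream = 4, downstream = 2)
  # plus: positions [11-4, 11+2) = 7..12 -> TTTTGG
  expect_equal(unname(pr["plus"]), "TTTTGG")
  # minus: genomic window (tss-2, tss+4] = 7..12 -> TTTTGG, then revcomp
  expect_equal(unname(pr["minus"]), reverse_complement("TTTTGG"))
  # truncation at the chromosome edge is flagged
  tr <- extract_promoters(genome, data.frame(gene = "edge", chrom = "chr1",
                                             tss = 2, strand = "+"),
                          upstream = 4, downstream = 2)
  expect_equal(attr(tr, "truncated"), "edge")
})

test_that("tfbs_enrichment assembles a full table over sets and motifs", {
  withr::local_seed(97)
  motif <- informative_pwm("ACGTAC", name = "ACGTAC")
  sim <- simulate_promoters(60, length = 200, motif = motif,
                            planted_set = sprintf("g%03d", 1:10), seed = 5)
  pwms <- list(motif, random_pwm(6, "DECOY"))
  sets <- list(planted = sprintf("g%03d", 1:10),
               random = sprintf("g%03d", 31:40))
  tab <- tfbs_enrichment(sim$seqs, pwms, sets)
  expect_equal(nrow(tab), 4L)
  planted_row <- tab[tab$tf == "ACGTAC" & tab$gene_set == "planted", ]
  expect_equal(planted_row$direction, "over")
  expect_lt(planted_row$p_value, 0.05)
  expect_equal(sign(tab$z_signed), ifelse(tab$direction == "over", 1, -1) *
                 (tab$p_value < 1))
})
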