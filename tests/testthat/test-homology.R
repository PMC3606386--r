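test_that("lambda solves the Karlin-Altschul root equation", {
  sc <- calibrate_scoring(scoring_scheme("nucleotide", match = 1,
                                         mismatch = -1))
  # independent bisection oracle on (4/16) e^l + (12/16) e^-l = 1
  f <- function(l) (4 / 16) * exp(l) + (12 / 16) * exp(-l) - 1
  lo <- 1e-9; hi <- 4
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(sc$lambda, (lo + hi) / 2, tolerance = 1e-9)
  expect_equal(sc$lambda, log(3), tolerance = 1e-9)  # closed form
})

test_that("calibration rejects non-negative expected scores", {
  expect_error(
    calibrate_scoring(scoring_scheme("nucleotide", match = 1, mismatch = 1)),
    "calibration error")
})

test_that("doubling all scores halves lambda", {
  s1 <- calibrate_scoring(scoring_scheme("nucleotide", match = 1,
                                         mismatch = -1))
  s2 <- calibrate_scoring(scoring_scheme("nucleotide", match = 2,
                                         mismatch = -2))
  expect_equal(s2$lambda, s1$lambda / 2, tolerance = 1e-9)
})

test_that("E-value formula identities hold", {
  sc <- NT_SCHEME
  m <- 500; n <- 1e6
  s_unit <- log(sc$K * m * n) / sc$lambda
  expect_equal(evalue_of(s_unit, m, n, sc), 1.0, tolerance = 1e-12)
  expect_equal(evalue_of(100, m, 2 * n, sc), 2 * evalue_of(100, m, n, sc))
  expect_lt(evalue_of(110, m, n, sc), evalue_of(100, m, n, sc))
  expect_error(evalue_of(100, m, n, scoring_scheme("nucleotide")),
               "not calibrated")
})

test_that("self-hit covers the full sequence at 100% identity", {
  set.seed(11)
  q <- random_seq(1000)
  h <- find_hsps(c(q = q), c(s = q), NT_SCHEME)
  expect_gte(nrow(h), 1L)
  expect_identical(h$q_start[[1L]], 0L)
  expect_identical(h$q_end[[1L]], 1000L)
  expect_identical(h$s_start[[1L]], 0L)
  expect_identical(h$s_end[[1L]], 1000L)
  expect_equal(h$pct_identity[[1L]], 100)
  expect_identical(h$raw_score[[1L]], 2000L)
})

test_that("unrelated random sequences yield nothing at the screen cutoff", {
  set.seed(42)
  q <- random_seq(1000)
  s <- random_seq(1000)
  # oracle: optimal local score is far below the score needed for 1e-5
  need <- log(NT_SCHEME$K * 1000 * 1000 / 1e-5) / NT_SCHEME$lambda
  expect_lt(sw_score(q, s, NT_SCHEME), need)
  h <- find_hsps(c(q = q), c(s = s), NT_SCHEME, evalue_cutoff = 1e-5)
  expect_identical(nrow(h), 0L)
})

test_that("engine best score never exceeds Smith-Waterman and matches it
           on ungapped-similar pairs", {
  set.seed(7)
  cases <- list()
  # ungapped-similar: planted identical/diverged blocks, no indels
  for (div in c(0, 0.05, 0.15)) {
    q <- random_seq(800)
    block <- random_seq(300)
    s <- random_seq(800)
    substr(q, 201, 500) <- block
    substr(s, 101, 400) <- mutate_dna(block, div)
    cases[[length(cases) + 1L]] <- list(q = q, s = s, ungapped = TRUE)
  }
  # gapped: indel-bearing homology
  q <- random_seq(1200)
  s <- paste0(substr(q, 1, 500), substr(q, 541, 1200))  # 40 bp deletion
  cases[[length(cases) + 1L]] <- list(q = q, s = s, ungapped = FALSE)
  # unrelated
  cases[[length(cases) + 1L]] <- list(q = random_seq(600),
                                      s = random_seq(600), ungapped = FALSE)
  for (cs in cases) {
    sw <- sw_score(cs$q, cs$s, NT_SCHEME)
    h <- find_hsps(c(q = cs$q), c(s = cs$s), NT_SCHEME, evalue_cutoff = Inf)
    best <- if (nrow(h)) max(h$raw_score) else 0
    expect_lte(best, sw + 1e-9)
    if (cs$ungapped) expect_equal(best, sw)
  }
})

test_that("E-value calibration is conservative on random pairs", {
  # Karlin-Altschul conservativeness: fraction of random pairs with best
  # E <= e should not exceed 2e
  set.seed(123)
  n_pairs <- 500
  hits <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    q <- random_seq(300)
    s <- random_seq(300)
    h <- find_hsps(c(q = q), c(s = s), NT_SCHEME, evalue_cutoff = Inf)
    hits[i] <- if (nrow(h)) h$evalue[[1L]] else Inf
  }
  for (e in c(0.01, 0.1))
    expect_lte(mean(hits <= e), 2 * e)
})

test_that("reverse-complementing the query flips strand, keeps subject
           interval and score", {
  set.seed(19)
  s <- random_seq(1500)
  q <- substr(s, 301, 800)
  h_fwd <- find_hsps(c(q = q), c(s = s), NT_SCHEME)
  h_rev <- find_hsps(c(q = revcomp(q)), c(s = s), NT_SCHEME)
  expect_identical(nrow(h_fwd), nrow(h_rev))
  expect_identical(h_fwd$s_start, h_rev$s_start)
  expect_identical(h_fwd$s_end, h_rev$s_end)
  expect_identical(h_fwd$raw_score, h_rev$raw_score)
  expect_true(all(h_fwd$strand != h_rev$strand))
})

test_that("best_hit applies the E / score / subject-id tie rules", {
  set.seed(23)
  q <- random_seq(400)
  mut <- mutate_dna(q, 0.2)
  h <- best_hit(c(q = q), c(zz_self = q, aa_mut = mut), NT_SCHEME)
  expect_identical(h$subject_id, "zz_self")
  # identical subjects under different names: lexicographic tie-break
  h2 <- best_hit(c(q = q), c(b_copy = q, a_copy = q), NT_SCHEME)
  expect_identical(h2$subject_id, "a_copy")
  expect_null(best_hit(c(q = q), character(0), NT_SCHEME))
})

test_that("degenerate inputs return empty results, not errors", {
  expect_identical(nrow(find_hsps(c(q = "ACGTACGT"), c(s = "ACGTACGT"),
                                  NT_SCHEME)), 0L)  # word size > length
  expect_identical(nrow(find_hsps(c(q = random_seq(100)), character(0),
                                  NT_SCHEME)), 0L)
})

test_that("protein search finds diverged homologs via neighborhood seeds", {
  set.seed(31)
  p <- paste(sample(c("M", PROT_CHARS[1:20]), 200, TRUE), collapse = "")
  pm <- mutate_protein_test(p, 0.25)
  h <- find_hsps(c(q = p), c(s = pm), AA_SCHEME, evalue_cutoff = 1e-5)
  expect_gte(nrow(h), 1L)
  expect_gt(h$align_len[[1L]], 150L)
  sw <- sw_score(p, pm, AA_SCHEME)
  expect_lte(max(h$raw_score), sw)
})

test_that("hit tables mirror the 12-column tabular format", {
  set.seed(5)
  q <- random_seq(300)
  h <- find_hsps(c(q = q), c(s = q), NT_SCHEME)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(h, f, meta = "test")
  lines <- readLines(f)
  expect_true(startsWith(lines[[1L]], "# "))
  expect_identical(strsplit(lines[[2L]], "\t")[[1L]][1:4],
                   c("qseqid", "sseqid", "pident", "length"))
  row <- strsplit(lines[[3L]], "\t")[[1L]]
  expect_identical(row[[7L]], "1")          # 1-based qstart
  expect_identical(row[[8L]], "300")
})
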