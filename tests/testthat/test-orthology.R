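test_that("identical proteomes pair every gene with itself", {
  withr::with_seed(4, {
    prot <- setNames(vapply(1:6, function(i)
      paste(sample(PROT_CHARS[1:20], 120, TRUE), collapse = ""),
      character(1)), sprintf("g%02d", 1:6))
  })
  pairs <- reciprocal_best_hits(prot, prot, AA_SCHEME)
  expect_identical(nrow(pairs), 6L)
  expect_identical(pairs$gene_a, pairs$gene_b)
  expect_true(all(pairs$pct_identity == 100))
})

test_that("reciprocity is required: a one-way best hit yields no pair", {
  withr::with_seed(14, {
    base <- paste(sample(PROT_CHARS[1:20], 150, TRUE), collapse = "")
    # b's best is c (identical); a is a diverged copy whose best is b or c,
    # but neither reciprocates to a
    protA <- c(a = mutate_protein_test(base, 0.2))
    protB <- c(b = base, c = base)
  })
  pairs <- reciprocal_best_hits(protA, protB, AA_SCHEME)
  # a's best is one of b/c (tie -> b); b's best in A is a (only choice), so
  # the (a, b) pair IS reciprocal; but c never pairs
  expect_false("c" %in% pairs$gene_b)
  # remove a's hit reciprocity by adding a better partner for b
  protA2 <- c(protA, b_twin = unname(protB[["b"]]))
  pairs2 <- reciprocal_best_hits(protA2, protB, AA_SCHEME)
  expect_false("a" %in% pairs2$gene_a)
  expect_true(all(c("b_twin") %in% pairs2$gene_a))
})

test_that("RBH recovers exactly the true pairs in a diverged panel with
           paralog confounders", {
  panel <- simulate_ortholog_panel(2L, tree_depth = 0.25, seed = 11L,
                                   n_genes = 50L, gene_codons = 100L)
  protA <- panel$proteomes$sp1
  protB <- panel$proteomes$sp2
  withr::with_seed(11, {
    paralogs <- setNames(vapply(1:5, function(i)
      mutate_protein_test(protA[[i]], 0.45), character(1)),
      paste0(names(protA)[1:5], "_paralog"))
  })
  protA <- c(protA, paralogs)
  pairs <- reciprocal_best_hits(protA, protB, AA_SCHEME)
  truth <- panel$truth$pairs[["sp1~sp2"]]
  expect_identical(nrow(pairs), 50L)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(truth$gene_a, truth$gene_b))
})

test_that("RBH is symmetric under swapping the proteomes", {
  panel <- simulate_ortholog_panel(2L, tree_depth = 0.3, seed = 21L,
                                   n_genes = 10L, gene_codons = 80L)
  ab <- reciprocal_best_hits(panel$proteomes$sp1, panel$proteomes$sp2,
                             AA_SCHEME)
  ba <- reciprocal_best_hits(panel$proteomes$sp2, panel$proteomes$sp1,
                             AA_SCHEME)
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
})

test_that("identity z-score matches hand computations and printed moments", {
  bk <- function(ids) data.frame(gene_a = paste0("a", seq_along(ids)),
                                 gene_b = paste0("b", seq_along(ids)),
                                 pct_identity = ids,
                                 stringsAsFactors = FALSE)
  focal <- data.frame(gene_a = "fa", gene_b = "fb", pct_identity = 70,
                      stringsAsFactors = FALSE)
  # two-point background {60, 80}: mean 70, sd 14.142 -> z = 0
  z0 <- identity_zscore(focal, bk(c(60, 80)))
  expect_equal(z0$z, 0)
  expect_equal(z0$sd, sqrt(200), tolerance = 1e-12)
  # focal equal to the mean -> 0
  z1 <- identity_zscore(data.frame(gene_a = "x", gene_b = "y",
                                   pct_identity = 70), bk(c(65, 70, 75)))
  expect_equal(z1$z, 0)
  # the published triple: identity 58.5 vs mean 70.7 at z = -0.78 implies
  # sd = 12.2 / 0.78; a background with those moments reproduces z
  implied_sd <- (70.7 - 58.5) / 0.78
  bg <- c(70.7 - implied_sd, 70.7, 70.7 + implied_sd)
  zf <- identity_zscore(data.frame(gene_a = "f", gene_b = "g",
                                   pct_identity = 58.5), bk(bg))
  # sample sd of the 3-point background equals implied_sd exactly
  expect_equal(round(zf$z, 2), -0.78)
  # location shift leaves z unchanged
  zshift <- identity_zscore(data.frame(gene_a = "f", gene_b = "g",
                                       pct_identity = 58.5 + 5), bk(bg + 5))
  expect_equal(zshift$z, zf$z)
  # degenerate background errors
  expect_error(identity_zscore(focal, bk(c(70, 70))), "zero standard")
  expect_error(identity_zscore(focal, bk(70)), "at least 2")
})

test_that("the focal pair is excluded from its own background", {
  bg <- data.frame(gene_a = c("f", "a2", "a3"), gene_b = c("g", "b2", "b3"),
                   pct_identity = c(99, 60, 80), stringsAsFactors = FALSE)
  focal <- data.frame(gene_a = "f", gene_b = "g", pct_identity = 70,
                      stringsAsFactors = FALSE)
  z <- identity_zscore(focal, bg)
  expect_identical(z$n, 2L)
  expect_equal(z$z, 0)
})

.toy_synteny <- function(order_b = NULL, focal_idx = 4L, n = 7L) {
  # two assemblies with n genes each; gene i of A is the ortholog of gene i
  # of B; B's gene order optionally permuted
  glen <- 30L
  mk <- function(ids, prefix) {
    total <- length(ids) * (glen + 10L) + 10L
    seqs <- paste(rep("ACGTACGTAC", total / 10L), collapse = "")
    rows <- data.frame(gene_id = ids, scaffold_id = paste0(prefix, "_s"),
                       start = (seq_along(ids) - 1L) * (glen + 10L),
                       end = (seq_along(ids) - 1L) * (glen + 10L) + glen,
                       strand = "+", stringsAsFactors = FALSE)
    assembly(setNames(substr(seqs, 1, total), paste0(prefix, "_s")), rows,
             validate_cds = FALSE)
  }
  ids_a <- sprintf("a%02d", 1:n)
  ids_b <- sprintf("b%02d", if (is.null(order_b)) 1:n else order_b)
  list(asm_a = mk(ids_a, "A"), asm_b = mk(ids_b, "B"),
       map = data.frame(gene_a = sprintf("a%02d", 1:n),
                        gene_b = sprintf("b%02d", 1:n),
                        stringsAsFactors = FALSE),
       focal = data.frame(gene_a = sprintf("a%02d", focal_idx),
                          gene_b = sprintf("b%02d", focal_idx),
                          stringsAsFactors = FALSE))
}

test_that("identical gene order gives full shared flanks and conserved
           order", {
  fx <- .toy_synteny()
  rep <- microsynteny(fx$focal, fx$asm_a, fx$asm_b, fx$map, window = 3L)
  expect_equal(rep$shared_flank_fraction, 1.0)
  expect_true(rep$order_conserved)
})

test_that("a shuffled partner window breaks order conservation", {
  withr::with_seed(3, perm <- sample(7))
  # keep the focal gene in place so it can be located
  perm <- c(setdiff(perm, 4L)[1:3], 4L, setdiff(perm, 4L)[4:6])
  fx <- .toy_synteny(order_b = perm)
  rep <- microsynteny(fx$focal, fx$asm_a, fx$asm_b, fx$map, window = 3L)
  expect_false(rep$order_conserved)
})

test_that("whole-window reversal still counts as conserved order", {
  fx <- .toy_synteny(order_b = 7:1, focal_idx = 4L)
  rep <- microsynteny(fx$focal, fx$asm_a, fx$asm_b, fx$map, window = 3L)
  expect_equal(rep$shared_flank_fraction, 1.0)
  expect_true(rep$order_conserved)
})

test_that("windows clip at scaffold ends", {
  fx <- .toy_synteny(focal_idx = 1L)
  rep <- microsynteny(fx$focal, fx$asm_a, fx$asm_b, fx$map, window = 3L)
  expect_identical(rep$n_flank, 3L)   # upstream side is empty
  expect_error(
    microsynteny(data.frame(gene_a = "zz", gene_b = "b01"), fx$asm_a,
                 fx$asm_b, fx$map, window = 3L), "not found")
})

test_that("neighbor distance reproduces the 85 bp arrangement and ties", {
  mk <- function(genes) {
    assembly(c(s = paste(rep("A", 500), collapse = "")), genes,
             validate_cds = FALSE)
  }
  g <- data.frame(gene_id = c("lgt", "host"), scaffold_id = "s",
                  start = c(0L, 185L), end = c(100L, 300L),
                  strand = c("+", "-"), stringsAsFactors = FALSE)
  nd <- neighbor_distance("lgt", mk(g))
  expect_identical(nd$neighbor_id, "host")
  expect_identical(nd$gap_bp, 85L)
  # overlap -> 0
  g2 <- data.frame(gene_id = c("x", "y"), scaffold_id = "s",
                   start = c(0L, 50L), end = c(100L, 200L), strand = "+",
                   stringsAsFactors = FALSE)
  expect_identical(neighbor_distance("x", mk(g2))$gap_bp, 0L)
  # middle focal takes the nearer flank; exact ties go downstream
  g3 <- data.frame(gene_id = c("up", "mid", "down"), scaffold_id = "s",
                   start = c(0L, 150L, 260L), end = c(100L, 250L, 300L),
                   strand = "+", stringsAsFactors = FALSE)
  nd3 <- neighbor_distance("mid", mk(g3))
  expect_identical(nd3$neighbor_id, "down")  # 10 bp vs 50 bp
  g4 <- data.frame(gene_id = c("up", "mid", "down"), scaffold_id = "s",
                   start = c(0L, 150L, 300L), end = c(100L, 250L, 400L),
                   strand = "+", stringsAsFactors = FALSE)
  expect_identical(neighbor_distance("mid", mk(g4))$neighbor_id, "down")
  # single-gene scaffold -> NULL
  g5 <- g[1, , drop = FALSE]
  expect_null(neighbor_distance("lgt", mk(g5)))
})
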