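test_that("generators are pure functions of the recipe", {
  rec <- simulation_recipe(seed = 1L)
  a1 <- simulate_host_assembly(rec)
  a2 <- simulate_host_assembly(rec)
  expect_identical(a1$assembly$scaffolds, a2$assembly$scaffolds)
  expect_identical(a1$assembly$genes, a2$assembly$genes)
  s1 <- simulate_screen_inputs(rec)
  s2 <- simulate_screen_inputs(rec)
  expect_identical(s1$assembly$scaffolds, s2$assembly$scaffolds)
  expect_identical(s1$bacterial_db, s2$bacterial_db)
  # byte-identical FASTA output
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen_inputs(s1, d1); write_screen_inputs(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_screen_inputs(rec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("host assemblies honor the recipe shape and GC content", {
  rec <- simulation_recipe(seed = 1L, host_gc = 0.30)
  sim <- simulate_host_assembly(rec)
  g <- sim$assembly$genes
  expect_identical(nrow(g), 30L)
  expect_length(sim$assembly$scaffolds, 3L)
  # genes non-overlapping within scaffolds
  for (sid in unique(g$scaffold_id)) {
    gg <- g[g$scaffold_id == sid, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # every CDS translates with no internal stop
  for (cds in g$cds_seq) {
    aa <- translate_cds(cds)
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # GC within the binomial concentration band at 50 kb (genes perturb it
  # slightly; the intergenic background is at the recipe GC)
  gc <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("G", "C"))
  }
  gcs <- vapply(sim$assembly$scaffolds, gc, numeric(1))
  expect_true(all(abs(gcs - 0.30) < 0.05))
  # genes that cannot fit error out
  expect_error(simulate_host_assembly(
    simulation_recipe(seed = 1, scaffold_length_bp = 3000L,
                      genes_per_scaffold = 10L)), "do not fit")
})

test_that("implants land intergenically at the requested divergence", {
  rec <- simulation_recipe(seed = 4L)
  host <- simulate_host_assembly(rec)
  withr::with_seed(50, donor <- random_seq(2001 %/% 3 * 3))
  imp <- implant_lgt(host$assembly, donor, "donor", 0, seed = 4L)
  tr <- imp$truth
  region <- scaffold_region(imp$assembly, tr$scaffold_id, tr$start, tr$end)
  expect_identical(region, donor)           # divergence 0: verbatim copy
  # no overlap with annotated genes
  g <- imp$assembly$genes[imp$assembly$genes$scaffold_id == tr$scaffold_id, ]
  expect_false(any(g$start < tr$end & g$end > tr$start))
  # divergence 0.3 realizes a mismatch fraction within the binomial band
  imp3 <- implant_lgt(host$assembly, donor, "donor", 0.3, seed = 5L)
  expect_lt(abs(imp3$truth$realized_divergence - 0.3), 0.05)
  # a donor too large for any intergenic gap errors
  expect_error(implant_lgt(host$assembly, strrep("ACG", 20000), "big", 0.1,
                           seed = 6L), "no intergenic room")
})

test_that("the decoy construction makes the animal hit beat the bacterial
           hit", {
  rec <- simulation_recipe(seed = 7L)
  sim <- simulate_screen_inputs(rec)
  decoy_gene <- sim$truth$decoy$decoy_gene_id
  row <- sim$assembly$genes[sim$assembly$genes$gene_id == decoy_gene, ]
  region <- setNames(row$cds_seq, "decoy")
  bact <- best_hit(region, sim$bacterial_db, NT_SCHEME)
  anim <- best_hit(region, sim$animal_db, NT_SCHEME)
  expect_lt(anim$log10_evalue, bact$log10_evalue)
  # removing the animal copy flips the decoy to retained
  no_anim <- sim$animal_db[!grepl(decoy_gene, names(sim$animal_db))]
  cands <- screen(sim$assembly, sim$bacterial_db, no_anim, NT_SCHEME)
  tab <- candidate_table(cands)
  decoy_row <- tab[tab$scaffold_id == row$scaffold_id &
                     tab$start < row$end & tab$end > row$start, ]
  expect_identical(decoy_row$status, "retained")
})

test_that("codon pair simulation respects its parameters", {
  # t = 0: identical sequences
  p0 <- simulate_codon_pair(0.5, 2, 0, 50, seed = 1)
  expect_identical(p0$codons_a, p0$codons_b)
  # omega = 0: only synonymous moves, so the translations are identical
  # (NG86 pathway averaging may still attribute fractional nonsynonymous
  # steps to multi-hit codons, e.g. across the serine boxes)
  p1 <- simulate_codon_pair(0, 2, 1.0, 500, seed = 2)
  expect_identical(translate_cds(paste(p1$codons_a, collapse = "")),
                   translate_cds(paste(p1$codons_b, collapse = "")))
  expect_gt(ng86_counts(p1)$Sd, 0)
  # transition/transversion difference ratio increases with kappa
  ti_tv <- function(pair) {
    diffs <- mapply(function(a, b) {
      pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (length(pos) != 1L) return(NA_character_)
      paste0(substr(a, pos, pos), substr(b, pos, pos))
    }, pair$codons_a, pair$codons_b)
    diffs <- diffs[!is.na(diffs)]
    ti <- sum(diffs %in% c("AG", "GA", "CT", "TC"))
    ti / max(1, length(diffs) - ti)
  }
  r1 <- ti_tv(simulate_codon_pair(1, 1, 0.5, 5000, seed = 3))
  r10 <- ti_tv(simulate_codon_pair(1, 10, 0.5, 5000, seed = 3))
  expect_gt(r10, r1)
})

test_that("zero-divergence ortholog panels are fully recovered by RBH and
           shuffling breaks order", {
  panel <- simulate_ortholog_panel(2, tree_depth = 1e-9, seed = 31,
                                   n_genes = 6, gene_codons = 60)
  pairs <- reciprocal_best_hits(panel$proteomes$sp1, panel$proteomes$sp2,
                                AA_SCHEME)
  truth <- panel$truth$pairs[["sp1~sp2"]]
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  shuffled <- simulate_ortholog_panel(2, tree_depth = 0.05, seed = 31,
                                      n_genes = 8, gene_codons = 60,
                                      shuffle_species = "sp2")
  expect_false(identical(shuffled$truth$order$sp1,
                         shuffled$truth$order$sp2))
  focal_fam <- shuffled$truth$order$sp1[[4]]
  rep <- microsynteny(
    data.frame(gene_a = paste0("sp1_", focal_fam),
               gene_b = paste0("sp2_", focal_fam)),
    shuffled$assemblies$sp1, shuffled$assemblies$sp2,
    shuffled$truth$pairs[["sp1~sp2"]], window = 3)
  expect_false(rep$order_conserved)
})

test_that("ground truth stays consistent with the emitted fixtures", {
  sim <- simulate_screen_inputs(simulation_recipe(seed = 7L))
  tr <- sim$truth
  expect_true(tr$implant$scaffold_id %in% names(sim$assembly$scaffolds))
  expect_true(tr$contaminant_scaffold_id %in% names(sim$assembly$scaffolds))
  expect_true(tr$decoy$decoy_gene_id %in% sim$assembly$genes$gene_id)
  expect_true(tr$implant$donor_id %in% names(sim$bacterial_db))
  expect_lte(tr$implant$end,
             nchar(sim$assembly$scaffolds[[tr$implant$scaffold_id]]))
  expect_lt(nchar(sim$assembly$scaffolds[[tr$contaminant_scaffold_id]]),
            5000L)
  # the implant region is recoverable and near the recipe divergence
  region <- scaffold_region(sim$assembly, tr$implant$scaffold_id,
                            tr$implant$start, tr$implant$end)
  donor <- sim$bacterial_db[[tr$implant$donor_id]]
  mismatch <- mean(strsplit(region, "")[[1]] != strsplit(donor, "")[[1]])
  expect_lt(abs(mismatch - 0.10), 0.05)
})

test_that("NJ recovers the species tree from simulated panels at moderate
           depth", {
  ok <- 0L
  for (seed in 1:8) {
    panel <- simulate_ortholog_panel(6, tree_depth = 0.3, seed = seed,
                                     n_genes = 4, gene_codons = 120)
    concat <- vapply(names(panel$proteomes), function(sp)
      paste(panel$proteomes[[sp]], collapse = ""), character(1))
    d <- protein_distance(concat)
    rec <- nj_tree(d)
    if (ape::dist.topo(ape::unroot(panel$truth$tree), rec) == 0)
      ok <- ok + 1L
  }
  expect_gte(ok, 7L)
})
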