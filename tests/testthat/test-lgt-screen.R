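# small deterministic screen fixture: one scaffold carrying a verbatim
# bacterial gene, built in code
.fixture_exact_implant <- function(scaffold_len = 8000L, gene_len = 2000L,
                                   at = 3000L, seed = 101L) {
  withr::with_seed(seed, {
    scaffold <- random_seq(scaffold_len)
    gene <- random_seq(gene_len)
    substr(scaffold, at + 1L, at + gene_len) <- gene
    list(asm = assembly(c(scf = scaffold)),
         bact = c(donor = gene), at = at, gene_len = gene_len)
  })
}

test_that("a verbatim bacterial gene yields one region spanning the
           implant", {
  fx <- .fixture_exact_implant()
  cands <- find_bacterial_regions(fx$asm, fx$bact, NT_SCHEME)
  expect_length(cands, 1L)
  expect_lte(cands[[1L]]$start, fx$at)
  expect_gte(cands[[1L]]$end, fx$at + fx$gene_len)
  expect_identical(cands[[1L]]$bacterial_best$subject_id, "donor")
})

test_that("sub-cutoff HSPs within the merge gap collapse into one region", {
  withr::with_seed(5, {
    scaffold <- random_seq(6000)
    g1 <- random_seq(600); g2 <- random_seq(600)
    substr(scaffold, 1001, 1600) <- g1
    substr(scaffold, 1701, 2300) <- g2   # 100 bp apart
    asm <- assembly(c(scf = scaffold))
    cands <- find_bacterial_regions(asm, c(b1 = g1, b2 = g2), NT_SCHEME,
                                    screen_params(hsp_merge_gap = 1000L))
    expect_length(cands, 1L)
    expect_lte(cands[[1L]]$start, 1000L)
    expect_gte(cands[[1L]]$end, 2300L)
    # with a tiny merge gap the two regions stay separate
    cands2 <- find_bacterial_regions(asm, c(b1 = g1, b2 = g2), NT_SCHEME,
                                     screen_params(hsp_merge_gap = 10L))
    expect_length(cands2, 2L)
  })
})

test_that("random scaffolds produce no bacterial regions", {
  withr::with_seed(6, {
    asm <- assembly(c(scf = random_seq(5000)))
    bact <- c(b1 = random_seq(2000))
    expect_length(find_bacterial_regions(asm, bact, NT_SCHEME), 0L)
  })
})

test_that("animal filter excludes iff the animal E-value is strictly
           smaller", {
  # scaffold that is exactly the bacterial gene, so the extracted region
  # equals the bacterial query and E-values can be exactly equal
  withr::with_seed(102, gene <- random_seq(2000))
  asm_eq <- assembly(c(scf = gene))
  cand_eq <- find_bacterial_regions(asm_eq, c(donor = gene), NT_SCHEME)[[1L]]
  # animal db of the same size holding the identical gene: equal E ->
  # retained (the exclusion inequality is strict)
  same <- animal_filter(cand_eq, asm_eq, c(an = gene), NT_SCHEME)
  expect_equal(same$animal_best_log10_evalue,
               same$bacterial_best$log10_evalue)
  expect_identical(same$status, "retained")
  fx <- .fixture_exact_implant()
  cand <- find_bacterial_regions(fx$asm, fx$bact, NT_SCHEME)[[1L]]
  # no animal hit -> retained
  none <- animal_filter(cand, fx$asm, c(an = random_seq(500)), NT_SCHEME)
  expect_identical(none$status, "retained")
  # longer exact animal match -> smaller E -> excluded
  withr::with_seed(8, {
    region <- scaffold_region(fx$asm, "scf", cand$start, cand$end)
    longer <- paste0(region,
                     substr(fx$asm$scaffolds[["scf"]], cand$end + 1L,
                            cand$end + 500L))
    better <- animal_filter(cand, fx$asm, c(an = longer), NT_SCHEME)
    expect_lt(better$animal_best_log10_evalue,
              better$bacterial_best$log10_evalue)
    expect_identical(better$status, "excluded_animal")
    expect_match(better$audit[[1L]], "animal_filter:excluded")
  })
})

test_that("scaffold length filter is strict at the 5 kb boundary", {
  withr::with_seed(9, {
    gene <- random_seq(1500)
    for (cfg in list(list(len = 4999L, status = "excluded_scaffold_length"),
                     list(len = 5000L, status = "retained"),
                     list(len = 100000L, status = "retained"))) {
      scaffold <- random_seq(cfg$len)
      substr(scaffold, 1001, 2500) <- gene
      asm <- assembly(c(scf = scaffold))
      cand <- find_bacterial_regions(asm, c(b = gene), NT_SCHEME)[[1L]]
      out <- scaffold_length_filter(cand, asm)
      expect_identical(out$status, cfg$status)
    }
  })
})

test_that("the seed-7 synthetic assembly resolves all three candidate
           fates", {
  sim <- simulate_screen_inputs(simulation_recipe(seed = 7L))
  cands <- screen(sim$assembly, sim$bacterial_db, sim$animal_db, NT_SCHEME)
  tab <- candidate_table(cands)
  retained <- tab[tab$status == "retained", ]
  expect_identical(nrow(retained), 1L)
  expect_identical(retained$scaffold_id, sim$truth$implant$scaffold_id)
  expect_lte(sim$truth$implant$start + 50L, retained$end)
  expect_gte(sim$truth$implant$end, retained$start)
  expect_true(any(tab$status == "excluded_animal"))
  expect_true(any(tab$status == "excluded_scaffold_length"))
  expect_identical(
    tab$scaffold_id[tab$status == "excluded_scaffold_length"],
    sim$truth$contaminant_scaffold_id)
  # audit completeness: every candidate lists each filter exactly once
  for (aud in strsplit(tab$audit, ";")) {
    expect_length(aud, 2L)
    expect_match(aud[[1L]], "^animal_filter:")
    expect_match(aud[[2L]], "^scaffold_length_filter:")
  }
  # empty animal db: every bacterial region survives the animal filter
  cands2 <- screen(sim$assembly, sim$bacterial_db, character(0), NT_SCHEME)
  expect_false(any(candidate_table(cands2)$status == "excluded_animal"))
  # a much stricter cutoff keeps only candidates whose E-value beats it
  tab3 <- candidate_table(screen(sim$assembly, sim$bacterial_db,
                                 sim$animal_db, NT_SCHEME,
                                 screen_params(1e-300)))
  expect_lt(nrow(tab3), nrow(tab))
  expect_true(all(tab3$bacterial_log10_evalue < -300))
})

test_that("relaxing the bacterial cutoff never drops a retained candidate", {
  sim <- simulate_screen_inputs(simulation_recipe(seed = 12L))
  strict <- screen(sim$assembly, sim$bacterial_db, sim$animal_db, NT_SCHEME,
                   screen_params(1e-20))
  lax <- screen(sim$assembly, sim$bacterial_db, sim$animal_db, NT_SCHEME,
                screen_params(1e-5))
  key <- function(cands) {
    tab <- candidate_table(cands)
    tab[tab$status == "retained",
        c("scaffold_id", "bacterial_subject")]
  }
  ks <- key(strict); kl <- key(lax)
  expect_true(all(paste(ks$scaffold_id, ks$bacterial_subject) %in%
                    paste(kl$scaffold_id, kl$bacterial_subject)))
})

test_that("candidate tables write with audit columns and 1-based reports", {
  sim <- simulate_screen_inputs(simulation_recipe(seed = 7L))
  cands <- screen(sim$assembly, sim$bacterial_db, sim$animal_db, NT_SCHEME)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidate_table(cands, f, meta = "screen run")
  lines <- readLines(f)
  expect_match(lines[[1L]], "^# ")
  hdr <- strsplit(lines[[2L]], "\t")[[1L]]
  expect_true(all(c("status", "audit", "start1", "end1") %in% hdr))
  tab <- candidate_table(cands)
  expect_identical(tab$start1, tab$start + 1L)
})
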