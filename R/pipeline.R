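#' @title End-to-end candidate characterization pipeline
#' @description Orchestrates screen -> orthology/microsynteny -> dN/dS ->
#'   placement -> primer design and emits one structured report per
#'   candidate.  Optional stages whose inputs are absent are marked skipped
#'   with a reason; the screen itself is required.  Reports embed the full
#'   configuration so every threshold used is auditable.
#' @name pipeline_cli
NULL

.cfg_defaults <- list(evalue = 1e-5, min_scaffold = 5000, merge_gap = 1000,
                      window = 4, boot_reps = 100, seed = 1,
                      max_degeneracy = 512, primer_min_len = 18,
                      primer_max_len = 27, support_threshold = 0.8)

#' Read a plain-text key=value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment.  Unset keys take
#' package defaults (embedded in the report provenance).
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("bad config line: ", ln)
    key <- trimws(kv[[1L]])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

.validate_config <- function(cfg) {
  for (k in names(.cfg_defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- .cfg_defaults[[k]]
  req <- c("genome", "genes", "bacteria", "animal")
  for (k in req) {
    if (is.null(cfg[[k]])) stop("config is missing required key: ", k)
    if (!file.exists(cfg[[k]]))
      stop("config path does not exist (", k, "): ", cfg[[k]])
  }
  for (k in c("partner_genome", "partner_genes", "panel_alignment",
              "panel_labels"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config path does not exist (", k, "): ", cfg[[k]])
  if (cfg$evalue <= 0 || cfg$min_scaffold < 0)
    stop("thresholds must be positive")
  cfg
}

.skip <- function(reason) list(skipped = TRUE, reason = reason)

# host gene overlapping (or nearest to) a candidate region on its scaffold
.candidate_gene <- function(asm, cand) {
  g <- asm$genes[asm$genes$scaffold_id == cand$scaffold_id, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  ov <- g$start < cand$end & g$end > cand$start
  if (any(ov)) return(g[which(ov)[1L], , drop = FALSE])
  NULL
}

#' Run the characterization pipeline
#'
#' @param config Named list or path to a key=value config file.  Required
#'   keys: `genome`, `genes`, `bacteria`, `animal` (paths).  Optional:
#'   `partner_genome`, `partner_genes` (enables orthology, microsynteny,
#'   dN/dS and primer design), `panel_alignment`, `panel_labels`,
#'   `panel_focal` (enables placement), plus thresholds `evalue`,
#'   `min_scaffold`, `merge_gap`, `window`, `boot_reps`, `seed`,
#'   `max_degeneracy`, `support_threshold`.
#' @param quiet Suppress progress messages on standard error.
#' @return List of candidate reports (class `candidate_report`): screen
#'   candidate plus `orthology`, `selection`, `placement`, `primers`
#'   sections (each either results or `skipped` + reason) and `provenance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- .validate_config(config)
  say <- function(...) if (!quiet) message("[lgt-hunter] ", ...)
  say("loading inputs")
  asm <- assembly(read_fasta(cfg$genome, "dna"))
  asm <- read_gene_table(cfg$genes, asm)
  bacterial_db <- read_fasta(cfg$bacteria, "dna")
  animal_db <- read_fasta(cfg$animal, "dna")
  nt <- calibrate_scoring(scoring_scheme("nucleotide"))
  aa <- calibrate_scoring(scoring_scheme("protein"))
  params <- screen_params(cfg$evalue, cfg$min_scaffold, cfg$merge_gap)
  say("screening ", length(asm$scaffolds), " scaffolds")
  cands <- screen(asm, bacterial_db, animal_db, nt, params)
  has_partner <- !is.null(cfg$partner_genome) && !is.null(cfg$partner_genes)
  partner <- NULL
  rbh <- NULL
  if (has_partner) {
    say("loading partner species")
    partner <- assembly(read_fasta(cfg$partner_genome, "dna"))
    partner <- read_gene_table(cfg$partner_genes, partner)
    prot_a <- setNames(vapply(asm$genes$cds_seq, translate_cds, character(1)),
                       asm$genes$gene_id)
    prot_b <- setNames(vapply(partner$genes$cds_seq, translate_cds,
                              character(1)), partner$genes$gene_id)
    say("reciprocal best hits (", length(prot_a), " x ", length(prot_b),
        " proteins)")
    rbh <- reciprocal_best_hits(prot_a, prot_b, aa)
  }
  has_panel <- !is.null(cfg$panel_alignment) && !is.null(cfg$panel_labels) &&
    !is.null(cfg$panel_focal)
  panel <- NULL
  if (has_panel) {
    panel_aln <- read_fasta_aligned(cfg$panel_alignment)
    lab_tab <- read.delim(cfg$panel_labels, stringsAsFactors = FALSE)
    panel <- list(alignment = panel_aln,
                  labels = setNames(lab_tab$kingdom, lab_tab$label),
                  focal = cfg$panel_focal)
  }
  reports <- lapply(cands, function(cand) {
    rep <- list(candidate = cand,
                orthology = .skip("no partner species supplied"),
                selection = .skip("no partner species supplied"),
                placement = .skip("no placement panel supplied"),
                primers = .skip("no partner species supplied"),
                provenance = list(config = cfg,
                                  version = as.character(
                                    utils::packageVersion("lgthunter"))))
    class(rep) <- "candidate_report"
    if (cand$status != "retained") return(rep)
    gene <- .candidate_gene(asm, cand)
    if (has_partner) {
      if (is.null(gene)) {
        reason <- "no annotated gene overlaps the candidate region"
        rep$orthology <- .skip(reason)
        rep$selection <- .skip(reason)
        rep$primers <- .skip(reason)
      } else {
        hit <- rbh[rbh$gene_a == gene$gene_id, , drop = FALSE]
        if (nrow(hit) == 0L) {
          reason <- paste0("gene ", gene$gene_id, " has no 1:1 ortholog")
          rep$orthology <- .skip(reason)
          rep$selection <- .skip(reason)
          rep$primers <- .skip(reason)
        } else {
          say("orthology/selection/primers for ", gene$gene_id)
          background <- rbh[rbh$gene_a != gene$gene_id, , drop = FALSE]
          zres <- if (nrow(background) >= 2L)
            identity_zscore(hit, background) else .skip("background < 2 pairs")
          syn <- microsynteny(hit, asm, partner, rbh, window = cfg$window)
          rep$orthology <- list(skipped = FALSE, pair = hit, zscore = zres,
                                synteny = syn,
                                neighbor = neighbor_distance(gene$gene_id, asm))
          cds_b <- partner$genes$cds_seq[[
            which(partner$genes$gene_id == hit$gene_b)]]
          pair <- build_codon_alignment(gene$cds_seq, cds_b,
                                        gene$gene_id, hit$gene_b, aa)
          rep$selection <- list(skipped = FALSE, ng86 = ng86(pair),
                                ml = ml_pairwise_dnds(pair))
          rep$primers <- .design_primers(pair, asm, partner, cfg)
        }
      }
    }
    if (has_panel) {
      say("placement (", cfg$boot_reps, " bootstrap replicates)")
      bs <- bootstrap_supports(panel$alignment, n_reps = cfg$boot_reps,
                               seed = cfg$seed)
      cls <- classify_origin(bs, panel$focal, panel$labels,
                             threshold = cfg$support_threshold)
      rep$placement <- list(skipped = FALSE, call = cls$call,
                            support = cls$support, side = cls$side,
                            tree = bs$tree)
    }
    rep
  })
  reports
}

# degenerate primer pair from the codon alignment of the candidate and its
# ortholog, plus in-silico PCR on both genomes
.design_primers <- function(pair, asm, partner, cfg) {
  to_dna <- function(codons) paste(codons, collapse = "")
  aln <- c(a = to_dna(pair$codons_a), b = to_dna(pair$codons_b))
  blocks <- find_conserved_blocks(aln, min_len = cfg$primer_min_len,
                                  max_degeneracy = cfg$max_degeneracy)
  if (nrow(blocks) < 2L)
    return(.skip("fewer than two conserved blocks for primer design"))
  clip <- function(block) {
    len <- min(block$end - block$start, cfg$primer_max_len)
    data.frame(start = block$start, end = block$start + len)
  }
  # forward from the leftmost admissible block, reverse from the rightmost
  ord <- blocks[order(blocks$start), , drop = FALSE]
  fb <- clip(ord[1L, ])
  rb0 <- ord[nrow(ord), ]
  rb <- data.frame(start = max(rb0$start, rb0$end - cfg$primer_max_len),
                   end = rb0$end)
  if (rb$start <= fb$end)
    return(.skip("conserved blocks too close for a primer pair"))
  fwd <- make_primer(fb, aln, "forward", name = "F1")
  rev <- make_primer(rb, aln, "reverse", name = "R1")
  amps <- list()
  for (nm in names(asm$scaffolds))
    amps[[nm]] <- insilico_pcr(fwd, rev, asm$scaffolds[nm])
  for (nm in names(partner$scaffolds))
    amps[[nm]] <- insilico_pcr(fwd, rev, partner$scaffolds[nm])
  amps <- do.call(rbind, amps[vapply(amps, nrow, integer(1)) > 0])
  list(skipped = FALSE, fwd = fwd, rev = rev,
       amplicons = if (is.null(amps)) data.frame() else amps)
}

# read an aligned protein FASTA (gaps allowed)
read_fasta_aligned <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @export
print.candidate_report <- function(x, ...) {
  print(x$candidate)
  sec <- function(name, s) {
    if (isTRUE(s$skipped)) cat(sprintf("  %s: skipped (%s)\n", name, s$reason))
    else cat(sprintf("  %s: present\n", name))
  }
  sec("orthology", x$orthology); sec("selection", x$selection)
  sec("placement", x$placement); sec("primers", x$primers)
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits `candidates.tsv` (all candidates with audit trails) and one
#' human-readable `report_<n>.txt` per candidate, each embedding the
#' configuration snapshot.  Output is deterministic for identical inputs.
#'
#' @param reports List from [run_pipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cands <- lapply(reports, `[[`, "candidate")
  write_candidate_table(cands, file.path(dir, "candidates.tsv"),
                        meta = "coordinates: start1/end1 are 1-based inclusive")
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    con <- file(file.path(dir, sprintf("report_%02d.txt", i)), "w")
    c0 <- r$candidate
    lines <- c(
      sprintf("candidate %d: %s:%d-%d [%s]", i, c0$scaffold_id,
              c0$start + 1L, c0$end, c0$status),
      sprintf("  bacterial best: %s (E = %.3g)", c0$bacterial_best$subject_id,
              c0$bacterial_best$evalue),
      sprintf("  animal best E: %s",
              ifelse(is.na(c0$animal_best_evalue), "none",
                     format(c0$animal_best_evalue, digits = 3))),
      sprintf("  audit: %s", paste(c0$audit, collapse = " -> ")))
    sec <- function(name, s, fmt) {
      if (isTRUE(s$skipped))
        sprintf("%s: skipped (%s)", name, s$reason)
      else fmt(s)
    }
    lines <- c(lines,
      sec("orthology", r$orthology, function(s) c(
        sprintf("orthology: %s ~ %s, identity %.1f%%", s$pair$gene_a,
                s$pair$gene_b, s$pair$pct_identity),
        if (!isTRUE(s$zscore$skipped))
          sprintf("  identity z-score: %.2f (background mean %.1f, sd %.1f, n = %d)",
                  s$zscore$z, s$zscore$mean, s$zscore$sd, s$zscore$n),
        sprintf("  microsynteny: %d/%d flanking orthologs shared, order %s",
                s$synteny$n_shared, s$synteny$n_flank,
                ifelse(s$synteny$order_conserved, "conserved", "broken")),
        if (!is.null(s$neighbor))
          sprintf("  nearest neighbor: %s at %d bp", s$neighbor$neighbor_id,
                  s$neighbor$gap_bp))),
      sec("selection", r$selection, function(s) c(
        sprintf("selection: NG86 dN/dS = %.4f; ML omega = %.4f (dN = %.4f, dS = %.4f, kappa = %.2f)",
                s$ng86$omega, s$ml$omega, s$ml$dN, s$ml$dS, s$ml$kappa))),
      sec("placement", r$placement, function(s)
        sprintf("placement: %s (support %.2f)", s$call, s$support)),
      sec("primers", r$primers, function(s) c(
        sprintf("primers: F1 5'-%s-3' (deg %d), R1 5'-%s-3' (deg %d)",
                s$fwd$iupac_seq, s$fwd$degeneracy, s$rev$iupac_seq,
                s$rev$degeneracy),
        sprintf("  amplicons: %d", nrow(s$amplicons)))),
      "config:",
      vapply(names(r$provenance$config), function(k)
        sprintf("  %s = %s", k, as.character(r$provenance$config[[k]])),
        character(1)),
      sprintf("version: %s", r$provenance$version))
    writeLines(unlist(lines), con)
    close(con)
  }
  invisible(dir)
}

#' Simulate a complete two-species pipeline input set
#'
#' Builds, from one seed: a two-species ortholog panel with shared gene
#' order; an orthologous LGT gene pair evolved under the GY94 model at the
#' recipe's omega, inserted as an annotated gene in both species; a
#' bacterial database containing the donor; an animal database with no
#' homology to the LGT; and an aligned two-kingdom protein panel in which
#' the focal sequence is the species-A LGT protein nested among bacterial
#' homologs.  Files are written under `dir` together with a ready-to-run
#' config.
#'
#' @param recipe A [simulation_recipe()].
#' @param dir Output directory.
#' @param n_genes Conserved gene families per species.
#' @return List with `config` (named list also written to
#'   `file.path(dir, "run.cfg")`) and `truth`.
#' @export
simulate_pipeline_inputs <- function(recipe, dir, n_genes = 8L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_ortholog_panel(2L, tree_depth = 0.15,
                                   seed = recipe$seed, n_genes = n_genes,
                                   gene_codons = 150L)
  lgt <- simulate_codon_pair(recipe$omega, recipe$kappa, recipe$t, 300L,
                             seed = recipe$seed + 31L)
  lgt_a <- paste(lgt$codons_a, collapse = "")
  lgt_b <- paste(lgt$codons_b, collapse = "")
  with_seed(recipe$seed + 41L, {
    donor <- mutate_codons(lgt_a, 0.15)
    animal_bg <- random_dna(2000L, 0.42)
    bact_bg <- random_dna(2000L, recipe$donor_gc)
    # two-kingdom protein panel around the focal LGT protein: the focal is
    # grafted as sister of bact1, inside the bacterial clade
    focal_prot <- translate_cds(lgt_a)
    banc <- mutate_protein(focal_prot, 0.12)
    eanc <- mutate_protein(focal_prot, 0.45)
    bact_leaves <- c(
      setNames(mutate_protein(focal_prot, 0.05), "bact1"),
      setNames(vapply(2:5, function(i) mutate_protein(banc, 0.08),
                      character(1)), paste0("bact", 2:5)))
    euk_leaves <- setNames(vapply(1:5, function(i)
      mutate_protein(eanc, 0.08), character(1)), paste0("euk", 1:5))
  })
  # rebuild each species' scaffold with the LGT inserted mid-order
  spacer <- 200L
  rebuild <- function(asm, sp, lgt_cds) {
    g <- asm$genes[order(asm$genes$start), , drop = FALSE]
    mid <- nrow(g) %/% 2L
    ids <- append(g$gene_id, paste0(sp, "_lgt"), after = mid)
    cds <- append(g$cds_seq, lgt_cds, after = mid)
    total <- sum(nchar(cds)) + spacer * (length(cds) + 1L)
    seq <- with_seed(recipe$seed + 43L, random_dna(total, recipe$host_gc))
    rows <- list(); pos <- spacer
    for (k in seq_along(ids)) {
      substr(seq, pos + 1L, pos + nchar(cds[[k]])) <- cds[[k]]
      rows[[k]] <- data.frame(gene_id = ids[[k]],
                              scaffold_id = paste0(sp, "_scf"), start = pos,
                              end = pos + nchar(cds[[k]]), strand = "+",
                              stringsAsFactors = FALSE)
      pos <- pos + nchar(cds[[k]]) + spacer
    }
    assembly(setNames(seq, paste0(sp, "_scf")), do.call(rbind, rows))
  }
  asm_a <- rebuild(panel$assemblies$sp1, "sp1", lgt_a)
  asm_b <- rebuild(panel$assemblies$sp2, "sp2", lgt_b)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    genes = file.path(dir, "genes.tsv"),
    bacteria = file.path(dir, "bacteria.fasta"),
    animal = file.path(dir, "animal.fasta"),
    partner_genome = file.path(dir, "partner_genome.fasta"),
    partner_genes = file.path(dir, "partner_genes.tsv"),
    panel_alignment = file.path(dir, "panel.faa"),
    panel_labels = file.path(dir, "panel_labels.tsv"))
  write_fasta(asm_a$scaffolds, paths$genome)
  write_gene_table(asm_a, paths$genes)
  write_fasta(asm_b$scaffolds, paths$partner_genome)
  write_gene_table(asm_b, paths$partner_genes)
  write_fasta(c(bact_donor_GH = donor, bact_bg1 = bact_bg), paths$bacteria)
  write_fasta(c(animal_bg1 = animal_bg), paths$animal)
  aln <- c(bact_leaves, euk_leaves, focal = translate_cds(lgt_a))
  write_fasta(aln, paths$panel_alignment)
  lab <- data.frame(label = c(names(bact_leaves), names(euk_leaves)),
                    kingdom = c(rep("bacterial", 5), rep("eukaryotic", 5)),
                    stringsAsFactors = FALSE)
  con <- file(paths$panel_labels, "w")
  writeLines(paste(names(lab), collapse = "\t"), con)
  writeLines(do.call(paste, c(lab, sep = "\t")), con)
  close(con)
  cfg <- c(paths, list(panel_focal = "focal", seed = recipe$seed,
                       boot_reps = 100))
  cfg_lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", cfg[[k]]), character(1))
  writeLines(cfg_lines, file.path(dir, "run.cfg"))
  list(config = cfg,
       truth = list(lgt_gene_a = "sp1_lgt", lgt_gene_b = "sp2_lgt",
                    omega = recipe$omega, recipe = recipe))
}
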