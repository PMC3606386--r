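#' @title Synthetic genomes and evolved sequence fixtures
#' @description Deterministic generators that give every pipeline stage
#'   ground-truthed input: host assemblies with intronless genes, implanted
#'   bacterial-origin genes at controlled divergence, conserved-gene decoys
#'   that the animal filter must remove, short pure-bacterial contaminant
#'   scaffolds, codon alignment pairs evolved under the package's own GY94
#'   model, multi-species ortholog panels with shared gene order, and
#'   two-kingdom protein panels with a grafted focal sequence.  Every
#'   generator is a pure function of its recipe: the caller's RNG state is
#'   saved and restored, and identical seeds give identical output.
#' @name synthetic_data
NULL

#' Evaluate an expression under a fixed RNG seed, restoring the caller's
#' RNG state afterwards
#' @param seed Integer seed.
#' @param expr Expression.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation recipe
#'
#' Bundles every tunable of the synthetic-genome generators.  Probabilities
#' are per-site substitution probabilities and must lie in `[0, 0.75]`.
#'
#' @param seed Integer seed; recorded in the metadata of every output.
#' @param host_gc,donor_gc GC content of host scaffolds and of the
#'   bacterial donor pool.
#' @param n_scaffolds,scaffold_length_bp,genes_per_scaffold Host assembly
#'   shape.
#' @param gene_length_bp Host gene length (multiple of 3).
#' @param implant_divergence Substitution probability applied to the donor
#'   CDS before implantation.
#' @param decoy_animal_divergence,decoy_bacterial_divergence Divergence of
#'   the decoy gene's animal and bacterial database copies (animal lower,
#'   so its animal E-value wins).
#' @param contaminant_length_bp Length of the pure-bacterial contaminant
#'   scaffold (below the 5 kb screen floor by default).
#' @param omega,kappa,t Codon-simulation parameters.
#' @return List of class `simulation_recipe`.
#' @export
simulation_recipe <- function(seed = 1L, host_gc = 0.35, donor_gc = 0.40,
                              n_scaffolds = 3L, scaffold_length_bp = 50000L,
                              genes_per_scaffold = 10L, gene_length_bp = 900L,
                              implant_divergence = 0.10,
                              decoy_animal_divergence = 0.05,
                              decoy_bacterial_divergence = 0.25,
                              contaminant_length_bp = 3000L,
                              omega = 0.062, kappa = 2, t = 0.8) {
  probs <- c(implant_divergence, decoy_animal_divergence,
             decoy_bacterial_divergence)
  stopifnot(all(probs >= 0 & probs <= 0.75), host_gc > 0, host_gc < 1,
            donor_gc > 0, donor_gc < 1, gene_length_bp %% 3L == 0L)
  structure(list(seed = as.integer(seed), host_gc = host_gc,
                 donor_gc = donor_gc, n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length_bp = as.integer(scaffold_length_bp),
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 gene_length_bp = as.integer(gene_length_bp),
                 implant_divergence = implant_divergence,
                 decoy_animal_divergence = decoy_animal_divergence,
                 decoy_bacterial_divergence = decoy_bacterial_divergence,
                 contaminant_length_bp = as.integer(contaminant_length_bp),
                 omega = omega, kappa = kappa, t = t),
            class = "simulation_recipe")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random intronless CDS: ATG + random sense codons (uniform over the 60
# non-ATG-requiring sense codons) -- always translatable with no internal
# stop
random_cds <- function(n_codons) {
  cm <- codon_machinery()
  body <- sample(cm$codons, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

#' Mutate a DNA string by uniform substitution
#'
#' Each site is substituted with probability `p`, uniformly over the three
#' alternative bases.  No indels.
#'
#' @param seq DNA string.
#' @param p Per-site substitution probability.
#' @return Mutated string.
#' @export
mutate_dna <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < p & chars %in% c("A", "C", "G", "T"))
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# codon-level mutation that preserves the open reading frame: each codon is
# replaced with probability p by a uniformly drawn different sense codon
mutate_codons <- function(cds, p) {
  cm <- codon_machinery()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  hit <- which(runif(length(codons)) < p)
  for (i in hit) codons[i] <- sample(setdiff(cm$codons, codons[i]), 1L)
  paste(codons, collapse = "")
}

#' Simulate a host assembly with intronless genes
#'
#' Scaffolds are i.i.d. at the recipe's host GC; each carries
#' `genes_per_scaffold` non-overlapping intronless genes (random sense-codon
#' ORFs written into the scaffold, on random strands) at evenly spaced slots
#' with random offsets.
#'
#' @param recipe A [simulation_recipe()].
#' @return List with `assembly` (an [assembly()]) and `truth` (list; gene
#'   ids and the recipe).
#' @export
simulate_host_assembly <- function(recipe) {
  with_seed(recipe$seed, {
    glen <- recipe$gene_length_bp
    slot <- recipe$scaffold_length_bp %/% recipe$genes_per_scaffold
    if (slot < glen + 200L)
      stop("genes do not fit: need at least ",
           recipe$genes_per_scaffold * (glen + 200L), " bp per scaffold")
    scaffolds <- character(0)
    rows <- list()
    for (s in seq_len(recipe$n_scaffolds)) {
      sid <- sprintf("scaffold%02d", s)
      seq <- random_dna(recipe$scaffold_length_bp, recipe$host_gc)
      for (g in seq_len(recipe$genes_per_scaffold)) {
        start <- (g - 1L) * slot +
          sample.int(slot - glen - 100L, 1L) + 50L
        cds <- random_cds(glen %/% 3L)
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "-") revcomp(cds) else cds
        substr(seq, start + 1L, start + glen) <- ins
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("%s_g%02d", sid, g), scaffold_id = sid,
          start = start, end = start + glen, strand = strand,
          stringsAsFactors = FALSE)
      }
      scaffolds[sid] <- seq
    }
    genes <- do.call(rbind, rows)
    asm <- assembly(scaffolds, genes)
    list(assembly = asm,
         truth = list(recipe = recipe, gene_ids = genes$gene_id))
  })
}

# largest intergenic interval (gap between consecutive genes or scaffold
# ends) on a scaffold
.largest_intergenic <- function(asm, sid) {
  g <- asm$genes[asm$genes$scaffold_id == sid, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  bounds <- c(0L, as.vector(rbind(g$start, g$end)),
              nchar(asm$scaffolds[[sid]]))
  starts <- bounds[seq(1L, length(bounds), 2L)]
  ends <- bounds[seq(2L, length(bounds), 2L)]
  i <- which.max(ends - starts)
  c(starts[i], ends[i])
}

#' Implant a diverged bacterial gene into an assembly
#'
#' The donor CDS is mutated at per-site probability `divergence` (uniform
#' over the three alternatives) and written into the middle of the largest
#' intergenic interval of the chosen scaffold.  The implant replaces host
#' background sequence, so all gene coordinates remain valid.
#'
#' @param asm An [assembly()].
#' @param donor_cds Donor CDS string.
#' @param donor_id Donor id (as present in the bacterial database).
#' @param divergence Per-site substitution probability.
#' @param seed Integer seed.
#' @param scaffold_id Target scaffold (default: first scaffold).
#' @return List with `assembly` and `truth` (scaffold, 0-based half-open
#'   interval, donor id, realized mismatch fraction).
#' @export
implant_lgt <- function(asm, donor_cds, donor_id, divergence, seed,
                        scaffold_id = names(asm$scaffolds)[[1L]]) {
  with_seed(seed, {
    gap <- .largest_intergenic(asm, scaffold_id)
    glen <- nchar(donor_cds)
    if (gap[2L] - gap[1L] < glen + 20L)
      stop("no intergenic room for a ", glen, " bp implant on ", scaffold_id)
    start <- gap[1L] + (gap[2L] - gap[1L] - glen) %/% 2L
    mutated <- mutate_dna(donor_cds, divergence)
    seq <- asm$scaffolds[[scaffold_id]]
    substr(seq, start + 1L, start + glen) <- mutated
    asm$scaffolds[[scaffold_id]] <- seq
    mismatch <- mean(strsplit(mutated, "")[[1L]] !=
                       strsplit(donor_cds, "")[[1L]])
    list(assembly = asm,
         truth = list(scaffold_id = scaffold_id, start = start,
                      end = start + glen, donor_id = donor_id,
                      realized_divergence = mismatch))
  })
}

#' Add a conserved-gene decoy to the databases
#'
#' A host gene is copied into the bacterial database at high divergence and
#' into the animal database at low divergence, emulating a slowly evolving
#' conserved gene that hits bacteria but hits animals better -- the class
#' the animal filter exists to remove.
#'
#' @param asm Host [assembly()] (with genes).
#' @param recipe A [simulation_recipe()] (divergence settings and seed).
#' @param gene_id Host gene to use (default: last gene of the last
#'   scaffold).
#' @return List with `bacterial_seq`, `animal_seq` (named single-element
#'   character vectors to append to the databases) and `truth`.
#' @export
make_decoy_conserved_gene <- function(asm, recipe, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- asm$genes$gene_id[[nrow(asm$genes)]]
  row <- asm$genes[asm$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("gene not found: ", gene_id)
  with_seed(recipe$seed + 101L, {
    bact <- mutate_dna(row$cds_seq, recipe$decoy_bacterial_divergence)
    anim <- mutate_dna(row$cds_seq, recipe$decoy_animal_divergence)
    list(bacterial_seq = setNames(bact, paste0("bact_decoy_", gene_id)),
         animal_seq = setNames(anim, paste0("animal_", gene_id)),
         truth = list(decoy_gene_id = gene_id,
                      decoy_region = row[c("scaffold_id", "start", "end")]))
  })
}

#' Simulate the full screen input set
#'
#' One call builds everything [screen()] needs, with known ground truth:
#' a host assembly; an implanted bacterial-origin gene at the recipe's
#' divergence; a conserved-gene decoy whose animal E-value beats its
#' bacterial E-value; a short pure-bacterial contaminant scaffold (below
#' the length floor); and bacterial/animal databases containing the donor,
#' the decoy copies, the contaminant source and unrelated background
#' sequences.
#'
#' @param recipe A [simulation_recipe()].
#' @return List with `assembly`, `bacterial_db`, `animal_db`, `truth`
#'   (implanted region, decoy gene/scaffold ids, contaminant scaffold id).
#' @export
simulate_screen_inputs <- function(recipe) {
  host <- simulate_host_assembly(recipe)
  asm <- host$assembly
  with_seed(recipe$seed + 7L, {
    donor_cds <- random_cds(667L)  # ~2 kb donor gene
    bact_bg1 <- setNames(random_dna(2000L, recipe$donor_gc), "bact_bg1")
    bact_bg2 <- setNames(random_dna(2000L, recipe$donor_gc), "bact_bg2")
    animal_bg <- setNames(random_dna(2000L, 0.42), "animal_bg1")
    contam_src <- random_dna(2500L, recipe$donor_gc)
    contam_flank <- random_dna(recipe$contaminant_length_bp - 2500L,
                               recipe$donor_gc)
  })
  imp <- implant_lgt(asm, donor_cds, "bact_donor_GH", recipe$implant_divergence,
                     recipe$seed + 13L)
  asm <- imp$assembly
  decoy <- make_decoy_conserved_gene(asm, recipe)
  contam_sid <- "scaffold_contam"
  contam_scaffold <- with_seed(recipe$seed + 23L,
                               paste0(mutate_dna(contam_src, 0.02),
                                      contam_flank))
  scaffolds <- c(asm$scaffolds, setNames(contam_scaffold, contam_sid))
  asm2 <- assembly(scaffolds, asm$genes)
  bacterial_db <- c(setNames(donor_cds, "bact_donor_GH"),
                    decoy$bacterial_seq,
                    setNames(contam_src, "bact_contam_src"),
                    bact_bg1, bact_bg2)
  animal_db <- c(decoy$animal_seq, animal_bg)
  list(assembly = asm2, bacterial_db = bacterial_db, animal_db = animal_db,
       truth = list(recipe = recipe, implant = imp$truth,
                    decoy = decoy$truth,
                    contaminant_scaffold_id = contam_sid))
}

#' Simulate a codon alignment pair under the GY94 model
#'
#' An ancestral sequence is drawn from the F3x4 stationary distribution and
#' two lineages are evolved for `t/2` each by exact sampling from the
#' transition probabilities of the selection module's rate matrix.
#'
#' @param omega,kappa,t Model parameters (`t` in expected substitutions per
#'   codon between the two tips).
#' @param n_codons Number of codons.
#' @param seed Integer seed.
#' @param pos_freqs 3 x 4 positional nucleotide frequency matrix for F3x4
#'   (default mildly non-uniform).
#' @return A `codon_alignment` with attribute `truth` (the generating
#'   parameters).
#' @export
simulate_codon_pair <- function(omega, kappa, t, n_codons, seed = 1L,
                                pos_freqs = rbind(c(0.30, 0.20, 0.25, 0.25),
                                                  c(0.25, 0.25, 0.25, 0.25),
                                                  c(0.20, 0.30, 0.25, 0.25))) {
  stopifnot(omega >= 0, kappa > 0, t >= 0, n_codons >= 1L)
  colnames(pos_freqs) <- c("A", "C", "G", "T")
  cm <- codon_machinery()
  pi <- f3x4_frequencies(pos_freqs)
  with_seed(seed, {
    anc <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    if (t == 0) {
      a <- b <- cm$codons[anc]
    } else {
      rm_ <- gy94_rate_matrix(pi, kappa, omega)
      P <- .gy94_pmat(rm_$Q, pi, t / 2)
      draw <- function(anc) vapply(anc, function(i)
        sample.int(61L, 1L, prob = P[i, ]), integer(1))
      a <- cm$codons[draw(anc)]
      b <- cm$codons[draw(anc)]
    }
    out <- codon_alignment(a, b, "sim_a", "sim_b")
    attr(out, "truth") <- list(omega = omega, kappa = kappa, t = t,
                               seed = seed)
    out
  })
}

#' Simulate a multi-species ortholog panel with shared gene order
#'
#' A random species tree (branch lengths rescaled so the maximum
#' root-to-tip path equals `tree_depth`) is generated; each gene family
#' starts from a random ORF at the root and evolves by codon-level
#' substitution along the tree.  Every species carries the same gene order
#' on one scaffold (unless listed in `shuffle_species`, in which case its
#' gene order is randomly permuted).
#'
#' @param n_species Number of species (>= 2).
#' @param tree_depth Root-to-tip divergence (codon substitution
#'   probability; <= 0.7).
#' @param seed Integer seed.
#' @param n_genes Gene families.
#' @param gene_codons Codons per gene.
#' @param shuffle_species Character vector of species ids (`sp1`, ...)
#'   whose gene order is shuffled.
#' @return List with `assemblies` (named list of [assembly()]),
#'   `proteomes` (named list of protein vectors), `truth` (`tree` as ape
#'   phylo, `pairs` of true orthologs for each species pair, `order` the
#'   per-species gene order).
#' @export
simulate_ortholog_panel <- function(n_species, tree_depth = 0.3, seed = 1L,
                                    n_genes = 10L, gene_codons = 150L,
                                    shuffle_species = character()) {
  stopifnot(n_species >= 2L, tree_depth <= 0.7)
  with_seed(seed, {
    tree <- ape::rtree(n_species, tip.label = paste0("sp", seq_len(n_species)))
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_species)])
    tree$edge.length <- tree$edge.length / depth * tree_depth
    root <- n_species + 1L
    # evolve each gene family along the tree at codon level
    evolve <- function(node, cds_by_gene, out) {
      kids <- tree$edge[tree$edge[, 1L] == node, 2L]
      for (k in seq_along(kids)) {
        child <- kids[[k]]
        bl <- tree$edge.length[tree$edge[, 1L] == node][[k]]
        mutated <- lapply(cds_by_gene, mutate_codons, p = min(0.75, bl))
        if (child <= n_species) {
          out[[tree$tip.label[[child]]]] <- mutated
        } else {
          out <- evolve(child, mutated, out)
        }
      }
      out
    }
    root_genes <- lapply(seq_len(n_genes), function(i) random_cds(gene_codons))
    names(root_genes) <- sprintf("fam%02d", seq_len(n_genes))
    tip_genes <- evolve(root, root_genes, list())
    assemblies <- list()
    proteomes <- list()
    orders <- list()
    spacer <- 200L
    for (sp in tree$tip.label) {
      fams <- names(root_genes)
      if (sp %in% shuffle_species) fams <- sample(fams)
      orders[[sp]] <- fams
      glen <- gene_codons * 3L
      total <- n_genes * (glen + spacer) + spacer
      seq <- random_dna(total, 0.4)
      rows <- list()
      pos <- spacer
      for (f in fams) {
        cds <- tip_genes[[sp]][[f]]
        substr(seq, pos + 1L, pos + glen) <- cds
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = paste0(sp, "_", f), scaffold_id = paste0(sp, "_scf"),
          start = pos, end = pos + glen, strand = "+",
          stringsAsFactors = FALSE)
        pos <- pos + glen + spacer
      }
      asm <- assembly(setNames(seq, paste0(sp, "_scf")),
                      do.call(rbind, rows))
      assemblies[[sp]] <- asm
      prot <- vapply(asm$genes$cds_seq, translate_cds, character(1))
      proteomes[[sp]] <- setNames(prot, asm$genes$gene_id)
    }
    pairs <- list()
    combos <- combn(sort(tree$tip.label), 2L)
    for (k in seq_len(ncol(combos))) {
      a <- combos[1L, k]; b <- combos[2L, k]
      pairs[[paste(a, b, sep = "~")]] <- data.frame(
        gene_a = paste0(a, "_", names(root_genes)),
        gene_b = paste0(b, "_", names(root_genes)), stringsAsFactors = FALSE)
    }
    list(assemblies = assemblies, proteomes = proteomes,
         truth = list(tree = tree, pairs = pairs, order = orders,
                      seed = seed))
  })
}

# random protein of length L
random_protein <- function(L) {
  paste(sample(PROT_CHARS[1:20], L, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(PROT_CHARS[1:20], chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Simulate a two-kingdom protein panel with a grafted focal sequence
#'
#' A bacterial clade and a eukaryotic clade diverge across a long internal
#' branch; leaves radiate within each clade.  The focal sequence is grafted
#' as the sister of one bacterial leaf -- the signature of a
#' bacteria-to-eukaryote transfer in an otherwise eukaryotic gene pool.
#'
#' @param n_bact,n_euk Leaves per clade.
#' @param seed Integer seed.
#' @param L Alignment length (aa).
#' @param deep_div Per-site divergence from the root to each clade
#'   ancestor.
#' @param within_div Per-site divergence from the clade ancestor to each
#'   leaf.
#' @param graft_div Per-site divergence of the focal from its bacterial
#'   sister.
#' @return List with `alignment` (named protein vector incl. `focal`),
#'   `kingdom_labels`, `focal`, `sister` (the donor leaf id).
#' @export
simulate_placement_panel <- function(n_bact = 6L, n_euk = 6L, seed = 1L,
                                     L = 200L, deep_div = 0.35,
                                     within_div = 0.08, graft_div = 0.05) {
  with_seed(seed, {
    root <- random_protein(L)
    banc <- mutate_protein(root, deep_div)
    eanc <- mutate_protein(root, deep_div)
    bact <- setNames(lapply(seq_len(n_bact), function(i)
      mutate_protein(banc, within_div)), paste0("bact", seq_len(n_bact)))
    euk <- setNames(lapply(seq_len(n_euk), function(i)
      mutate_protein(eanc, within_div)), paste0("euk", seq_len(n_euk)))
    sister <- sample(names(bact), 1L)
    focal <- mutate_protein(bact[[sister]], graft_div)
    aln <- c(unlist(bact), unlist(euk), focal = focal)
    labels <- setNames(c(rep("bacterial", n_bact), rep("eukaryotic", n_euk)),
                       c(names(bact), names(euk)))
    list(alignment = aln, kingdom_labels = labels, focal = "focal",
         sister = sister)
  })
}

#' Write a simulated screen input set to a directory
#'
#' Emits `genome.fasta`, `genes.tsv`, `bacteria.fasta`, `animal.fasta` and
#' `ground_truth.tsv` (seed and implant/decoy/contaminant ids), all plain
#' text.
#'
#' @param sim Output of [simulate_screen_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$assembly$scaffolds, file.path(dir, "genome.fasta"))
  write_gene_table(sim$assembly, file.path(dir, "genes.tsv"),
                   meta = paste0("seed=", sim$truth$recipe$seed))
  write_fasta(sim$bacterial_db, file.path(dir, "bacteria.fasta"))
  write_fasta(sim$animal_db, file.path(dir, "animal.fasta"))
  gt <- data.frame(
    key = c("seed", "implant_scaffold", "implant_start", "implant_end",
            "implant_donor", "decoy_gene", "contaminant_scaffold"),
    value = c(sim$truth$recipe$seed, sim$truth$implant$scaffold_id,
              sim$truth$implant$start, sim$truth$implant$end,
              sim$truth$implant$donor_id, sim$truth$decoy$decoy_gene_id,
              sim$truth$contaminant_scaffold_id),
    stringsAsFactors = FALSE)
  con <- file(file.path(dir, "ground_truth.tsv"), "w")
  writeLines(paste(names(gt), collapse = "\t"), con)
  writeLines(do.call(paste, c(gt, sep = "\t")), con)
  close(con)
  invisible(dir)
}
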