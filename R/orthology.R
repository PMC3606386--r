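#' @title Reciprocal-best-hit orthology and microsynteny
#' @description 1:1 orthologs by reciprocal best protein hits, an identity
#'   Z-score of a focal pair against the ortholog background, microsynteny
#'   scoring of the gene neighborhood around a focal locus, and the
#'   nearest-neighbor distance used to design bridging PCR across an
#'   LGT/host-gene boundary.
#' @name orthology
NULL

#' Reciprocal best hits between two proteomes
#'
#' A pair `(a, b)` is emitted iff `b` is `a`'s best hit against proteome B
#' and `a` is `b`'s best hit against proteome A, under the [best_hit()] tie
#' rules (minimum E, then higher score, then lexicographic subject id).
#' Each gene appears in at most one pair.
#'
#' @param proteome_a,proteome_b Named protein character vectors.
#' @param scheme Calibrated protein [scoring_scheme()].
#' @param evalue_cutoff Maximum E-value for a hit to count.
#' @return data.frame with columns `gene_a`, `gene_b`, `pct_identity`
#'   (over the aligned columns of the best a-to-b HSP), `evalue_ab`,
#'   `evalue_ba`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, scheme,
                                 evalue_cutoff = 1e-3) {
  stopifnot(length(proteome_a) > 0, length(proteome_b) > 0)
  best_ab <- lapply(names(proteome_a), function(id)
    best_hit(proteome_a[id], proteome_b, scheme, evalue_cutoff = evalue_cutoff))
  names(best_ab) <- names(proteome_a)
  best_ba <- lapply(names(proteome_b), function(id)
    best_hit(proteome_b[id], proteome_a, scheme, evalue_cutoff = evalue_cutoff))
  names(best_ba) <- names(proteome_b)
  rows <- list()
  for (a in names(proteome_a)) {
    hab <- best_ab[[a]]
    if (is.null(hab)) next
    b <- hab$subject_id
    hba <- best_ba[[b]]
    if (is.null(hba) || hba$subject_id != a) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = a, gene_b = b, pct_identity = hab$pct_identity,
      evalue_ab = hab$evalue, evalue_ba = hba$evalue,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_a = character(), gene_b = character(),
                      pct_identity = numeric(), evalue_ab = numeric(),
                      evalue_ba = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identity Z-score of a focal ortholog pair against the genome background
#'
#' `z = (focal - mean(background)) / sd(background)` with the sample
#' standard deviation (denominator `n - 1`).  The focal pair is excluded
#' from the background if present.
#'
#' @param focal_pair One-row data.frame with `gene_a`, `gene_b`,
#'   `pct_identity` (e.g. a row of [reciprocal_best_hits()] output).
#' @param background data.frame of background ortholog pairs with a
#'   `pct_identity` column.
#' @return List with `z`, `mean`, `sd`, `n` (background size used).
#' @export
identity_zscore <- function(focal_pair, background) {
  keep <- !(background$gene_a == focal_pair$gene_a &
              background$gene_b == focal_pair$gene_b)
  ids <- background$pct_identity[keep]
  if (length(ids) < 2L) stop("background must contain at least 2 pairs")
  s <- sd(ids)
  if (s == 0) stop("degenerate background: zero standard deviation")
  m <- mean(ids)
  list(z = (focal_pair$pct_identity - m) / s, mean = m, sd = s,
       n = length(ids))
}

.scaffold_gene_order <- function(assembly, gene_id) {
  g <- assembly$genes
  row <- g[g$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("gene not found in assembly: ", gene_id)
  same <- g[g$scaffold_id == row$scaffold_id, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  list(genes = same, idx = which(same$gene_id == gene_id))
}

#' Microsynteny around a focal ortholog pair
#'
#' Collects the `window` genes on each side of the focal gene in both
#' assemblies and scores how many of the flanking genes in assembly A have
#' their 1:1 ortholog inside the partner window in assembly B.  The
#' denominator is `2 * window`, clipped at scaffold ends to the number of
#' flanking genes actually available.  `order_conserved` is `TRUE` iff the
#' shared orthologs appear in the same relative order in both windows,
#' allowing reversal of the whole window (orientation-insensitive).
#'
#' @param focal_pair One-row data.frame with `gene_a` (in `assembly_a`) and
#'   `gene_b` (in `assembly_b`).
#' @param assembly_a,assembly_b Assemblies with gene tables attached.
#' @param ortholog_map data.frame with `gene_a`, `gene_b` columns (1:1).
#' @param window Genes per side (default 4).
#' @return List of class `synteny_report`: `focal_pair`, `window`,
#'   `shared_flank_fraction`, `order_conserved`, `neighbor_gap_bp`.
#' @export
microsynteny <- function(focal_pair, assembly_a, assembly_b, ortholog_map,
                         window = 4L) {
  oa <- .scaffold_gene_order(assembly_a, focal_pair$gene_a)
  ob <- .scaffold_gene_order(assembly_b, focal_pair$gene_b)
  flank_idx <- function(o, window) {
    n <- nrow(o$genes)
    setdiff(seq(max(1L, o$idx - window), min(n, o$idx + window)), o$idx)
  }
  fa <- flank_idx(oa, window)
  fb <- flank_idx(ob, window)
  a_flank <- oa$genes$gene_id[fa]            # in positional order
  b_flank <- ob$genes$gene_id[fb]
  map <- setNames(ortholog_map$gene_b, ortholog_map$gene_a)
  partners <- unname(map[a_flank])
  shared <- !is.na(partners) & partners %in% b_flank
  denom <- length(a_flank)
  frac <- if (denom == 0L) 0 else sum(shared) / denom
  order_ok <- TRUE
  if (sum(shared) >= 2L) {
    pos_b <- match(partners[shared], b_flank)
    order_ok <- all(diff(pos_b) > 0) || all(diff(pos_b) < 0)
  }
  nd <- neighbor_distance(focal_pair$gene_a, assembly_a)
  structure(list(focal_pair = focal_pair, window = as.integer(window),
                 shared_flank_fraction = frac, order_conserved = order_ok,
                 n_shared = sum(shared), n_flank = denom,
                 neighbor_gap_bp = if (is.null(nd)) NA_integer_ else nd$gap_bp),
            class = "synteny_report")
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf(
    "<synteny_report> %s ~ %s  window %d: %d/%d flanking orthologs shared (%.2f), order %s\n",
    x$focal_pair$gene_a, x$focal_pair$gene_b, x$window, x$n_shared,
    x$n_flank, x$shared_flank_fraction,
    if (x$order_conserved) "conserved" else "not conserved"))
  invisible(x)
}

#' Nearest neighboring gene and intergenic gap
#'
#' The nearest other gene on the same scaffold by inter-interval gap
#' (end-to-start distance; 0 if the intervals overlap).  Ties are broken
#' toward the downstream gene.  The gap defines the bridging interval for
#' PCR primer design across an LGT/host-gene boundary.
#'
#' @param focal_gene Gene id.
#' @param assembly An [assembly()] with genes.
#' @return List with `neighbor_id` and `gap_bp`, or `NULL` if the scaffold
#'   has a single gene.
#' @export
neighbor_distance <- function(focal_gene, assembly) {
  o <- .scaffold_gene_order(assembly, focal_gene)
  g <- o$genes
  if (nrow(g) < 2L) return(NULL)
  focal <- g[o$idx, ]
  others <- g[-o$idx, , drop = FALSE]
  gap <- pmax(0L, pmax(others$start - focal$end, focal$start - others$end))
  downstream <- others$start >= focal$end
  ord <- order(gap, !downstream)  # ties -> downstream gene first
  list(neighbor_id = others$gene_id[[ord[1L]]], gap_bp = gap[[ord[1L]]])
}
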