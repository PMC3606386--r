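#' Recompute the published GH31 comparison from the real gene sets
#'
#' Given a directory containing the real coding sequences of the three
#' lepidopteran GH31 lateral-transfer genes --- `bmgh31.fna` (BGIBMGA013995,
#' SilkDB OGS), `dpgh31.fna` (DPGLEAN20412, MonarchBase OGS1) and
#' `pxgh31.fna` (Px016165, DBM gene set), each a single-record DNA FASTA ---
#' recomputes the quantities reported for them: peptide lengths, pairwise
#' amino-acid identity over the aligned columns of the Bm/Dp protein
#' alignment, and maximum-likelihood dN/dS for the three pairs.  These gene
#' sets are distributed by their genome databases and are not bundled with
#' the package.
#'
#' @param dir Directory holding `bmgh31.fna`, `dpgh31.fna`, `pxgh31.fna`.
#' @return List with `peptide_lengths` (named, aa), `identity_bm_dp`
#'   (percent), and `dnds` (named list of `dnds_result`: `bm_dp`, `dp_px`,
#'   `bm_px`).
#' @export
reproduce_published_comparison <- function(dir) {
  need <- c(bm = "bmgh31.fna", dp = "dpgh31.fna", px = "pxgh31.fna")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing real gene set file(s) in ", dir, ": ",
         paste(missing, collapse = ", "),
         " (retrieve the BmGH31/DpGH31/PxGH31 CDS from SilkDB, MonarchBase",
         " and the DBM database; they are not redistributable fixtures)")
  cds <- lapply(paths, function(p) unname(read_fasta(p, "dna")[[1L]]))
  names(cds) <- names(need)
  aa_scheme <- scoring_scheme("protein")
  pep <- vapply(cds, function(x) {
    chk <- .check_cds(x)
    nchar(chk$aa)
  }, integer(1))
  aln <- build_codon_alignment(cds$bm, cds$dp, "BmGH31", "DpGH31", aa_scheme)
  keep <- aln$codons_a != "---" & aln$codons_b != "---"
  aa_a <- vapply(aln$codons_a[keep], translate_cds, character(1))
  aa_b <- vapply(aln$codons_b[keep], translate_cds, character(1))
  identity <- 100 * mean(aa_a == aa_b)
  pairs <- list(bm_dp = c("bm", "dp"), dp_px = c("dp", "px"),
                bm_px = c("bm", "px"))
  dnds <- lapply(pairs, function(pr) {
    pair <- build_codon_alignment(cds[[pr[1L]]], cds[[pr[2L]]],
                                  pr[1L], pr[2L], aa_scheme)
    ml_pairwise_dnds(pair)
  })
  list(peptide_lengths = pep, identity_bm_dp = identity, dnds = dnds)
}
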