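#' @title Sequence and annotation data model
#' @description Readers/writers and validated containers for the formats the
#'   pipeline touches: FASTA (DNA and protein) and a 5-column gene table.
#'   Sequences are carried as named uppercase character vectors; assemblies
#'   bundle scaffolds with an ordered gene table.  All internal coordinates
#'   are 0-based half-open; human-readable report writers emit 1-based
#'   inclusive coordinates.
#' @name datamodel
NULL

DNA_CHARS  <- c("A", "C", "G", "T", "N")
PROT_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.alphabet_chars <- function(alphabet) {
  switch(alphabet, dna = DNA_CHARS, protein = PROT_CHARS,
         stop("unknown alphabet: ", alphabet))
}

.validate_seqs <- function(seqs, alphabet) {
  chars <- .alphabet_chars(alphabet)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all records must carry a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[[1L]])
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record ", ids[!nzchar(seqs)][[1L]])
  }
  bad_rx <- paste0("[^", paste(chars, collapse = ""), "]")
  hit <- regexpr(bad_rx, seqs)
  if (any(hit > 0L)) {
    i <- which(hit > 0L)[[1L]]
    stop(sprintf("illegal %s character '%s' in record %s at position %d",
                 alphabet, substr(seqs[[i]], hit[[i]], hit[[i]]), ids[[i]],
                 hit[[i]]))
  }
  invisible(seqs)
}

#' Read a FASTA file into a named character vector
#'
#' Accepts line-wrapped and single-line records and tolerates blank lines.
#' Sequences are uppercased on load and validated against the requested
#' alphabet (DNA: `ACGTN`; protein: the 20 amino acids plus `X`).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of uppercase sequences, in file order,
#'   with attribute `alphabet`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))  # id = first token of header
  .validate_seqs(seqs, alphabet)
  structure(seqs, alphabet = alphabet)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' `N` complements to `N`.
#'
#' @param seq DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

#' Construct an assembly
#'
#' An assembly bundles scaffolds (named DNA character vector) with an
#' optional gene table.  Genes are validated against scaffold bounds,
#' sorted by start within each scaffold, and carry their extracted CDS
#' (reverse-complemented for minus-strand genes).
#'
#' @param scaffolds Named character vector of DNA scaffolds.
#' @param genes Optional data.frame with columns `gene_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open) and `strand` (`+`/`-`).
#' @param validate_cds Require each CDS length to be a multiple of 3 with no
#'   internal stop codon (the intronless-gene invariant).
#' @return Object of class `lgt_assembly`: list with elements `scaffolds`
#'   and `genes` (gene table plus a `cds_seq` column).
#' @export
assembly <- function(scaffolds, genes = NULL, validate_cds = TRUE) {
  .validate_seqs(scaffolds, "dna")
  obj <- list(scaffolds = scaffolds, genes = NULL)
  class(obj) <- "lgt_assembly"
  if (!is.null(genes)) obj <- attach_genes(obj, genes, validate_cds)
  obj
}

#' @export
print.lgt_assembly <- function(x, ...) {
  cat(sprintf("<lgt_assembly> %d scaffolds (%d bp), %d genes\n",
              length(x$scaffolds), sum(nchar(x$scaffolds)),
              if (is.null(x$genes)) 0L else nrow(x$genes)))
  invisible(x)
}

#' Extract a scaffold subsequence (0-based half-open)
#' @param assembly An `lgt_assembly`.
#' @param scaffold_id Scaffold id.
#' @param start,end 0-based half-open interval.
#' @return DNA string.
#' @export
scaffold_region <- function(assembly, scaffold_id, start, end) {
  s <- assembly$scaffolds[[scaffold_id]]
  if (is.null(s) || is.na(s)) stop("unknown scaffold: ", scaffold_id)
  if (start < 0 || end > nchar(s) || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for scaffold %s (%d bp)",
                 start, end, scaffold_id, nchar(s)))
  substr(s, start + 1L, end)
}

attach_genes <- function(assembly, genes, validate_cds = TRUE) {
  need <- c("gene_id", "scaffold_id", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  genes <- genes[need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][[1L]])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(genes))) {
    sid <- genes$scaffold_id[[i]]
    if (!sid %in% names(assembly$scaffolds))
      stop("unknown scaffold in gene table: ", sid)
    slen <- nchar(assembly$scaffolds[[sid]])
    if (genes$start[[i]] < 0L || genes$end[[i]] > slen ||
        genes$start[[i]] >= genes$end[[i]])
      stop(sprintf("gene %s coordinates [%d,%d) out of bounds (scaffold %s, %d bp)",
                   genes$gene_id[[i]], genes$start[[i]], genes$end[[i]], sid,
                   slen))
  }
  genes$cds_seq <- vapply(seq_len(nrow(genes)), function(i) {
    s <- scaffold_region(assembly, genes$scaffold_id[[i]], genes$start[[i]],
                         genes$end[[i]])
    if (genes$strand[[i]] == "-") revcomp(s) else s
  }, character(1))
  if (validate_cds && nrow(genes)) {
    bad <- which(nchar(genes$cds_seq) %% 3L != 0L)
    if (length(bad)) stop("CDS length of gene ", genes$gene_id[[bad[1L]]],
                          " is not a multiple of 3")
    for (i in seq_len(nrow(genes))) {
      aa <- translate_cds(genes$cds_seq[[i]])
      if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L)))
        stop("internal stop codon in gene ", genes$gene_id[[i]])
    }
  }
  # sort by scaffold then start; reject duplicated intervals
  ord <- order(genes$scaffold_id, genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  assembly$genes <- genes
  assembly
}

#' Read a gene table and attach it to an assembly
#'
#' The gene table is a 5-column TSV (`gene_id`, `scaffold_id`, `start`,
#' `end`, `strand`) with a header row; `start`/`end` are 0-based half-open.
#' Lines starting with `#` are metadata and are skipped.
#'
#' @param path Path to the TSV.
#' @param assembly An `lgt_assembly` whose scaffolds the genes refer to.
#' @param validate_cds See [assembly()].
#' @return The assembly with genes attached (sorted by start per scaffold),
#'   each with its extracted `cds_seq`.
#' @export
read_gene_table <- function(path, assembly, validate_cds = TRUE) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attach_genes(assembly, tab, validate_cds)
}

#' Write a gene table as TSV
#' @param assembly An `lgt_assembly` with genes.
#' @param path Output path.
#' @param meta Optional character vector of metadata lines (written
#'   '#'-prefixed above the header).
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(assembly, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  g <- assembly$genes[c("gene_id", "scaffold_id", "start", "end", "strand")]
  writeLines(paste(names(g), collapse = "\t"), con)
  writeLines(do.call(paste, c(g, sep = "\t")), con)
  invisible(path)
}

.codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  codons <- character(64); k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
}

#' Translate an in-frame CDS
#'
#' Universal genetic code; codons containing `N` translate to `X`; stop
#' codons translate to `*`.
#'
#' @param cds DNA string with length a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  tab <- .codon_table()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
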