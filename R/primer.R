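#' @title Degenerate primer design and in-silico PCR
#' @description Conserved gap-free blocks of a DNA alignment are reduced to
#'   their minimal covering IUPAC consensus, turned into degenerate primers,
#'   and screened against templates by degeneracy-aware in-silico PCR: a
#'   template base matches a primer code iff it belongs to the code's base
#'   set, mismatches are allowed outside an exactly matching 3'-terminal
#'   anchor.
#' @name primer
NULL

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
BITS_IUPAC <- setNames(names(IUPAC_BITS)[order(IUPAC_BITS)],
                       sort(IUPAC_BITS))

.iupac_card <- function(code) {
  bits <- IUPAC_BITS[[code]]
  sum(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)
}

#' Degeneracy of an IUPAC pattern
#'
#' The product of per-position code cardinalities (e.g. `R` contributes 2,
#' `N` contributes 4).
#'
#' @param iupac_seq IUPAC nucleotide string.
#' @return Integer degeneracy.
#' @export
degeneracy <- function(iupac_seq) {
  codes <- strsplit(iupac_seq, "")[[1L]]
  if (!all(codes %in% names(IUPAC_BITS)))
    stop("not an IUPAC nucleotide string: ", iupac_seq)
  prod(vapply(codes, .iupac_card, integer(1)))
}

#' Reverse-complement an IUPAC pattern
#' @param iupac_seq IUPAC string.
#' @return Reverse complement (codes complemented set-wise, e.g. `R` to
#'   `Y`, `D` to `H`).
#' @export
revcomp_iupac <- function(iupac_seq) {
  bits <- IUPAC_BITS[strsplit(iupac_seq, "")[[1L]]]
  # complement base sets: swap A<->T and C<->G bits
  comp <- bitwOr(bitwOr(ifelse(bitwAnd(bits, 1L) > 0L, 8L, 0L),
                        ifelse(bitwAnd(bits, 8L) > 0L, 1L, 0L)),
                 bitwOr(ifelse(bitwAnd(bits, 2L) > 0L, 4L, 0L),
                        ifelse(bitwAnd(bits, 4L) > 0L, 2L, 0L)))
  paste(rev(BITS_IUPAC[as.character(comp)]), collapse = "")
}

.column_consensus_bits <- function(chars) {
  # chars: vector of observed bases (A/C/G/T/N) in one alignment column
  Reduce(bitwOr, IUPAC_BITS[chars])
}

#' Find conserved low-degeneracy blocks in a DNA alignment
#'
#' Maximal gap-free column windows whose per-column minimal covering IUPAC
#' consensus gives a window degeneracy at most `max_degeneracy` and length
#' at least `min_len`.
#'
#' @param dna_alignment Named character vector of equal-length aligned DNA
#'   sequences (`-` for gaps).
#' @param min_len Minimum window length in bp.
#' @param max_degeneracy Maximum product of column cardinalities.
#' @return data.frame with `start`, `end` (0-based half-open alignment
#'   columns), `length`, `degeneracy`, sorted by ascending degeneracy then
#'   descending length.
#' @export
find_conserved_blocks <- function(dna_alignment, min_len = 18L,
                                  max_degeneracy = 512L) {
  stopifnot(length(dna_alignment) >= 2L)
  L <- unique(nchar(dna_alignment))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(dna_alignment), ""))
  has_gap <- apply(chars == "-", 2L, any)
  card <- rep(NA_integer_, L)
  for (j in which(!has_gap))
    card[j] <- .iupac_card(BITS_IUPAC[[as.character(
      .column_consensus_bits(chars[, j]))]])
  out <- list()
  seg_bounds <- function(gapmask) {
    r <- rle(!gapmask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  for (seg in seq_len(nrow(seg_bounds(has_gap)))) {
    sb <- seg_bounds(has_gap)[seg, ]
    lo <- sb[[1L]]; hi <- sb[[2L]]
    # sliding window: for each start, furthest end with product <= max
    e <- lo - 1L; prodv <- 1
    max_end <- integer(hi - lo + 1L)
    for (s in lo:hi) {
      if (e < s - 1L) { e <- s - 1L; prodv <- 1 }
      while (e < hi && prodv * card[e + 1L] <= max_degeneracy) {
        e <- e + 1L; prodv <- prodv * card[e]
      }
      max_end[s - lo + 1L] <- e
      prodv <- prodv / card[s]
    }
    for (s in lo:hi) {
      e <- max_end[s - lo + 1L]
      len <- e - s + 1L
      if (len < min_len) next
      # maximal: cannot extend left (s == lo or left window reaches less far)
      if (s > lo && max_end[s - lo] >= e) next
      out[[length(out) + 1L]] <- data.frame(
        start = s - 1L, end = e, length = len,
        degeneracy = prod(card[s:e]))
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      degeneracy = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$degeneracy, -res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Make a degenerate primer from an alignment block
#'
#' The block's per-column minimal covering IUPAC consensus; reverse
#' orientation returns the reverse complement of the consensus.
#'
#' @param block One-row data.frame from [find_conserved_blocks()] (fields
#'   `start`, `end`), or a list with those fields.
#' @param dna_alignment The alignment the block came from.
#' @param orientation `"forward"` or `"reverse"`.
#' @param name Primer name.
#' @return Object of class `degenerate_primer`: list with `name`,
#'   `iupac_seq`, `degeneracy`, `alignment_span`, `orientation`.
#' @export
make_primer <- function(block, dna_alignment,
                        orientation = c("forward", "reverse"),
                        name = "primer") {
  orientation <- match.arg(orientation)
  chars <- do.call(rbind, strsplit(toupper(dna_alignment), ""))
  cols <- seq(block$start + 1L, block$end)
  consensus <- vapply(cols, function(j)
    BITS_IUPAC[[as.character(.column_consensus_bits(chars[, j]))]],
    character(1))
  seq <- paste(consensus, collapse = "")
  if (orientation == "reverse") seq <- revcomp_iupac(seq)
  structure(list(name = name, iupac_seq = seq, degeneracy = degeneracy(seq),
                 alignment_span = c(block$start, block$end),
                 orientation = orientation),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer %s %s> 5'-%s-3' (degeneracy %d)\n",
              x$name, x$orientation, x$iupac_seq, x$degeneracy))
  invisible(x)
}

# 0-based start offsets where the IUPAC pattern matches the template,
# allowing <= max_mismatch mismatches outside the last `anchor` pattern
# positions (3' end at the pattern's right), which must match exactly.
.pattern_sites <- function(pattern_bits, template_bits, max_mismatch,
                           anchor) {
  k <- length(pattern_bits)
  n <- length(template_bits)
  if (n < k) return(list(start = integer(), mism = integer()))
  n_off <- n - k + 1L
  mism <- integer(n_off)
  anchored <- rep(TRUE, n_off)
  for (j in seq_len(k)) {
    hit <- bitwAnd(template_bits[j:(j + n_off - 1L)], pattern_bits[[j]]) > 0L
    if (j > k - anchor) anchored <- anchored & hit
    else mism <- mism + !hit
  }
  keep <- anchored & mism <= max_mismatch
  list(start = which(keep) - 1L, mism = mism[keep])
}

.encode_bits <- function(seq) unname(IUPAC_BITS[strsplit(seq, "")[[1L]]])

#' In-silico PCR with degenerate primers
#'
#' Finds all template sites where the forward primer matches the plus
#' strand and the reverse primer matches the minus strand (i.e. the reverse
#' complement of the reverse primer matches the plus strand, with its 3'
#' anchor at the left end).  Matching is degeneracy-aware; at most
#' `max_mismatch` mismatches are allowed outside the 3'-terminal
#' `anchor_3prime` bases, which must match exactly.  All pairings with
#' `0 < product_length <= max_product` are reported.
#'
#' @param fwd,rev `degenerate_primer` objects (or IUPAC strings).
#' @param template Single named DNA character (the template sequence).
#' @param max_mismatch Mismatches tolerated outside the anchor (default 1).
#' @param anchor_3prime 3'-terminal bases that must match exactly
#'   (default 3).
#' @param max_product Maximum product length in bp (default 5000).
#' @return data.frame of amplicons: `template_id`, `fwd_start`, `fwd_end`,
#'   `rev_start`, `rev_end` (0-based half-open, plus strand),
#'   `product_length`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   product length.
#' @export
insilico_pcr <- function(fwd, rev, template, max_mismatch = 1L,
                         anchor_3prime = 3L, max_product = 5000L) {
  fseq <- if (inherits(fwd, "degenerate_primer")) fwd$iupac_seq else fwd
  rseq <- if (inherits(rev, "degenerate_primer")) rev$iupac_seq else rev
  template_id <- if (!is.null(names(template))) names(template)[[1L]]
  else "template"
  tbits <- .encode_bits(toupper(template[[1L]]))
  fbits <- .encode_bits(fseq)
  # reverse primer binds the minus strand: its plus-strand footprint is the
  # reverse complement, whose leftmost base is the primer's 3' terminus
  rc <- revcomp_iupac(rseq)
  rbits <- .encode_bits(rc)
  fsites <- .pattern_sites(fbits, tbits, max_mismatch, anchor_3prime)
  # for the reverse footprint the anchor is at the left: match the reversed
  # pattern against the reversed template, then map coordinates back
  rsites_rev <- .pattern_sites(rev(rbits), rev(tbits), max_mismatch,
                               anchor_3prime)
  n <- length(tbits)
  rstarts <- n - (rsites_rev$start + length(rbits))
  out <- list()
  for (i in seq_along(fsites$start)) {
    fs <- fsites$start[[i]]
    for (j in seq_along(rstarts)) {
      rs <- rstarts[[j]]
      plen <- (rs + length(rbits)) - fs
      if (plen <= 0L || plen > max_product) next
      if (rs < fs + length(fbits)) next  # primers must not overlap
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, fwd_start = fs,
        fwd_end = fs + length(fbits), rev_start = rs,
        rev_end = rs + length(rbits), product_length = plen,
        fwd_mismatches = fsites$mism[[i]],
        rev_mismatches = rsites_rev$mism[[j]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(template_id = character(), fwd_start = integer(),
                      fwd_end = integer(), rev_start = integer(),
                      rev_end = integer(), product_length = integer(),
                      fwd_mismatches = integer(), rev_mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$product_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expand a degenerate IUPAC pattern into all non-degenerate variants
#' @param iupac_seq IUPAC string.
#' @return Character vector of plain ACGT sequences.
#' @export
expand_iupac <- function(iupac_seq) {
  sets <- lapply(strsplit(iupac_seq, "")[[1L]], function(code) {
    bits <- IUPAC_BITS[[code]]
    c("A", "C", "G", "T")[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
  })
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}
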