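#' @title Local similarity search with Karlin-Altschul statistics
#' @description A self-contained seed-and-extend local alignment engine
#'   (exact-word seeding for DNA, neighborhood-word seeding for protein;
#'   ungapped X-drop extension followed by banded gapped refinement) with
#'   E-values from the Karlin-Altschul formula `E = K m n exp(-lambda S)`.
#'   Gapped alignments reuse the ungapped `lambda`/`K` (a documented
#'   approximation: the screen's decisions rest on E-value comparisons,
#'   which this preserves).  No composition-based statistics and no
#'   effective-length correction are applied (raw `m * n`).
#' @name homology
NULL

#' Build a scoring scheme
#'
#' Nucleotide defaults are BLASTN-like (match +2, mismatch -3, gap open 5,
#' extend 2, word size 11); protein defaults are BLOSUM62 with gap open 11,
#' extend 1, word size 3 and neighborhood seed threshold 11.  `N` (DNA) and
#' `X` (protein) score as the worst-case mismatch and never seed.
#' Gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param matrix_name Protein substitution matrix (only `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param word_size Seed word length.
#' @param seed_threshold Minimum word score to seed (protein neighborhood
#'   threshold; for DNA the exact-word score is always used).
#' @return An object of class `scoring_scheme` (uncalibrated: `lambda` and
#'   `K` are `NULL` until [calibrate_scoring()] is applied).
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 2L, mismatch = -3L,
                           matrix_name = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           word_size = NULL, seed_threshold = NULL) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    chars <- DNA_CHARS
    m <- matrix(as.integer(mismatch), 5L, 5L, dimnames = list(chars, chars))
    diag(m) <- as.integer(match)
    worst <- min(m)
    m["N", ] <- worst; m[, "N"] <- worst
    scheme <- list(kind = kind, match = as.integer(match),
                   mismatch = as.integer(mismatch), matrix = m,
                   alphabet = chars, wild_code = 4L,
                   gap_open = if (is.null(gap_open)) 5L else as.integer(gap_open),
                   gap_extend = if (is.null(gap_extend)) 2L else as.integer(gap_extend),
                   word_size = if (is.null(word_size)) 11L else as.integer(word_size),
                   seed_threshold = if (is.null(seed_threshold))
                     as.integer(match) * (if (is.null(word_size)) 11L else as.integer(word_size))
                   else as.integer(seed_threshold),
                   lambda = NULL, K = NULL, K_method = NULL)
  } else {
    if (matrix_name != "BLOSUM62")
      stop("only BLOSUM62 is bundled for protein scoring")
    data("BLOSUM62", package = "Biostrings", envir = environment())
    chars <- PROT_CHARS
    m <- BLOSUM62[chars[chars != "X"], chars[chars != "X"]]
    worst <- min(m)
    m <- rbind(cbind(m, X = worst), X = worst)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(chars, chars)
    scheme <- list(kind = kind, matrix_name = matrix_name, matrix = m,
                   alphabet = chars, wild_code = 20L,
                   gap_open = if (is.null(gap_open)) 11L else as.integer(gap_open),
                   gap_extend = if (is.null(gap_extend)) 1L else as.integer(gap_extend),
                   word_size = if (is.null(word_size)) 3L else as.integer(word_size),
                   seed_threshold = if (is.null(seed_threshold)) 11L
                   else as.integer(seed_threshold),
                   lambda = NULL, K = NULL, K_method = NULL)
  }
  class(scheme) <- "scoring_scheme"
  scheme
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s; gap %d/%d; word %d", x$kind, x$gap_open,
              x$gap_extend, x$word_size))
  if (!is.null(x$lambda))
    cat(sprintf("; lambda = %.6f, K = %.6f (%s)", x$lambda, x$K, x$K_method))
  cat("\n")
  invisible(x)
}

.default_background <- function(scheme) {
  n <- scheme$wild_code  # non-wildcard alphabet size
  setNames(rep(1 / n, n), scheme$alphabet[seq_len(n)])
}

#' Calibrate Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda s_ij) = 1`, solved to a residual below 1e-10.
#' `K` is computed by the standard ungapped lattice computation of Karlin &
#' Altschul (score-distribution convolutions over the score lattice); the
#' method name is recorded in the scheme.
#'
#' @param scheme A [scoring_scheme()].
#' @param background Named residue frequencies over the non-wildcard
#'   alphabet (default uniform).
#' @return The scheme with `lambda`, `K` and `K_method` filled in.
#' @export
calibrate_scoring <- function(scheme, background = NULL) {
  if (is.null(background)) background <- .default_background(scheme)
  chars <- scheme$alphabet[seq_len(scheme$wild_code)]
  p <- background[chars]
  if (any(is.na(p)) || abs(sum(p) - 1) > 1e-8)
    stop("background must be frequencies over ", paste(chars, collapse = ""))
  s <- scheme$matrix[chars, chars]
  pp <- outer(p, p)
  es <- sum(pp * s)
  if (es >= 0)
    stop("calibration error: expected score per aligned pair is ",
         format(es), " >= 0; Karlin-Altschul statistics undefined")
  if (max(s) <= 0) stop("calibration error: no positive score")
  f <- function(lam) sum(pp * exp(lam * s)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-9, hi), tol = 1e-14)$root
  stopifnot(abs(f(lambda)) < 1e-10)
  scheme$lambda <- lambda
  # --- K: lattice computation over the single-pair score distribution
  svals <- sort(unique(as.vector(s)))
  probs <- vapply(svals, function(v) sum(pp[s == v]), numeric(1))
  delta <- Reduce(.gcd, abs(svals[svals != 0]))
  H <- lambda * sum(probs * svals * exp(lambda * svals))  # relative entropy
  # sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ]
  lo <- min(svals); hi_s <- max(svals)
  dist <- setNames(probs, as.character(svals))  # distribution of S_k
  offset <- lo                                  # current minimum support
  vals <- svals; pr <- probs
  sigma <- 0
  for (k in 1:60) {
    if (k > 1) {
      # convolve with single-pair distribution
      newmin <- offset + lo; newmax <- (k * hi_s)
      support <- seq(newmin, newmax)
      newpr <- numeric(length(support))
      for (t in seq_along(svals)) {
        idx <- (vals + svals[t]) - newmin + 1
        newpr[idx] <- newpr[idx] + pr * probs[t]
      }
      keep <- newpr > 0
      vals <- support[keep]; pr <- newpr[keep]
      offset <- min(vals)
    }
    neg <- vals < 0
    term <- (sum(pr[!neg]) + sum(pr[neg] * exp(lambda * vals[neg]))) / k
    sigma <- sigma + term
    if (term < 1e-12) break
  }
  K <- (delta * lambda * exp(-2 * sigma)) / (H * (1 - exp(-lambda * delta)))
  scheme$K <- K
  scheme$K_method <- "karlin-altschul-1990-lattice"
  scheme
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score Raw alignment score.
#' @param m Query length.
#' @param n Total database length.
#' @param scheme A calibrated [scoring_scheme()].
#' @return Expected number of chance alignments scoring at least `score`.
#' @export
evalue_of <- function(score, m, n, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$K))
    stop("scheme is not calibrated; run calibrate_scoring() first")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

.bitscore <- function(score, scheme) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

encode_seq <- function(seq, scheme) {
  codes <- match(strsplit(seq, "")[[1L]], scheme$alphabet) - 1L
  if (anyNA(codes)) stop("sequence contains characters outside the scheme alphabet")
  codes
}

#' Find high-scoring segment pairs between a query and a database
#'
#' Exact-word seeding on both strands for DNA (reverse-complement hits carry
#' strand `-`); neighborhood-word seeding for protein.  Seeds are extended
#' ungapped with X-drop, then refined by banded gapped extension.
#' Overlapping HSPs are deduplicated keeping the higher score.
#'
#' @param query Single named character (one sequence), or unnamed with
#'   `query_id` supplied.
#' @param db Named character vector of subject sequences.
#' @param scheme Calibrated [scoring_scheme()].
#' @param evalue_cutoff Report only HSPs with `E <= evalue_cutoff`.
#' @param xdrop Ungapped X-drop threshold (raw score units).
#' @param band_pad Half-width of the gapped-refinement band.
#' @param query_id Query id when `query` is unnamed.
#' @param both_strands Search the reverse complement of each subject too
#'   (DNA only).
#' @return data.frame of HSPs with columns `query_id`, `subject_id`,
#'   `strand`, `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open on
#'   the plus strand of both sequences), `raw_score`, `bitscore`, `evalue`,
#'   `pct_identity`, `align_len`, `mismatch`, `gapopen`; sorted by ascending
#'   E-value then descending score.
#' @export
find_hsps <- function(query, db, scheme, evalue_cutoff = 10,
                      xdrop = 20L, band_pad = 50L, query_id = NULL,
                      both_strands = (scheme$kind == "nucleotide")) {
  if (is.null(scheme$lambda)) stop("scheme is not calibrated")
  if (is.null(query_id)) query_id <- names(query)
  if (is.null(query_id)) stop("query must be named or query_id supplied")
  query <- unname(query[[1L]])
  empty <- data.frame(query_id = character(), subject_id = character(),
                      strand = character(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), raw_score = integer(),
                      bitscore = numeric(), evalue = numeric(),
                      log10_evalue = numeric(),
                      pct_identity = numeric(), align_len = integer(),
                      mismatch = integer(), gapopen = integer(),
                      stringsAsFactors = FALSE)
  if (length(db) == 0L || nchar(query) < scheme$word_size) return(empty)
  m <- nchar(query)
  n_total <- sum(nchar(db))
  # minimum raw score that can reach the cutoff (pruning only)
  min_score <- ceiling(log(scheme$K * m * n_total / evalue_cutoff) /
                         scheme$lambda)
  if (!is.finite(min_score)) min_score <- scheme$seed_threshold
  min_score <- max(scheme$seed_threshold, min_score)
  qcodes <- encode_seq(query, scheme)
  out <- list()
  strands <- if (scheme$kind == "nucleotide" && both_strands) c("+", "-") else "+"
  for (si in seq_along(db)) {
    sname <- names(db)[[si]]
    for (strand in strands) {
      sseq <- if (strand == "+") db[[si]] else revcomp(db[[si]])
      scodes <- encode_seq(sseq, scheme)
      hits <- cpp_hsp_search(qcodes, scodes, scheme$matrix, scheme$wild_code,
                             scheme$gap_open, scheme$gap_extend,
                             scheme$word_size, scheme$seed_threshold,
                             scheme$kind == "protein", as.integer(xdrop),
                             as.integer(band_pad), as.integer(min_score))
      if (nrow(hits) == 0L) next
      slen <- nchar(db[[si]])
      if (strand == "-") {
        # map coordinates back to the plus strand of the subject
        new_s_start <- slen - hits$s_end
        hits$s_end <- slen - hits$s_start
        hits$s_start <- new_s_start
      }
      hits$query_id <- query_id
      hits$subject_id <- sname
      hits$strand <- strand
      out[[length(out) + 1L]] <- hits
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$bitscore <- .bitscore(res$raw_score, scheme)
  # E kept in log10 space alongside: strict E-value comparisons stay
  # meaningful where the linear value underflows to 0
  res$log10_evalue <- log10(scheme$K * m * n_total) -
    scheme$lambda * res$raw_score / log(10)
  res$evalue <- 10^res$log10_evalue
  res$pct_identity <- 100 * res$nident / res$align_len
  res <- res[res$log10_evalue <= log10(evalue_cutoff), , drop = FALSE]
  res <- res[order(res$log10_evalue, -res$raw_score, res$subject_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[c("query_id", "subject_id", "strand", "q_start", "q_end", "s_start",
        "s_end", "raw_score", "bitscore", "evalue", "log10_evalue",
        "pct_identity", "align_len", "mismatch", "gapopen")]
}

#' Best database hit for a query
#'
#' The HSP with minimum E-value; ties broken by higher raw score, then
#' lexicographically smaller subject id.
#'
#' @inheritParams find_hsps
#' @return One-row HSP data.frame, or `NULL` when nothing scores below the
#'   cutoff.
#' @export
best_hit <- function(query, db, scheme, evalue_cutoff = 10, ...) {
  hits <- find_hsps(query, db, scheme, evalue_cutoff = evalue_cutoff, ...)
  if (nrow(hits) == 0L) return(NULL)
  hits[1L, , drop = FALSE]  # find_hsps sort order encodes the tie rules
}

#' Write HSPs as a BLAST outfmt-6-style TSV
#'
#' Columns `qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`, 1-based inclusive coordinates; minus-strand hits
#' carry `sstart > send`.
#'
#' @param hsps data.frame from [find_hsps()].
#' @param path Output path.
#' @param meta Optional '#'-prefixed metadata lines.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hsps, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(hsps)) {
    sstart <- ifelse(hsps$strand == "-", hsps$s_end, hsps$s_start + 1L)
    send <- ifelse(hsps$strand == "-", hsps$s_start + 1L, hsps$s_end)
    rows <- paste(hsps$query_id, hsps$subject_id,
                  sprintf("%.3f", hsps$pct_identity), hsps$align_len,
                  hsps$mismatch, hsps$gapopen, hsps$q_start + 1L, hsps$q_end,
                  sstart, send, format(hsps$evalue, digits = 3),
                  sprintf("%.1f", hsps$bitscore), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
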