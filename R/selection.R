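#' @title Pairwise dN/dS under counting and maximum-likelihood methods
#' @description Codon alignments are built by globally aligning the
#'   translated proteins and back-translating.  dN/dS is estimated either
#'   by Nei-Gojobori (1986) counting with Jukes-Cantor correction, or by
#'   maximum likelihood under a Goldman-Yang-style 61-state codon model
#'   with F3x4 equilibrium frequencies, an estimated
#'   transition/transversion ratio kappa, and a nonsynonymous/synonymous
#'   rate ratio omega.  The ML convention matches pairwise codeml
#'   (`runmode = -2`, `CodonFreq = 2`, `fix_kappa = 0`): gap columns are
#'   dropped pairwise, and dN/dS are derived from the estimated divergence
#'   and the model's synonymous/nonsynonymous flux proportions.
#' @name selection
NULL

.lgt_cache <- new.env(parent = emptyenv())

# Sense-codon machinery for the universal code: codon list, amino acids,
# single-nucleotide-change classification (synonymous / transition).
codon_machinery <- function() {
  if (!is.null(.lgt_cache$codon)) return(.lgt_cache$codon)
  tab <- .codon_table()
  codons <- names(tab)[tab != "*"]           # 61 sense codons
  aa <- unname(tab[codons])
  n <- length(codons)
  nt <- do.call(rbind, strsplit(codons, ""))  # 61 x 3
  ndiff <- matrix(0L, n, n)
  diff_pos <- matrix(0L, n, n)
  for (p in 1:3) {
    neq <- outer(nt[, p], nt[, p], "!=")
    ndiff <- ndiff + neq
    diff_pos[neq & ndiff == 1L & diff_pos == 0L] <- p
  }
  # recompute diff_pos cleanly for single-difference pairs
  diff_pos <- matrix(0L, n, n)
  for (p in 1:3) {
    only_p <- outer(nt[, p], nt[, p], "!=") & ndiff == 1L
    diff_pos[only_p] <- p
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  is_ti <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (ndiff[i, j] == 1L) {
      p <- diff_pos[i, j]
      is_ti[i, j] <- purine[[nt[i, p]]] == purine[[nt[j, p]]]
    }
  }
  syn <- outer(aa, aa, "==")
  obj <- list(codons = codons, aa = aa, nt = nt, ndiff = ndiff,
              diff_pos = diff_pos, is_ti = is_ti, syn = syn,
              stop_codons = names(tab)[tab == "*"])
  .lgt_cache$codon <- obj
  obj
}

.check_cds <- function(cds, id = "cds") {
  if (nchar(cds) %% 3L != 0L)
    stop("CDS ", id, " length (", nchar(cds), ") is not a multiple of 3")
  aa <- translate_cds(cds)
  n_aa <- nchar(aa)
  if (substr(aa, n_aa, n_aa) == "*") {       # strip trailing stop
    cds <- substr(cds, 1L, nchar(cds) - 3L)
    aa <- substr(aa, 1L, n_aa - 1L)
  }
  pos <- regexpr("\\*", aa)
  if (pos > 0L)
    stop("internal stop codon in ", id, " at codon position ", pos)
  list(cds = cds, aa = aa)
}

#' Build a pairwise codon alignment
#'
#' The two CDS are translated, the proteins are globally aligned
#' (Needleman-Wunsch with the protein scoring scheme), and the alignment is
#' back-translated: each aligned residue column becomes its source codon,
#' residue gaps become `---` codon gaps.  Trailing stop codons are
#' stripped; internal stops are an error.
#'
#' @param cds_a,cds_b In-frame CDS strings.
#' @param id_a,id_b Sequence ids.
#' @param scheme Protein [scoring_scheme()] (calibration not required).
#' @return Object of class `codon_alignment`: list with `id_a`, `id_b`,
#'   `codons_a`, `codons_b` (character vectors, `---` at gaps).
#' @export
build_codon_alignment <- function(cds_a, cds_b, id_a = "a", id_b = "b",
                                  scheme = scoring_scheme("protein")) {
  a <- .check_cds(cds_a, id_a)
  b <- .check_cds(cds_b, id_b)
  pa <- encode_seq(a$aa, scheme)
  pb <- encode_seq(b$aa, scheme)
  aln <- cpp_global_align(pa, pb, scheme$matrix, scheme$gap_open,
                          scheme$gap_extend)
  codon_at <- function(cds, i)
    ifelse(is.na(i), "---", substring(cds, 3L * i + 1L, 3L * i + 3L))
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = codon_at(a$cds, aln$a_pos),
                 codons_b = codon_at(b$cds, aln$b_pos)),
            class = "codon_alignment")
}

#' Construct a codon alignment from pre-aligned codon vectors
#' @param codons_a,codons_b Equal-length character vectors of codons
#'   (`---` for gaps).
#' @param id_a,id_b Sequence ids.
#' @return A `codon_alignment`.
#' @export
codon_alignment <- function(codons_a, codons_b, id_a = "a", id_b = "b") {
  stopifnot(length(codons_a) == length(codons_b))
  cm <- codon_machinery()
  ok <- function(x) all(x %in% c(cm$codons, "---"))
  if (!ok(codons_a) || !ok(codons_b))
    stop("codons must be sense codons or '---'")
  structure(list(id_a = id_a, id_b = id_b, codons_a = codons_a,
                 codons_b = codons_b), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  ng <- sum(x$codons_a != "---" & x$codons_b != "---")
  cat(sprintf("<codon_alignment> %s ~ %s: %d columns (%d non-gap)\n",
              x$id_a, x$id_b, length(x$codons_a), ng))
  invisible(x)
}

.ungapped_columns <- function(pair) {
  keep <- pair$codons_a != "---" & pair$codons_b != "---"
  list(a = pair$codons_a[keep], b = pair$codons_b[keep])
}

#' Positional (codon-position) nucleotide frequencies of a codon alignment
#'
#' The F3x4 input: a 3 x 4 matrix of nucleotide frequencies at each codon
#' position, pooled over both sequences' non-gap columns.
#'
#' @param pair A `codon_alignment`.
#' @return 3 x 4 matrix (rows: codon positions; columns: A, C, G, T).
#' @export
positional_base_freqs <- function(pair) {
  cols <- .ungapped_columns(pair)
  all_cod <- c(cols$a, cols$b)
  m <- matrix(0, 3L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in 1:3) {
    ntp <- substring(all_cod, p, p)
    tb <- table(factor(ntp, levels = c("A", "C", "G", "T")))
    m[p, ] <- as.numeric(tb) / length(ntp)
  }
  m
}

#' F3x4 codon equilibrium frequencies
#'
#' Sense-codon frequencies proportional to the product of positional
#' nucleotide frequencies, renormalized over the 61 sense codons.
#' Frequencies are floored at `1e-6` before normalization so that unseen
#' nucleotides do not produce structural zeros.
#'
#' @param pos_freqs 3 x 4 positional frequency matrix.
#' @return Named numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(pos_freqs) {
  cm <- codon_machinery()
  pf <- pmax(pos_freqs, 1e-6)
  pf <- pf / rowSums(pf)
  colnames(pf) <- c("A", "C", "G", "T")
  pi <- vapply(seq_along(cm$codons), function(i)
    pf[1L, cm$nt[i, 1L]] * pf[2L, cm$nt[i, 2L]] * pf[3L, cm$nt[i, 3L]],
    numeric(1))
  setNames(pi / sum(pi), cm$codons)
}

#' Goldman-Yang codon rate matrix
#'
#' 61-state generator with `q_ij = 0` for multi-nucleotide changes and
#' `q_ij` proportional to `pi_j`, times `kappa` for transitions and `omega`
#' for nonsynonymous changes.  Scaled so the expected number of
#' substitutions per codon per unit time is 1 (`-sum_i pi_i q_ii = 1`).
#'
#' @param pi Named vector of 61 sense-codon frequencies.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @return List with `Q` (61 x 61 generator), `rho_syn` (proportion of the
#'   substitution flux that is synonymous) and `pi`.
#' @export
gy94_rate_matrix <- function(pi, kappa, omega) {
  cm <- codon_machinery()
  n <- length(cm$codons)
  stopifnot(length(pi) == n, kappa >= 0, omega >= 0)
  Q <- matrix(0, n, n, dimnames = list(cm$codons, cm$codons))
  single <- cm$ndiff == 1L
  Q[single] <- rep(pi, each = n)[single]
  Q[single & cm$is_ti] <- Q[single & cm$is_ti] * kappa
  Q[single & !cm$syn] <- Q[single & !cm$syn] * omega
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  flux <- pi * Q
  rho_syn <- sum(flux[single & cm$syn])
  list(Q = Q, rho_syn = rho_syn, pi = pi)
}

# transition probability matrix exp(Q t) via eigendecomposition of the
# pi-symmetrized generator
.gy94_pmat <- function(Q, pi, t) {
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)   # diag(sq) %*% Q %*% diag(1/sq)
  B <- (B + t(B)) / 2              # enforce symmetry numerically
  e <- eigen(B, symmetric = TRUE)
  P <- (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P <- (1 / sq) * P %*% diag(sq)   # diag(1/sq) %*% ... %*% diag(sq)
  pmax(P, 0)
}

.pair_counts <- function(pair) {
  cm <- codon_machinery()
  cols <- .ungapped_columns(pair)
  ia <- match(cols$a, cm$codons)
  ib <- match(cols$b, cm$codons)
  N <- matrix(0, length(cm$codons), length(cm$codons))
  for (k in seq_along(ia)) N[ia[k], ib[k]] <- N[ia[k], ib[k]] + 1
  N
}

.dnds_result <- function(dN, dS, omega, kappa, t, logL, n_codons, method) {
  structure(list(dN = dN, dS = dS, omega = omega, kappa = kappa, t = t,
                 logL = logL, n_codons = n_codons, method = method),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf(
    "<dnds_result %s> dN = %.4f  dS = %.4f  omega = %.4f  kappa = %s  t = %.4f  (%d codons)\n",
    x$method, x$dN, x$dS, x$omega,
    if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa), x$t, x$n_codons))
  invisible(x)
}

# ---- NG86 ----------------------------------------------------------------

# Synonymous/nonsynonymous site fractions of one codon.  Each of the nine
# single-nucleotide neighbors is classified; changes to stop codons are
# excluded and the fractions rescaled so s + n = 3.
.ng86_sites <- function(codon) {
  cm <- codon_machinery()
  i <- match(codon, cm$codons)
  nbr <- which(cm$ndiff[i, ] == 1L)
  n_viable <- length(nbr)                 # stop neighbors are absent from 61
  syn <- sum(cm$syn[i, nbr])
  s <- 3 * syn / n_viable
  c(s = s, n = 3 - s)
}

# Average synonymous/nonsynonymous difference counts between two codons,
# over all minimal substitution pathways; pathways through stop codons are
# discarded (if every pathway is blocked, all are used and steps into stops
# count as nonsynonymous).
.ng86_diffs <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  tab <- .codon_table()
  pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  perms <- if (length(pos) == 1L) list(pos) else {
    if (length(pos) == 2L) list(pos, rev(pos)) else {
      idx <- list()
      for (p1 in pos) for (p2 in setdiff(pos, p1))
        idx[[length(idx) + 1L]] <- c(p1, p2, setdiff(pos, c(p1, p2)))
      idx
    }
  }
  walk <- function(order) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (tab[[cur]] != "*" && tab[[nxt]] != "*" && tab[[cur]] == tab[[nxt]])
        sd <- sd + 1
      else nd <- nd + 1
      if (tab[[nxt]] == "*") blocked <- TRUE  # codon_b itself is sense
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  open <- res["blocked", ] == 0
  use <- if (any(open)) res[, open, drop = FALSE] else res
  c(sd = mean(use["sd", ]), nd = mean(use["nd", ]))
}

#' Nei-Gojobori site and difference counts
#'
#' The uncorrected counting layer: per-codon synonymous/nonsynonymous site
#' fractions averaged over the two sequences, and difference counts
#' averaged over all minimal substitution pathways (pathways through stop
#' codons discarded).
#'
#' @param pair A `codon_alignment`.
#' @return List with `S`, `N` (site totals), `Sd`, `Nd` (difference
#'   totals), `pS`, `pN` (proportions) and `n_codons`.
#' @export
ng86_counts <- function(pair) {
  cols <- .ungapped_columns(pair)
  n_cod <- length(cols$a)
  if (n_cod < 1L) stop("no non-gap codon columns")
  sites_a <- vapply(cols$a, .ng86_sites, numeric(2))
  sites_b <- vapply(cols$b, .ng86_sites, numeric(2))
  S <- (sum(sites_a["s", ]) + sum(sites_b["s", ])) / 2
  N <- (sum(sites_a["n", ]) + sum(sites_b["n", ])) / 2
  diffs <- vapply(seq_len(n_cod),
                  function(k) .ng86_diffs(cols$a[[k]], cols$b[[k]]),
                  numeric(2))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  # zero differences give proportion 0 even when the site total is 0
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       pS = if (Sd == 0) 0 else Sd / S,
       pN = if (Nd == 0) 0 else Nd / N,
       n_codons = n_cod)
}

#' Nei-Gojobori (1986) dN/dS
#'
#' Per-codon synonymous/nonsynonymous site fractions averaged over the two
#' sequences; difference counts averaged over all minimal substitution
#' pathways (pathways through stop codons discarded); Jukes-Cantor
#' correction `d = -3/4 log(1 - 4 p / 3)` applied to the proportions.
#'
#' @param pair A `codon_alignment`.
#' @return A `dnds_result` with `method = "NG86"` (`kappa` and `logL` are
#'   `NA`: the counting method estimates neither).
#' @export
ng86 <- function(pair) {
  cnt <- ng86_counts(pair)
  pS <- cnt$pS; pN <- cnt$pN
  n_cod <- cnt$n_codons
  jc <- function(p) {
    if (p >= 0.75)
      stop("Jukes-Cantor correction undefined: proportion ", format(p),
           " >= 3/4")
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (dS > 0) dN / dS else NA_real_
  .dnds_result(dN, dS, omega, NA_real_, NA_real_, NA_real_, n_cod, "NG86")
}

# ---- GY94 maximum likelihood --------------------------------------------

.gy94_loglik <- function(N, pi, kappa, omega, t) {
  rm <- gy94_rate_matrix(pi, kappa, omega)
  P <- .gy94_pmat(rm$Q, pi, t)
  L <- pi * P                        # pi_i P_ij(t), reversible pairwise form
  nz <- N > 0
  if (any(L[nz] <= 0)) return(-Inf)
  sum(N[nz] * log(L[nz]))
}

#' Maximum-likelihood pairwise dN/dS under the GY94 codon model
#'
#' Maximizes the reversible pairwise likelihood
#' `prod_columns pi_i P_ij(t)` over `(t, kappa, omega)`, with F3x4 codon
#' frequencies taken from the pair.  `dN` and `dS` are derived from the
#' fitted divergence and the model's synonymous/nonsynonymous flux, with
#' site totals computed at `omega = 1` (mutational opportunity), the
#' pairwise codeml convention; under it `dN/dS` equals the fitted `omega`.
#' Optimization is multi-start Nelder-Mead on `(log t, log kappa, log
#' omega)`.
#'
#' @param pair A `codon_alignment` with at least 10 non-gap columns.
#' @param starts Matrix of starting values, one row per start, columns
#'   `t`, `kappa`, `omega`.
#' @return A `dnds_result` with `method = "ML"`.
#' @export
ml_pairwise_dnds <- function(pair,
                             starts = rbind(c(0.5, 2, 0.5),
                                            c(0.1, 1, 0.05),
                                            c(1.5, 4, 1))) {
  cols <- .ungapped_columns(pair)
  n_cod <- length(cols$a)
  if (n_cod < 10L)
    stop("need at least 10 non-gap codon columns (got ", n_cod, ")")
  if (all(cols$a == cols$b)) {
    pi <- f3x4_frequencies(positional_base_freqs(pair))
    idx <- match(cols$a, codon_machinery()$codons)
    logL <- sum(log(pi[idx]))
    warning("no variable columns: divergence at the t = 0 boundary")
    return(.dnds_result(0, 0, NA_real_, NA_real_, 0, logL, n_cod, "ML"))
  }
  pi <- f3x4_frequencies(positional_base_freqs(pair))
  N <- .pair_counts(pair)
  obj <- function(par) {
    ll <- .gy94_loglik(N, pi, exp(par[2L]), exp(par[3L]), exp(par[1L]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(starts[r, ]), obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge from all starts")
  t_hat <- exp(best$par[[1L]])
  kappa_hat <- exp(best$par[[2L]])
  omega_hat <- exp(best$par[[3L]])
  rm_hat <- gy94_rate_matrix(pi, kappa_hat, omega_hat)
  rm_one <- gy94_rate_matrix(pi, kappa_hat, 1)
  rho_s <- rm_hat$rho_syn; rho_n <- 1 - rho_s
  rho_s1 <- rm_one$rho_syn; rho_n1 <- 1 - rho_s1
  dS <- t_hat * rho_s / (3 * rho_s1)
  dN <- t_hat * rho_n / (3 * rho_n1)
  .dnds_result(dN, dS, omega_hat, kappa_hat, t_hat, -best$value, n_cod, "ML")
}

#' Write dN/dS results as TSV
#' @param results A `dnds_result` or list of them.
#' @param path Output path.
#' @param ids Optional character vector labelling each result.
#' @return `path`, invisibly.
#' @export
write_dnds_table <- function(results, path, ids = NULL) {
  if (inherits(results, "dnds_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(x)
    data.frame(dN = x$dN, dS = x$dS, omega = x$omega, kappa = x$kappa,
               t = x$t, logL = x$logL, n_codons = x$n_codons,
               method = x$method, stringsAsFactors = FALSE)))
  if (!is.null(ids)) tab <- cbind(pair = ids, tab)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}
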