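# ---- independent Nei-Gojobori oracle (enumeration written from scratch,
# no shared code with the implementation) ---------------------------------

.oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                         "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1L]]
  cods <- character(64); k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1; cods[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, cods)
})

oracle_sites <- function(codon) {
  s <- 0; n_ok <- 0; syn <- 0
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, p, p)) next
    nb <- codon; substr(nb, p, p) <- b
    if (.oracle_code[[nb]] == "*") next
    n_ok <- n_ok + 1
    if (.oracle_code[[nb]] == .oracle_code[[codon]]) syn <- syn + 1
  }
  3 * syn / n_ok
}

oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1L) list(pos)
  else if (length(pos) == 2L) list(pos, rev(pos))
  else unlist(lapply(combinat_perms(pos), list), recursive = FALSE)
  res <- list()
  for (ord in perms) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
      if (.oracle_code[[cur]] != "*" && .oracle_code[[nxt]] != "*" &&
          .oracle_code[[cur]] == .oracle_code[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      if (.oracle_code[[nxt]] == "*") ok <- FALSE
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(sd, nd, ok)
  }
  m <- do.call(rbind, res)
  use <- m[m[, 3] == 1, , drop = FALSE]
  if (!nrow(use)) use <- m
  c(mean(use[, 1]), mean(use[, 2]))
}

combinat_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

SENSE <- names(.oracle_code)[.oracle_code != "*"]


# brute-force matcher used as the expansion oracle: plain string comparison
# of every expanded variant at every offset
.oracle_sites <- function(primer, tmpl, max_mm, anchor) {
  k <- nchar(primer)
  variants <- expand_iupac(primer)
  hits <- list()
  for (o in 0:(nchar(tmpl) - k)) {
    win <- substr(tmpl, o + 1, o + k)
    best <- Inf
    for (v in variants) {
      wc <- strsplit(win, "")[[1]]; vc <- strsplit(v, "")[[1]]
      neq <- wc != vc
      if (any(neq[(k - anchor + 1):k])) next
      best <- min(best, sum(neq[seq_len(k - anchor)]))
    }
    if (best <= max_mm) hits[[length(hits) + 1L]] <- c(o, best)
  }
  if (!length(hits)) matrix(numeric(0), ncol = 2)
  else do.call(rbind, hits)
}

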