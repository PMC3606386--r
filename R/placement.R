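#' @title Distance-based phylogenetic placement
#' @description Poisson-corrected protein distances, Saitou-Nei neighbor
#'   joining with deterministic tie-breaking, nonparametric bootstrap
#'   support, and origin classification of a focal sequence by the smallest
#'   well-supported split around it.  This is a lightweight, fully testable
#'   stand-in for MCMC tree inference: the decision-relevant output --
#'   whether the focal sequence nests inside the bacterial clade -- is
#'   preserved.
#' @name placement
NULL

#' Poisson-corrected protein distance matrix
#'
#' `d = -log(1 - p)` per pair, where `p` is the mismatch fraction over the
#' columns where both sequences are ungapped (pairwise deletion).
#'
#' @param alignment Named character vector of equal-length aligned protein
#'   sequences (`-` for gaps).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 3L)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(alignment, ""))
  gap <- chars == "-"
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- !gap[i, ] & !gap[j, ]
    if (!any(shared))
      stop("no shared ungapped columns between ", names(alignment)[[i]],
           " and ", names(alignment)[[j]])
    p <- mean(chars[i, shared] != chars[j, shared])
    if (p >= 1)
      stop("saturated distance (p >= 1) between ", names(alignment)[[i]],
           " and ", names(alignment)[[j]])
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion.  Ties in the
#' Q-minimum are broken toward the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf).  Negative
#' branch lengths are clamped to 0 with the deficit moved to the sister
#' branch, preserving their sum.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n >= 3L, identical(labels, colnames(d)))
  # active clusters: newick fragment + representative (smallest leaf) label
  nwk <- labels
  rep_lab <- labels
  D <- d
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_lab[ij[1L]], rep_lab[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], bi, nwk[j], bj)
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
    rownames(D2) <- colnames(D2) <- nwk
    D <- D2
  }
  # final three-cluster star: closed-form three-point branch lengths
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  tree <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                        nwk[1], b[1], nwk[2], b[2],
                                        nwk[3], b[3]))
  tree
}

# canonical string keys of the non-trivial bipartitions of a phylo tree
# (each internal edge; the side not containing the alphabetically first
# leaf, sorted)
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[[1L]]
  parts <- ape::prop.part(tree)
  out <- character()
  for (k in seq_along(parts)) {
    side <- sort(attr(parts, "labels")[parts[[k]]])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate's NJ tree's bipartitions are tallied, and support =
#' tally / `n_reps` is mapped onto the full-data tree's internal edges.
#'
#' @param alignment Named character vector of aligned proteins.
#' @param n_reps Number of pseudoreplicates (>= 1).
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @return List with `tree` (ape phylo; `node.label` holds supports in
#'   `[0, 1]`, empty at the root) and `supports` (named vector keyed by
#'   bipartition).
#' @export
bootstrap_supports <- function(alignment, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  full <- nj_tree(protein_distance(alignment))
  L <- nchar(alignment[[1L]])
  chars <- do.call(rbind, strsplit(alignment, ""))
  tally <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      res <- apply(chars[, cols, drop = FALSE], 1L, paste, collapse = "")
      tr <- tryCatch(nj_tree(protein_distance(setNames(res, names(alignment)))),
                     error = function(e) NULL)
      if (is.null(tr)) next
      for (bp in tree_bipartitions(tr))
        assign(bp, (if (exists(bp, tally)) get(bp, tally) else 0) + 1, tally)
    }
  })
  full_bps <- tree_bipartitions(full)
  supports <- vapply(full_bps, function(bp)
    (if (exists(bp, tally)) get(bp, tally) else 0) / n_reps, numeric(1))
  # attach to internal nodes: find for each internal node its clade key
  tree <- full
  parts <- ape::prop.part(tree)
  tips <- sort(tree$tip.label)
  anchor <- tips[[1L]]
  labs <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- sort(attr(parts, "labels")[parts[[k]]])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) {
      labs[k] <- ""
      next
    }
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "\r")
    labs[k] <- if (key %in% names(supports))
      sprintf("%.3f", supports[[key]]) else ""
  }
  tree$node.label <- labs
  list(tree = tree, supports = supports)
}

#' Classify the origin of a focal leaf
#'
#' Among internal edges with bootstrap support at or above `threshold`, the
#' one whose focal-containing side is smallest is examined: the call is
#' `bacterial_nested` iff every same-side non-focal leaf is labelled
#' bacterial, `eukaryotic_nested` symmetrically, and `ambiguous` otherwise
#' (including when no split reaches the threshold).
#'
#' @param bs Result of [bootstrap_supports()] (list with `tree`,
#'   `supports`).
#' @param focal Focal leaf label.
#' @param kingdom_labels Named character vector mapping every non-focal
#'   leaf to `"bacterial"` or `"eukaryotic"`.
#' @param threshold Support threshold (default 0.8).
#' @return List with `call` (one of `bacterial_nested`,
#'   `eukaryotic_nested`, `ambiguous`), `side` (the supporting leaf set)
#'   and `support`.
#' @export
classify_origin <- function(bs, focal, kingdom_labels, threshold = 0.8) {
  tree <- bs$tree
  if (!focal %in% tree$tip.label) stop("focal leaf not in tree: ", focal)
  others <- setdiff(tree$tip.label, focal)
  miss <- setdiff(others, names(kingdom_labels))
  if (length(miss)) stop("unlabelled leaves: ", paste(miss, collapse = ", "))
  tips <- sort(tree$tip.label)
  best <- NULL
  for (key in names(bs$supports)) {
    if (bs$supports[[key]] < threshold) next
    side <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    focal_side <- if (focal %in% side) side else setdiff(tips, side)
    if (is.null(best) || length(focal_side) < length(best$side))
      best <- list(side = focal_side, support = bs$supports[[key]])
  }
  if (is.null(best))
    return(list(call = "ambiguous", side = character(), support = NA_real_))
  mates <- setdiff(best$side, focal)
  kinds <- unique(kingdom_labels[mates])
  call <- if (identical(kinds, "bacterial")) "bacterial_nested"
  else if (identical(kinds, "eukaryotic")) "eukaryotic_nested"
  else "ambiguous"
  list(call = call, side = best$side, support = best$support)
}

#' Write a tree as Newick with supports as internal-node labels
#' @param bs Result of [bootstrap_supports()], or a bare `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(bs, path) {
  tree <- if (inherits(bs, "phylo")) bs else bs$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
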