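#' @title Differential-homology LGT screen
#' @description Scaffold regions with strong bacterial identity (E-value
#'   below a cutoff) are collected, then discarded when a better animal
#'   E-value marks them as slowly evolving conserved genes, or when they
#'   lie on a short scaffold of the kind dominated by environmental
#'   contamination.  Every candidate is reported with an ordered audit trail
#'   of the filters applied; exclusions are never silently dropped.
#' @name lgt_screen
NULL

#' Screen parameters
#'
#' @param bacterial_evalue_cutoff Regions must have a bacterial E-value
#'   strictly below this (default `1e-5`).
#' @param min_scaffold_length Candidates on scaffolds strictly shorter than
#'   this are excluded (default 5000 bp).
#' @param hsp_merge_gap HSPs on the same scaffold separated by at most this
#'   many bp are merged into one region (default 1000 bp).
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(bacterial_evalue_cutoff = 1e-5,
                          min_scaffold_length = 5000L,
                          hsp_merge_gap = 1000L) {
  stopifnot(bacterial_evalue_cutoff > 0, min_scaffold_length >= 0)
  structure(list(bacterial_evalue_cutoff = bacterial_evalue_cutoff,
                 min_scaffold_length = as.integer(min_scaffold_length),
                 hsp_merge_gap = as.integer(hsp_merge_gap)),
            class = "screen_params")
}

.new_candidate <- function(scaffold_id, start, end, bacterial_best) {
  structure(list(scaffold_id = scaffold_id, start = start, end = end,
                 bacterial_best = bacterial_best, animal_best_evalue = NA_real_,
                 animal_best_log10_evalue = NA_real_,
                 status = "retained", audit = character()),
            class = "lgt_candidate")
}

#' @export
print.lgt_candidate <- function(x, ...) {
  cat(sprintf("<lgt_candidate> %s:%d-%d  bacterial best %s (E = %.3g)  status: %s\n",
              x$scaffold_id, x$start + 1L, x$end,
              x$bacterial_best$subject_id, x$bacterial_best$evalue, x$status))
  if (length(x$audit)) cat("  audit:", paste(x$audit, collapse = " -> "), "\n")
  invisible(x)
}

#' Find scaffold regions with significant bacterial identity
#'
#' Each scaffold is searched against the bacterial database; HSPs with
#' E-value strictly below the cutoff are merged per scaffold when separated
#' by at most `hsp_merge_gap` bp.  Each merged region carries its
#' minimum-E-value HSP as `bacterial_best`.
#'
#' @param assembly An [assembly()].
#' @param bacterial_db Named DNA character vector.
#' @param scheme Calibrated nucleotide [scoring_scheme()].
#' @param params A [screen_params()].
#' @return List of `lgt_candidate` (pre-filter; all `retained`).
#' @export
find_bacterial_regions <- function(assembly, bacterial_db, scheme,
                                   params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  candidates <- list()
  for (sid in names(assembly$scaffolds)) {
    hits <- find_hsps(assembly$scaffolds[sid], bacterial_db, scheme,
                      evalue_cutoff = params$bacterial_evalue_cutoff)
    hits <- hits[hits$log10_evalue < log10(params$bacterial_evalue_cutoff), ,
                 drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- hits[order(hits$q_start), , drop = FALSE]
    # merge query intervals separated by <= hsp_merge_gap
    grp <- integer(nrow(hits)); grp[1L] <- 1L
    cur_end <- hits$q_end[[1L]]
    for (i in seq_len(nrow(hits))[-1L]) {
      if (hits$q_start[[i]] - cur_end <= params$hsp_merge_gap) {
        grp[i] <- grp[i - 1L]
      } else grp[i] <- grp[i - 1L] + 1L
      cur_end <- max(cur_end, hits$q_end[[i]])
    }
    for (g in unique(grp)) {
      sub <- hits[grp == g, , drop = FALSE]
      best <- sub[order(sub$log10_evalue, -sub$raw_score,
                        sub$subject_id)[1L], , drop = FALSE]
      candidates[[length(candidates) + 1L]] <-
        .new_candidate(sid, min(sub$q_start), max(sub$q_end), best)
    }
  }
  candidates
}

#' Animal (conserved-gene) exclusion filter
#'
#' The candidate's extracted region sequence is searched against the animal
#' database; the candidate is excluded iff the best animal E-value is
#' strictly less than its bacterial E-value (the region is then better
#' explained as a slowly evolving, highly conserved gene).  Equal E-values
#' retain.
#'
#' @param candidate An `lgt_candidate`.
#' @param assembly The source [assembly()].
#' @param animal_db Named DNA character vector (may be empty).
#' @param scheme Calibrated nucleotide [scoring_scheme()].
#' @param params A [screen_params()].
#' @return The candidate with `animal_best_evalue`, possibly
#'   `status = "excluded_animal"`, and the filter appended to its audit.
#' @export
animal_filter <- function(candidate, assembly, animal_db, scheme,
                          params = screen_params()) {
  region <- scaffold_region(assembly, candidate$scaffold_id, candidate$start,
                            candidate$end)
  best <- if (length(animal_db))
    best_hit(setNames(region, "region"), animal_db, scheme,
             evalue_cutoff = Inf)
  else NULL
  candidate$animal_best_evalue <- if (is.null(best)) NA_real_ else best$evalue
  candidate$animal_best_log10_evalue <-
    if (is.null(best)) NA_real_ else best$log10_evalue
  excluded <- !is.null(best) &&
    best$log10_evalue < candidate$bacterial_best$log10_evalue
  if (excluded && candidate$status == "retained")
    candidate$status <- "excluded_animal"
  candidate$audit <- c(candidate$audit,
                       sprintf("animal_filter:%s",
                               if (excluded) "excluded" else "passed"))
  candidate
}

#' Scaffold-length exclusion filter
#'
#' Candidates on scaffolds strictly shorter than `min_scaffold_length` are
#' excluded (short scaffolds are over-represented by DNA from environmental
#' sources).
#'
#' @inheritParams animal_filter
#' @return Candidate with updated status and audit.
#' @export
scaffold_length_filter <- function(candidate, assembly,
                                   params = screen_params()) {
  s <- assembly$scaffolds[[candidate$scaffold_id]]
  if (is.null(s) || is.na(s)) stop("unknown scaffold: ", candidate$scaffold_id)
  short <- nchar(s) < params$min_scaffold_length
  if (short && candidate$status == "retained")
    candidate$status <- "excluded_scaffold_length"
  candidate$audit <- c(candidate$audit,
                       sprintf("scaffold_length_filter:%s",
                               if (short) "excluded" else "passed"))
  candidate
}

#' Run the full differential-homology screen
#'
#' Bacterial-region discovery, then the animal filter, then the
#' scaffold-length filter, in that order.  Every candidate -- retained or
#' excluded -- is reported with its audit trail.  Output is sorted
#' retained-first by ascending bacterial E-value.
#'
#' @inheritParams find_bacterial_regions
#' @param animal_db Named DNA character vector (may be empty).
#' @return List of `lgt_candidate`.
#' @export
screen <- function(assembly, bacterial_db, animal_db, scheme,
                   params = screen_params()) {
  cands <- find_bacterial_regions(assembly, bacterial_db, scheme, params)
  cands <- lapply(cands, animal_filter, assembly = assembly,
                  animal_db = animal_db, scheme = scheme, params = params)
  cands <- lapply(cands, scaffold_length_filter, assembly = assembly,
                  params = params)
  retained <- vapply(cands, function(x) x$status == "retained", logical(1))
  ev <- vapply(cands, function(x) x$bacterial_best$log10_evalue, numeric(1))
  cands[order(!retained, ev)]
}

#' Tabulate screen candidates
#'
#' @param candidates List of `lgt_candidate` from [screen()].
#' @return data.frame, one row per candidate (1-based inclusive region
#'   coordinates in `start1`/`end1`; internal 0-based half-open in
#'   `start`/`end`).
#' @export
candidate_table <- function(candidates) {
  if (!length(candidates))
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), start1 = integer(), end1 = integer(),
                      bacterial_subject = character(),
                      bacterial_evalue = numeric(),
                      bacterial_log10_evalue = numeric(),
                      animal_best_evalue = numeric(),
                      animal_best_log10_evalue = numeric(),
                      status = character(),
                      audit = character(), stringsAsFactors = FALSE))
  data.frame(
    scaffold_id = vapply(candidates, `[[`, character(1), "scaffold_id"),
    start = vapply(candidates, `[[`, integer(1), "start"),
    end = vapply(candidates, `[[`, integer(1), "end"),
    start1 = vapply(candidates, function(x) x$start + 1L, integer(1)),
    end1 = vapply(candidates, `[[`, integer(1), "end"),
    bacterial_subject = vapply(candidates,
                               function(x) x$bacterial_best$subject_id,
                               character(1)),
    bacterial_evalue = vapply(candidates,
                              function(x) x$bacterial_best$evalue, numeric(1)),
    bacterial_log10_evalue = vapply(candidates,
                                    function(x) x$bacterial_best$log10_evalue,
                                    numeric(1)),
    animal_best_evalue = vapply(candidates, `[[`, numeric(1),
                                "animal_best_evalue"),
    animal_best_log10_evalue = vapply(candidates, `[[`, numeric(1),
                                      "animal_best_log10_evalue"),
    status = vapply(candidates, `[[`, character(1), "status"),
    audit = vapply(candidates, function(x) paste(x$audit, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' Write screen candidates as TSV
#' @param candidates List from [screen()].
#' @param path Output path.
#' @param meta Optional '#'-prefixed metadata lines (coordinates in the
#'   body are reported 1-based inclusive in `start1`/`end1`).
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  tab <- candidate_table(candidates)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab)) writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}
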