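# calibrated schemes shared across tests (calibration is deterministic)
NT_SCHEME <- calibrate_scoring(scoring_scheme("nucleotide"))
AA_SCHEME <- calibrate_scoring(scoring_scheme("protein"))

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent local-alignment oracle: full Smith-Waterman via Biostrings,
# same scoring scheme (gap of length k costs open + k*extend)
sw_score <- function(a, b, scheme) {
  mat <- scheme$matrix
  if (scheme$kind == "nucleotide") {
    sub <- mat[c("A", "C", "G", "T", "N"), c("A", "C", "G", "T", "N")]
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = sub, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, scoreOnly = TRUE)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = scheme$gap_open,
      gapExtension = scheme$gap_extend, scoreOnly = TRUE)
  }
  pa
}

PROT_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")

mutate_protein_test <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) chars[i] <- sample(setdiff(PROT_CHARS[1:20], chars[i]), 1L)
  paste(chars, collapse = "")
}
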