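# Independent oracles and small fixture builders used across the suite.

# Exhaustive global-alignment oracle: enumerates every alignment (monotone
# column path) explicitly and scores gap runs as open + (k - 1) * extend.
# Exponential; only for short sequences.
enum_align_score <- function(q, r, sub, gap_open, gap_extend) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  nq <- length(qc)
  nr <- length(rc)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > nq && j > nr) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= nq && j <= nr) {
      rec(i + 1, j + 1, score + sub[qc[i], rc[j]], "M")
    }
    if (i <= nq) {
      rec(i + 1, j, score - if (identical(prev, "U")) gap_extend else gap_open,
          "U")
    }
    if (j <= nr) {
      rec(i, j + 1, score - if (identical(prev, "L")) gap_extend else gap_open,
          "L")
    }
  }
  rec(1L, 1L, 0, "start")
  best
}

# library-based alignment score oracle (affine-gap convention translated:
# our gap of length k costs open + (k-1)*ext = Biostrings' (open-ext) + ext*k)
biostrings_align_score <- function(q, r, sub, gap_open, gap_extend) {
  Biostrings::pairwiseAlignment(q, r, substitutionMatrix = sub,
                                gapOpening = gap_open - gap_extend,
                                gapExtension = gap_extend,
                                type = "global", scoreOnly = TRUE)
}

# brute-force sliding 3-mer motif oracle
slide_motif_oracle <- function(sequence, third = c("A", "S", "V", "L", "C",
                                                   "T", "G")) {
  aa <- strsplit(sequence, "")[[1]]
  hits <- data.frame(variant = character(0), position = integer(0))
  if (length(aa) < 3) return(hits)
  for (p in seq_len(length(aa) - 2)) {
    if (aa[p] == "N" && aa[p + 1] == "P" && aa[p + 2] %in% third) {
      hits <- rbind(hits, data.frame(variant = paste0("NP", aa[p + 2]),
                                     position = p))
    }
  }
  hits
}

random_protein <- function(n, letters = aqpscan:::AA_LETTERS) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

all_kmers <- function(alphabet, k) {
  if (k == 1) return(alphabet)
  shorter <- all_kmers(alphabet, k - 1)
  as.vector(outer(shorter, alphabet, paste0))
}

# simple substitution matrix over a reduced alphabet
test_submat <- function(alphabet = c("A", "C", "G", "T"), match = 2,
                        mismatch = -1) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}
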