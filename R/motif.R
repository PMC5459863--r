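# Third-position letters accepted for NPA-type motifs (N-P-x). A, S, V, L, C
# and T are the variants observed in Brassicaceae aquaporins, plus G as seen
# in NIP1 loop-E motifs.
NPA_THIRD_DEFAULT <- c("A", "S", "V", "L", "C", "T", "G")

#' Scan a protein for NPA-motif variants
#'
#' Reports every occurrence of N-P-x, where x is one of the accepted
#' third-position letters, in position order. Overlapping occurrences are all
#' reported. Positions are 1-based indices of the motif's N residue.
#'
#' @param sequence Amino-acid string.
#' @param third Allowed third-position letters (default
#'   `r paste(NPA_THIRD_DEFAULT, collapse = ", ")`).
#' @return data.frame with columns `variant` (3-letter string) and `position`.
#' @export
scan_npa_candidates <- function(sequence, third = NPA_THIRD_DEFAULT) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  out <- data.frame(variant = character(0), position = integer(0))
  if (n < 3L) return(out)
  idx <- which(aa[seq_len(n - 2L)] == "N" &
                 aa[seq_len(n - 2L) + 1L] == "P" &
                 aa[seq_len(n - 2L) + 2L] %in% third)
  if (!length(idx)) return(out)
  data.frame(variant = paste0("NP", aa[idx + 2L]), position = as.integer(idx))
}

#' NPA-NPA spacing between the loop-B and loop-E motifs
#'
#' The residue count between the two motifs: `le_position - lb_position - 3`.
#' This is the convention under which the spacing of every complete reference
#' table row equals its printed distance (e.g. motifs at 114 and 233 give 116).
#'
#' @param lb_position 1-based position of the loop-B motif's N residue.
#' @param le_position 1-based position of the loop-E motif's N residue; must
#'   exceed `lb_position + 2`.
#' @return Integer residue count (>= 0).
#' @export
npa_spacing <- function(lb_position, le_position) {
  if (any(le_position <= lb_position + 2)) {
    stop("loop-E motif must start after the loop-B motif ends")
  }
  as.integer(le_position - lb_position - 3)
}

#' Select the loop-B / loop-E motif pair
#'
#' Among all ordered motif pairs whose spacing falls inside
#' `spacing_window`, returns the pair whose spacing is closest to
#' `expected_spacing` when given; otherwise the pair with the leftmost loop-B
#' motif (ties broken by smallest deviation from `expected_spacing`, then by
#' leftmost loop-E). When no pair qualifies the result is `NULL` with the
#' `needs_review` attribute set, mirroring manual-review of single- or
#' missing-motif proteins.
#'
#' @param motifs data.frame from [scan_npa_candidates()], position-sorted.
#' @param spacing_window Length-2 numeric `[min, max]` of admissible spacings
#'   (default `c(85, 150)`, spanning the observed family range).
#' @param expected_spacing Optional subfamily-expected spacing.
#' @return A list with `lb`, `le` (each `variant`, `position`) and `spacing`,
#'   or `NULL` with attribute `needs_review = TRUE`.
#' @export
select_motif_pair <- function(motifs, spacing_window = c(85, 150),
                              expected_spacing = NULL) {
  # absence is a value: NULL marks a single/missing-motif protein needing
  # manual review (callers raise the needs_review flag)
  fail <- function() NULL
  if (is.null(motifs) || nrow(motifs) < 2L) return(fail())
  pairs <- expand.grid(i = seq_len(nrow(motifs)), j = seq_len(nrow(motifs)))
  pairs <- pairs[motifs$position[pairs$j] > motifs$position[pairs$i] + 2, ,
                 drop = FALSE]
  if (!nrow(pairs)) return(fail())
  sp <- npa_spacing(motifs$position[pairs$i], motifs$position[pairs$j])
  ok <- sp >= spacing_window[1] & sp <= spacing_window[2]
  if (!any(ok)) return(fail())
  pairs <- pairs[ok, , drop = FALSE]
  sp <- sp[ok]
  if (!is.null(expected_spacing)) {
    dev <- abs(sp - expected_spacing)
    ord <- order(dev, motifs$position[pairs$i], motifs$position[pairs$j])
  } else {
    ord <- order(motifs$position[pairs$i], motifs$position[pairs$j])
  }
  k <- ord[1]
  list(lb = list(variant = motifs$variant[pairs$i[k]],
                 position = motifs$position[pairs$i[k]]),
       le = list(variant = motifs$variant[pairs$j[k]],
                 position = motifs$position[pairs$j[k]]),
       spacing = sp[k])
}
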