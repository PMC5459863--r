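#' Default protein substitution matrix (BLOSUM62)
#'
#' @return The BLOSUM62 substitution matrix shipped with Biostrings.
#' @export
default_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch with Gotoh's affine-gap extension. A gap of length `k`
#' costs `gap_open + (k - 1) * gap_extend` (positive-cost convention, negated
#' internally). Traceback ties are broken deterministically: diagonal, then
#' up (gap in reference), then left (gap in query).
#'
#' @param query,reference Amino-acid strings (non-empty).
#' @param submat Substitution matrix with single-letter dimnames (default
#'   BLOSUM62).
#' @param gap_open,gap_extend Positive gap costs (defaults 10 and 1).
#' @return List of class `alignment_result`: `score`, `aligned_query`,
#'   `aligned_ref` (gapped strings), `identity` (matching columns over
#'   alignment length).
#' @export
global_align <- function(query, reference, submat = default_submat(),
                         gap_open = 10, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(reference)) stop("sequences must be non-empty")
  res <- .gotoh_align_cpp(toupper(query), toupper(reference), submat,
                          gap_open, gap_extend)
  qa <- strsplit(res$aligned_query, "")[[1]]
  ra <- strsplit(res$aligned_ref, "")[[1]]
  res$identity <- sum(qa == ra & qa != "-") / length(qa)
  class(res) <- "alignment_result"
  res
}

#' Map reference positions through an alignment
#'
#' For each 1-based reference position, gives the 1-based query position
#' aligned to it, or `NA` when the reference residue is aligned to a gap.
#'
#' @param alignment An `alignment_result` from [global_align()].
#' @param ref_positions Integer vector of 1-based reference positions.
#' @return Integer vector of query positions (`NA` for gap-aligned).
#' @export
map_positions <- function(alignment, ref_positions) {
  qa <- strsplit(alignment$aligned_query, "")[[1]]
  ra <- strsplit(alignment$aligned_ref, "")[[1]]
  ref_idx <- cumsum(ra != "-")
  qry_idx <- cumsum(qa != "-")
  n_ref <- ref_idx[length(ref_idx)]
  if (any(ref_positions < 1 | ref_positions > n_ref)) {
    stop("reference position out of range (1..", n_ref, ")")
  }
  vapply(as.integer(ref_positions), function(p) {
    col <- match(p, ref_idx)  # first column where ref residue p appears
    if (qa[col] == "-") NA_integer_ else qry_idx[col]
  }, integer(1))
}

#' Self-alignment score of a sequence under a substitution matrix
#' @keywords internal
self_score <- function(sequence, submat = default_submat()) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  sum(submat[cbind(aa, aa)])
}
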