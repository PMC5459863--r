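#' Extract the ar/R selectivity filter through a guided alignment
#'
#' Reads off the query residues aligned to the reference's annotated H2, H5,
#' LE1, LE2 (and Loop-C) columns. Positions aligned to a gap yield the
#' undefined marker `"-"`.
#'
#' @param sequence Query amino-acid string.
#' @param ref One row of a reference profile (list or single-row data.frame).
#' @param alignment `alignment_result` aligning `sequence` against
#'   `ref$sequence`.
#' @return List with single residue letters `h2`, `h5`, `le1`, `le2`, `lc`
#'   (`lc` is `"-"` when the reference has no annotated Loop-C column).
#' @export
extract_selectivity_filter <- function(sequence, ref, alignment) {
  cols <- c(h2 = ref$h2_pos, h5 = ref$h5_pos, le1 = ref$le1_pos,
            le2 = ref$le2_pos, lc = ref$lc_pos)
  out <- lapply(cols, function(p) residue_at_mapped(sequence, alignment, p))
  stats::setNames(out, c("h2", "h5", "le1", "le2", "lc"))
}

#' Extract Froger residues through a guided alignment
#'
#' As [extract_selectivity_filter()], using the five annotated Froger
#' positions P1-P5 of the reference.
#'
#' @inheritParams extract_selectivity_filter
#' @return Character vector of length 5 (letters or `"-"`).
#' @export
extract_froger_residues <- function(sequence, ref, alignment) {
  pos <- c(ref$froger1_pos, ref$froger2_pos, ref$froger3_pos,
           ref$froger4_pos, ref$froger5_pos)
  vapply(pos, function(p) residue_at_mapped(sequence, alignment, p),
         character(1))
}

# query residue aligned to reference position p, or "-" for gaps/NA positions
residue_at_mapped <- function(sequence, alignment, p) {
  if (is.null(p) || is.na(p)) return("-")
  q <- map_positions(alignment, p)
  if (is.na(q)) "-" else substr(sequence, q, q)
}

#' Full alignment-guided feature extraction against the best reference
#'
#' Aligns a query against every reference in the profile, picks the
#' best-scoring one, and extracts the motif pair (guided by the reference's
#' expected spacing), selectivity filter and Froger residues. A
#' `low_identity` flag is set when alignment identity falls below
#' `min_identity`.
#'
#' @param sequence Query amino-acid string.
#' @param profile Reference profile data.frame.
#' @param submat,gap_open,gap_extend Alignment parameters (see
#'   [global_align()]).
#' @param spacing_window Admissible NPA-NPA spacing window for pair selection.
#' @param min_identity Extraction-quality threshold on alignment identity
#'   (default 0.3).
#' @return List: `best_ref` (name), `subfamily`, `group`, `score`,
#'   `identity`, `motif_pair` (or `NULL`), `sf`, `froger`, `flags`
#'   (character vector of codes).
#' @export
extract_features <- function(sequence, profile,
                             submat = default_submat(), gap_open = 10,
                             gap_extend = 1, spacing_window = c(85, 150),
                             min_identity = 0.3) {
  validate_reference_profile(profile)
  scores <- numeric(nrow(profile))
  alns <- vector("list", nrow(profile))
  for (k in seq_len(nrow(profile))) {
    alns[[k]] <- global_align(sequence, profile$sequence[k], submat,
                              gap_open, gap_extend)
    scores[k] <- alns[[k]]$score
  }
  idents <- vapply(alns, `[[`, numeric(1), "identity")
  # best score; ties by identity then reference name order
  ord <- order(-scores, -idents, profile$name)
  best <- ord[1]
  ref <- as.list(profile[best, ])
  aln <- alns[[best]]

  motifs <- scan_npa_candidates(sequence)
  expected <- npa_spacing(ref$lb_pos, ref$le_pos)
  pair <- select_motif_pair(motifs, spacing_window, expected_spacing = expected)

  flags <- character(0)
  if (is.null(pair)) flags <- c(flags, "needs_review")
  if (aln$identity < min_identity) flags <- c(flags, "low_identity")

  list(best_ref = ref$name, subfamily = ref$subfamily, group = ref$group,
       score = aln$score, identity = aln$identity, alignment = aln,
       motif_pair = pair,
       sf = extract_selectivity_filter(sequence, ref, aln),
       froger = extract_froger_residues(sequence, ref, aln),
       flags = flags)
}
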