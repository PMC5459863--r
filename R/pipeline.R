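#' Annotate a candidate proteome end to end
#'
#' Runs the full characterization pipeline: per-protein transmembrane and
#' motif features, screening, best-reference classification,
#' alignment-guided feature extraction, genome/nomenclature assignment and
#' rule-based specificity prediction.
#'
#' @param proteins Named character vector or AAStringSet of candidate
#'   protein sequences.
#' @param profile Annotated reference profile (see
#'   [validate_reference_profile()]).
#' @param gene_models Optional named list of `gene_model` objects.
#' @param progenitor_profile Optional progenitor reference profile with a
#'   `genome` column, used to place scaffold-only genes.
#' @param config Pipeline configuration (see [default_config()]).
#' @return List: `annotations` (data.frame, one row per kept protein),
#'   `screen` (filter report for every input).
#' @export
annotate_proteome <- function(proteins, profile, gene_models = list(),
                              progenitor_profile = NULL,
                              config = default_config()) {
  proteins <- as_protein_set(proteins)
  validate_config(config)
  sc <- config$screening
  screen <- screen_candidates(proteins,
                              min_length = sc$min_length,
                              max_length = sc$max_length,
                              min_tm = sc$min_tm,
                              min_motifs = sc$min_motifs)
  kept <- screen$id[screen$kept]
  submat <- default_submat()
  al <- config$alignment

  rows <- lapply(kept, function(id) {
    s <- proteins[[id]]
    fx <- extract_features(s, profile, submat, al$gap_open, al$gap_extend,
                           spacing_window = config$motif$spacing_window,
                           min_identity = config$classification$min_identity)
    thr <- config$classification$score_frac *
      self_score(profile$sequence[profile$name == fx$best_ref], submat)
    classified <- fx$score >= thr
    flags <- fx$flags
    if (!classified) flags <- c(flags, "unclassified")
    pair <- fx$motif_pair
    tm <- suppressWarnings(predict_tm_segments(
      s, window = config$tm$window, threshold = config$tm$threshold,
      min_len = config$tm$min_len, merge_gap = config$tm$merge_gap))
    spacing <- if (is.null(pair)) NA_integer_ else pair$spacing
    spec_pred <- predict_specificity(fx$sf, spacing)
    data.frame(
      gene_id = id,
      name = NA_character_,
      subfamily = if (classified) fx$subfamily else NA_character_,
      group = if (classified) fx$group else NA_character_,
      genome = NA_character_, chromosome = NA_character_,
      length = nchar(s), tm_count = nrow(tm),
      lb_variant = if (is.null(pair)) NA_character_ else pair$lb$variant,
      lb_pos = if (is.null(pair)) NA_integer_ else pair$lb$position,
      le_variant = if (is.null(pair)) NA_character_ else pair$le$variant,
      le_pos = if (is.null(pair)) NA_integer_ else pair$le$position,
      spacing = spacing,
      h2 = fx$sf$h2, h5 = fx$sf$h5, le1 = fx$sf$le1, le2 = fx$sf$le2,
      lc = fx$sf$lc, froger = paste(fx$froger, collapse = ""),
      best_ref = fx$best_ref, score = fx$score, identity = fx$identity,
      substrates = paste(spec_pred$substrate[spec_pred$tier == 1],
                         collapse = ","),
      flags = paste(flags, collapse = ","))
  })
  annotations <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(annotations) && length(gene_models)) {
    annotations <- assign_genome_and_name(
      annotations, gene_models, progenitor_profile, proteins,
      prefix = config$naming$prefix)
  }
  list(annotations = annotations, screen = screen)
}
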