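#' Default pipeline configuration
#'
#' Nested list of every tunable threshold: screening (length window, minimum
#' transmembrane segments and motifs), transmembrane scanner (window,
#' hydropathy threshold, minimum length, merge gap), motif-pair spacing
#' window, alignment gap costs, classification score fraction and identity
#' floor, expression thresholds (expressed > 2 RPKM, |log2 fold change| > 2
#' with mean >= 2 RPKM and pseudo-count 1, dosage p < 0.01, co-expression
#' percentile ranks 5/95) and the naming prefix.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    screening = list(min_length = 150, max_length = 450, min_tm = 5,
                     min_motifs = 1),
    tm = list(window = 19, threshold = 1.6, min_len = 15, merge_gap = 3),
    motif = list(spacing_window = c(85, 150)),
    alignment = list(gap_open = 10, gap_extend = 1),
    classification = list(score_frac = 0.4, min_identity = 0.3),
    expression = list(expressed_rpkm = 2, deg_log2fc = 2, deg_min_mean = 2,
                      deg_pseudo = 1, dosage_alpha = 0.01,
                      coexpr_lower_pct = 5, coexpr_upper_pct = 95),
    naming = list(prefix = "Bna")
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys at either nesting level and checks each threshold's
#' documented range.
#'
#' @param config Nested configuration list.
#' @return `config`, invisibly; errors list every violation.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  problems <- character(0)
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) {
    problems <- c(problems, paste0("unknown section(s): ",
                                   paste(extra, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(ref))) {
    extra_k <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(extra_k)) {
      problems <- c(problems, paste0("unknown key(s) in ", sec, ": ",
                                     paste(extra_k, collapse = ", ")))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  s <- config$screening
  if (!is.null(s)) {
    chk(s$min_length >= 0 && s$min_length <= s$max_length,
        "screening: need 0 <= min_length <= max_length")
    chk(s$min_tm >= 0, "screening: min_tm must be >= 0")
  }
  tm <- config$tm
  if (!is.null(tm)) {
    chk(tm$window %% 2 == 1 && tm$window >= 3, "tm: window must be odd >= 3")
    chk(tm$min_len >= 1, "tm: min_len must be >= 1")
  }
  cl <- config$classification
  if (!is.null(cl)) {
    chk(cl$score_frac > 0 && cl$score_frac <= 1,
        "classification: score_frac must lie in (0, 1]")
  }
  ex <- config$expression
  if (!is.null(ex)) {
    chk(ex$dosage_alpha > 0 && ex$dosage_alpha < 1,
        "expression: dosage_alpha must lie in (0, 1)")
    chk(ex$coexpr_lower_pct >= 0 && ex$coexpr_upper_pct <= 100 &&
          ex$coexpr_lower_pct <= ex$coexpr_upper_pct,
        "expression: percentile ranks must satisfy 0 <= lower <= upper <= 100")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(config)
}

#' Load a YAML configuration file over the defaults
#'
#' Values in the file override the defaults; unknown keys are rejected.
#'
#' @param path YAML file path (optional; `NULL` gives the defaults).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in names(user)) {
      if (!sec %in% names(config)) {
        config[[sec]] <- user[[sec]]  # let validate_config name the offender
        next
      }
      for (k in names(user[[sec]])) config[[sec]][[k]] <- user[[sec]][[k]]
    }
  }
  validate_config(config)
  config
}
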