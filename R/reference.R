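REFPROFILE_COLS <- c("name", "subfamily", "group", "sequence",
                     "lb_pos", "le_pos", "h2_pos", "h5_pos", "le1_pos",
                     "le2_pos", "lc_pos", "froger1_pos", "froger2_pos",
                     "froger3_pos", "froger4_pos", "froger5_pos")

#' Validate a reference profile of annotated aquaporins
#'
#' A reference profile anchors alignment-guided feature extraction and
#' classification: one or more annotated sequences with known subfamily,
#' group and 1-based feature-column positions (loop-B/loop-E motifs, ar/R
#' selectivity filter H2/H5/LE1/LE2, Loop-C residue, Froger positions P1-P5).
#'
#' @param profile data.frame with columns
#'   `r paste(REFPROFILE_COLS, collapse = ", ")`.
#' @return The validated profile (invisibly usable), with an error describing
#'   every violation otherwise.
#' @export
validate_reference_profile <- function(profile) {
  missing_cols <- setdiff(REFPROFILE_COLS, names(profile))
  if (length(missing_cols)) {
    stop("reference profile missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(profile) == 0L) stop("reference profile is empty")
  if (anyDuplicated(profile$name)) stop("reference names must be unique")
  pos_cols <- grep("_pos$", REFPROFILE_COLS, value = TRUE)
  problems <- character(0)
  for (k in seq_len(nrow(profile))) {
    len <- nchar(profile$sequence[k])
    pos <- unlist(profile[k, pos_cols])
    out_of_range <- pos_cols[!is.na(pos) & (pos < 1 | pos > len)]
    if (length(out_of_range)) {
      problems <- c(problems, paste0(profile$name[k], ": position(s) out of range: ",
                                     paste(out_of_range, collapse = ", ")))
    }
    for (mp in c("lb_pos", "le_pos")) {
      p <- profile[[mp]][k]
      if (!is.na(p) && p + 2 <= len) {
        tri <- substr(profile$sequence[k], p, p + 2)
        if (!grepl("^NP", tri)) {
          problems <- c(problems,
                        paste0(profile$name[k], ": ", mp, " does not carry an N-P-x triplet (", tri, ")"))
        }
      }
    }
  }
  if (length(problems)) {
    stop("invalid reference profile:\n  ", paste(problems, collapse = "\n  "))
  }
  profile
}

#' Read / write a reference profile TSV
#'
#' @param path TSV path with the reference-profile columns.
#' @return data.frame (validated).
#' @export
read_reference_profile <- function(path) {
  prof <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_reference_profile(prof)
}

#' @rdname read_reference_profile
#' @param profile Reference profile data.frame.
#' @export
write_reference_profile <- function(profile, path) {
  validate_reference_profile(profile)
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
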