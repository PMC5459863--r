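#' Read a protein FASTA file
#'
#' Reads a multi-record protein FASTA into an [Biostrings::AAStringSet].
#' Sequences are uppercased and trailing `*` stop characters are stripped.
#' Only the 20 canonical amino-acid letters plus `X` are accepted; any other
#' residue raises an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet]; empty (with a warning) for an empty
#'   file. Record ids are the FASTA header words up to the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(set)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  bad <- grepl(paste0("[^", AA_ALPHABET_RE, "]"), seqs)
  if (any(bad)) {
    stop("illegal residue character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein records to FASTA
#'
#' @param x A named character vector of sequences or an
#'   [Biostrings::AAStringSet].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x <- Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

# 20 canonical residues plus X; used by readers and validators
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_RE <- paste0(paste(AA_LETTERS, collapse = ""), "X")

#' Coerce protein input to a named character vector of sequences
#' @param x AAStringSet or named character vector.
#' @return Named character vector, validated against the accepted alphabet.
#' @keywords internal
as_protein_set <- function(x) {
  if (methods::is(x, "AAStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected an AAStringSet or a named character vector of sequences")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("protein sequences must be named")
  }
  if (anyDuplicated(names(out))) stop("protein ids must be unique")
  bad <- grepl(paste0("[^", AA_ALPHABET_RE, "]"), out) | !nzchar(out)
  if (any(bad)) {
    stop("invalid sequence(s): ", paste(names(out)[bad], collapse = ", "))
  }
  out
}
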