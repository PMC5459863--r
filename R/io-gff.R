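#' Read gene models from a GFF3 file
#'
#' Imports exon features and groups them by their `Parent` attribute (falling
#' back to `ID`/`gene_id` when no Parent is present). Exons are stored as
#' 1-based inclusive intervals, sorted by start.
#'
#' @param path Path to a GFF3 file.
#' @return A list of gene models; each element is a list with `gene_id`,
#'   `chromosome`, `strand` and `exons` (a two-column matrix `start`, `end`).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) return(list())
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))
  if (anyNA(parent) && !is.null(gr$ID)) {
    parent[is.na(parent)] <- as.character(gr$ID)[is.na(parent)]
  }
  # strip a trailing transcript suffix like ".1" / "-mRNA-1" down to the gene id
  gene <- sub("\\.(t?\\d+)$", "", parent)
  split_idx <- split(seq_along(gr), gene)
  lapply(names(split_idx), function(g) {
    idx <- split_idx[[g]]
    sub_gr <- gr[idx]
    ex <- cbind(start = GenomicRanges::start(sub_gr), end = GenomicRanges::end(sub_gr))
    ex <- ex[order(ex[, "start"]), , drop = FALSE]
    gene_model(g, as.character(GenomicRanges::seqnames(sub_gr))[1],
               as.character(GenomicRanges::strand(sub_gr))[1], ex)
  }) |> stats::setNames(names(split_idx))
}

#' Construct a validated gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome or scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of 1-based inclusive `start`, `end`
#'   intervals, non-overlapping and sorted by start.
#' @return A list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene model '", gene_id, "' has zero exons")
  if (any(exons[, "end"] < exons[, "start"])) {
    stop("gene model '", gene_id, "': exon end < start")
  }
  if (is.unsorted(exons[, "start"], strictly = FALSE)) {
    stop("gene model '", gene_id, "': exons not sorted by start")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"])) {
    stop("gene model '", gene_id, "': overlapping exons")
  }
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 strand = strand, exons = exons),
            class = "gene_model")
}

#' Count introns in a gene model
#'
#' The intron count of a gene model is its exon count minus one.
#'
#' @param model A `gene_model` (see [gene_model()]).
#' @return Non-negative integer intron count.
#' @export
count_introns <- function(model) {
  if (is.null(model$exons) || nrow(model$exons) == 0L) {
    stop("invalid gene model: zero exons")
  }
  nrow(model$exons) - 1L
}
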