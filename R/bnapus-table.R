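#' Load the packaged B. napus aquaporin feature table
#'
#' The 120-row reference feature table for Brassica napus aquaporins:
#' gene id, assigned name, loop-B and loop-E motif variants with 1-based
#' positions of the motif's N residue, the four ar/R selectivity-filter
#' residues (H2, H5, LE1, LE2) and the printed NPA-NPA distance. Rows whose
#' motifs required manual curation are flagged `manual_star`; the one row
#' with incomplete motifs is flagged `partial` and carries no distance.
#'
#' @return data.frame with one row per gene.
#' @export
load_bnapus_table <- function() {
  path <- system.file("extdata", "bnapus_aqp_features.tsv", package = "aqpscan",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(lb_pos = "integer",
                                          le_pos = "integer",
                                          distance = "integer"))
  tab$genome <- ifelse(grepl("^Bna[AC]nn", tab$gene_id),
                       paste0(substr(tab$gene_id, 4, 4), "_random"),
                       substr(tab$gene_id, 4, 4))
  tab$group <- sub("^Bna[AC]([A-Z]+[0-9]+).*$", "\\1", tab$name)
  tab$subfamily <- sub("[0-9]+$", "", tab$group)
  tab
}

#' Validate the packaged feature-table fixture
#'
#' Asserts the spacing identity (`distance = le_pos - lb_pos - 3`) on every
#' complete row and reports partial rows as exempt.
#'
#' @param table Feature table (default: [load_bnapus_table()]).
#' @return List: `ok` (logical), `violations` (data.frame naming offending
#'   rows), `exempt` (names of partial rows checked against nothing).
#' @export
validate_bnapus_fixture <- function(table = load_bnapus_table()) {
  complete <- !table$partial
  expected <- npa_spacing(table$lb_pos[complete], table$le_pos[complete])
  bad <- which(expected != table$distance[complete])
  violations <- data.frame(name = table$name[complete][bad],
                           expected = expected[bad],
                           printed = table$distance[complete][bad])
  list(ok = nrow(violations) == 0L, violations = violations,
       exempt = table$name[!complete])
}
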