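#' Screen candidate proteins for aquaporin-like structure
#'
#' Deterministic pass/fail filter mirroring the exclusion of aquaporin-like
#' proteins on length, transmembrane-domain and motif grounds. A record is
#' kept iff its reason list is empty.
#'
#' @param proteins Named character vector (or AAStringSet) of sequences.
#' @param tm_counts Named integer vector: predicted TM-segment count per id
#'   (computed with [predict_tm_segments()] when `NULL`).
#' @param motif_counts Named integer vector: NPA-variant motif count per id
#'   (computed with [scan_npa_candidates()] when `NULL`).
#' @param min_length,max_length Admissible protein length (defaults 150, 450).
#' @param min_tm Minimum TM segments (default 5; 6 expected, 5 tolerates
#'   prediction error).
#' @param min_motifs Minimum NPA-variant motifs (default 1).
#' @return data.frame with `id`, `kept`, `reasons` (comma-joined codes among
#'   `too_short`, `too_long`, `missing_tm`, `missing_motif`).
#' @export
screen_candidates <- function(proteins, tm_counts = NULL, motif_counts = NULL,
                              min_length = 150, max_length = 450,
                              min_tm = 5, min_motifs = 1) {
  proteins <- as_protein_set(proteins)
  ids <- names(proteins)
  if (is.null(tm_counts)) {
    tm_counts <- vapply(proteins, function(s)
      nrow(suppressWarnings(predict_tm_segments(s))), integer(1))
  }
  if (is.null(motif_counts)) {
    motif_counts <- vapply(proteins, function(s)
      nrow(scan_npa_candidates(s)), integer(1))
  }
  reasons <- lapply(ids, function(id) {
    len <- nchar(proteins[[id]])
    r <- character(0)
    if (len < min_length) r <- c(r, "too_short")
    if (len > max_length) r <- c(r, "too_long")
    if (tm_counts[[id]] < min_tm) r <- c(r, "missing_tm")
    if (motif_counts[[id]] < min_motifs) r <- c(r, "missing_motif")
    r
  })
  data.frame(id = ids,
             kept = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, character(1), collapse = ","),
             row.names = NULL)
}

#' Classify a protein into subfamily and group by reference similarity
#'
#' Scores the query against every reference with [global_align()] and adopts
#' the best reference's subfamily and group. Ties are broken by identity,
#' then reference name order. A query whose best score falls below
#' `score_frac` of the best reference's self-alignment score is reported
#' unclassified.
#'
#' @param sequence Query amino-acid string.
#' @param profile Reference profile data.frame (non-empty).
#' @param score_frac Classification threshold as a fraction of the best
#'   reference's self-score (default 0.4).
#' @inheritParams extract_features
#' @return List: `subfamily`, `group`, `best_ref`, `score`, `identity`,
#'   `classified` (logical).
#' @export
classify_subfamily <- function(sequence, profile, score_frac = 0.4,
                               submat = default_submat(), gap_open = 10,
                               gap_extend = 1) {
  if (is.null(profile) || nrow(profile) == 0L) {
    stop("empty reference profile")
  }
  scores <- idents <- numeric(nrow(profile))
  for (k in seq_len(nrow(profile))) {
    a <- global_align(sequence, profile$sequence[k], submat, gap_open,
                      gap_extend)
    scores[k] <- a$score
    idents[k] <- a$identity
  }
  ord <- order(-scores, -idents, profile$name)
  best <- ord[1]
  threshold <- score_frac * self_score(profile$sequence[best], submat)
  classified <- scores[best] >= threshold
  list(subfamily = if (classified) profile$subfamily[best] else NA_character_,
       group = if (classified) profile$group[best] else NA_character_,
       best_ref = profile$name[best], score = scores[best],
       identity = idents[best], classified = classified)
}

#' Assign genome labels and gene-family names
#'
#' Genome letters come from the chromosome prefix of each gene's model (e.g.
#' `A03` or `chrA03` give genome `A`). Genes on unanchored scaffolds take the
#' genome of their best-scoring progenitor reference with suffix `_random`.
#' Paralog letters a, b, c, ... are assigned within (genome, group) sets
#' ordered by chromosome then start coordinate (scaffold genes last, ordered
#' by gene id), and names are assembled as
#' `<prefix><genome letter><group>-<homolog><paralog letter>`.
#'
#' @param annotations data.frame with at least `gene_id` and `group`
#'   (classification output; one row per gene).
#' @param gene_models Named list of `gene_model` objects (may omit genes).
#' @param progenitor_profile Optional reference profile whose `genome` column
#'   labels each progenitor reference `A` or `C`; used with `sequences` to
#'   place scaffold-only genes.
#' @param sequences Named character vector of gene protein sequences (needed
#'   only for scaffold genes).
#' @param prefix Species prefix for assembled names (default `"Bna"`).
#' @param homolog Homolog number used in names (default `1`).
#' @return `annotations` with added/updated `genome`, `chromosome`, `name`.
#' @export
assign_genome_and_name <- function(annotations, gene_models = list(),
                                   progenitor_profile = NULL,
                                   sequences = NULL, prefix = "Bna",
                                   homolog = 1) {
  n <- nrow(annotations)
  chrom <- vapply(annotations$gene_id, function(g) {
    m <- gene_models[[g]]
    if (is.null(m)) NA_character_ else m$chromosome
  }, character(1))
  chrom_clean <- sub("^chr", "", chrom, ignore.case = TRUE)
  anchored <- !is.na(chrom_clean) & grepl("^[AC][0-9]{2}$", chrom_clean)
  genome <- rep(NA_character_, n)
  genome[anchored] <- substr(chrom_clean[anchored], 1, 1)
  start <- vapply(annotations$gene_id, function(g) {
    m <- gene_models[[g]]
    if (is.null(m)) NA_integer_ else as.integer(m$exons[1, "start"])
  }, integer(1))

  unanchored <- which(!anchored)
  if (length(unanchored)) {
    if (is.null(progenitor_profile) || is.null(sequences)) {
      genome[unanchored] <- "unassigned"
    } else {
      stopifnot(!is.null(progenitor_profile$genome))
      for (i in unanchored) {
        seq_i <- sequences[[annotations$gene_id[i]]]
        scores <- vapply(progenitor_profile$sequence, function(ref)
          global_align(seq_i, ref)$score, numeric(1))
        best <- order(-scores, progenitor_profile$name)[1]
        genome[i] <- paste0(progenitor_profile$genome[best], "_random")
      }
    }
  }

  annotations$genome <- genome
  annotations$chromosome <- chrom_clean
  base_genome <- sub("_random$", "", genome)

  # paralog letters within (genome letter, group): anchored genes first by
  # chromosome then start; scaffold genes after, by gene id (stable tie-break)
  annotations$name <- NA_character_
  key <- paste(base_genome, annotations$group, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k & !is.na(annotations$group))
    if (!length(idx)) next
    ord <- order(!anchored[idx],
                 ifelse(is.na(chrom_clean[idx]), "zzz", chrom_clean[idx]),
                 ifelse(is.na(start[idx]), .Machine$integer.max, start[idx]),
                 annotations$gene_id[idx])
    idx <- idx[ord]
    annotations$name[idx] <- paste0(prefix, base_genome[idx],
                                    annotations$group[idx], "-", homolog,
                                    letters[seq_along(idx)])
  }
  annotations
}

#' Predict substrate specificity from the selectivity filter and spacing
#'
#' Rule-table lookup over the ar/R selectivity filter (H2, H5, LE1, LE2) and
#' the NPA-NPA spacing. Rules are data, not code: each row of the rules table
#' gives allowed letters per filter position (pipe-separated, `*` wildcard),
#' a required spacing (`*` for any) and a (substrate, tier) pair. Undefined
#' filter residues (`-`) lower the confidence tier by one. The packaged
#' default rules predict water for the F-H-T-R filter, water/urea/peroxide
#' tiers for tonoplast-type filters, glycerol for NIP-I (W-[VI]-A-R), boric
#' acid/urea for NIP-II (A-[IV]-[GA]-R), and silicic acid only for the
#' G-S-G-R filter at exactly 108-residue spacing.
#'
#' @param sf List or vector with `h2`, `h5`, `le1`, `le2` residue letters.
#' @param spacing NPA-NPA spacing (integer or `NA`).
#' @param rules Rules data.frame (default: packaged
#'   `specificity_rules.tsv`).
#' @return data.frame with `substrate` and `tier` (1 = primary evidence
#'   class); zero rows when nothing matches.
#' @export
predict_specificity <- function(sf, spacing = NA,
                                rules = default_specificity_rules()) {
  sf <- as.list(sf)
  letters4 <- toupper(c(sf$h2, sf$h5, sf$le1, sf$le2))
  any_undefined <- any(letters4 == "-")
  hits <- logical(nrow(rules))
  for (k in seq_len(nrow(rules))) {
    allowed <- strsplit(unlist(rules[k, c("h2", "h5", "le1", "le2")]), "|",
                        fixed = TRUE)
    pos_ok <- mapply(function(res, opts) {
      "*" %in% opts || res %in% opts
    }, letters4, allowed)
    sp_ok <- rules$spacing[k] == "*" ||
      (!is.na(spacing) && as.integer(rules$spacing[k]) == spacing)
    hits[k] <- all(pos_ok) && sp_ok
  }
  out <- rules[hits, c("substrate", "tier"), drop = FALSE]
  out$tier <- as.integer(out$tier) + if (any_undefined) 1L else 0L
  out <- out[!duplicated(out$substrate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname predict_specificity
#' @export
default_specificity_rules <- function() {
  utils::read.delim(system.file("extdata", "specificity_rules.tsv",
                                package = "aqpscan", mustWork = TRUE),
                    colClasses = "character")
}

#' Assemble the annotation feature table
#'
#' Tabular report mirroring the reference feature-table column order (gene
#' id, name, loop-B and loop-E motifs with positions, H2/H5/LE1/LE2, NPA-NPA
#' distance) with appended Loop-C, Froger, specificity and flag columns.
#' Rows are deterministically ordered by genome, subfamily, group, name.
#'
#' @param annotations Annotation data.frame (see [annotate_proteome()]).
#' @param path Optional TSV output path.
#' @return The ordered table (invisibly when `path` is given).
#' @export
build_feature_table <- function(annotations, path = NULL) {
  cols <- c("gene_id", "name", "npa_lb", "npa_le", "h2", "h5", "le1", "le2",
            "distance", "lc", "froger", "substrates", "flags")
  if (nrow(annotations) == 0L) {
    tab <- stats::setNames(data.frame(matrix(character(0), ncol = length(cols))), cols)
  } else {
    fmt_motif <- function(v, p) ifelse(is.na(p) | is.na(v), "-",
                                       paste0(v, "(", p, ")"))
    tab <- data.frame(
      gene_id = annotations$gene_id,
      name = annotations$name,
      npa_lb = fmt_motif(annotations$lb_variant, annotations$lb_pos),
      npa_le = fmt_motif(annotations$le_variant, annotations$le_pos),
      h2 = annotations$h2, h5 = annotations$h5,
      le1 = annotations$le1, le2 = annotations$le2,
      distance = annotations$spacing,
      lc = annotations$lc,
      froger = annotations$froger,
      substrates = annotations$substrates,
      flags = annotations$flags)
    ord <- order(annotations$genome, annotations$subfamily,
                 annotations$group, annotations$name)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Neighbor-joining tree over annotated sequences
#'
#' Quality-control tree from pairwise distances 1 - fractional identity
#' (identity from [global_align()]), agglomerated with neighbor joining.
#' Negative branch lengths are clipped at zero. The tree is unrooted; ties
#' are resolved by taxon order (input order).
#'
#' @param sequences Named character vector of >= 3 sequences.
#' @inheritParams extract_features
#' @return Newick text (terminated by a semicolon).
#' @export
neighbor_joining_tree <- function(sequences, submat = default_submat(),
                                  gap_open = 10, gap_extend = 1) {
  sequences <- as_protein_set(sequences)
  n <- length(sequences)
  if (n < 3L) stop("neighbor joining needs at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- global_align(sequences[[i]], sequences[[j]], submat, gap_open,
                        gap_extend)
      d[i, j] <- d[j, i] <- 1 - a$identity
    }
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}
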