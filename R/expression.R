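#' RPKM normalization
#'
#' Reads per kilobase of exon per million mapped fragments:
#' `1e9 * count / (length_bp * sample_total)`. Sample totals default to the
#' matrix column sums; pass the true library sizes via `totals` when the
#' matrix covers only a gene subset.
#'
#' @param counts Numeric genes x samples matrix of raw read counts.
#' @param lengths_bp Named (or positionally matched) vector of gene exon
#'   lengths in bp, all > 0.
#' @param totals Optional per-sample mapped-fragment totals (> 0); defaults
#'   to `colSums(counts)`.
#' @return Matrix of RPKM values with the input dimnames.
#' @export
rpkm_normalize <- function(counts, lengths_bp, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  if (length(lengths_bp) != nrow(counts)) {
    stop("need one gene length per matrix row")
  }
  if (any(is.na(lengths_bp)) || any(lengths_bp <= 0)) {
    stop("gene lengths must be positive")
  }
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("zero library total in sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(sweep(counts, 1, lengths_bp / 1e3, "/"), 2, totals / 1e6, "/")
}

#' Partition genes into expressed / not expressed
#'
#' A gene is expressed iff its maximum over samples strictly exceeds
#' `threshold` (default 2 RPKM in at least one library).
#'
#' @param rpkm Numeric genes x samples RPKM matrix.
#' @param threshold Strict threshold (default 2).
#' @return Logical vector named by gene: `TRUE` = expressed.
#' @export
expressed_filter <- function(rpkm, threshold = 2) {
  apply(as.matrix(rpkm), 1, function(x) max(x) > threshold)
}

#' Threshold-rule differential expression calls
#'
#' For a (treatment, control) condition pair, computes per-gene condition
#' means of RPKM, `log2fc = log2((mean_t + pseudo) / (mean_c + pseudo))`, and
#' calls a DEG iff `|log2fc| > lfc_cutoff` and the larger condition mean is
#' at least `min_mean` RPKM.
#'
#' @param rpkm Genes x samples RPKM matrix.
#' @param design data.frame with `sample` and a condition column.
#' @param conditions Length-2 character: `c(treatment, control)`.
#' @param condition_col Name of the design column holding condition labels
#'   (default `"condition"`).
#' @param lfc_cutoff Strict cutoff on `|log2fc|` (default 2).
#' @param min_mean Non-strict minimum on `max(mean_t, mean_c)` (default 2).
#' @param pseudo Pseudo-count guarding zeros (default 1).
#' @return data.frame: `gene`, `mean_treatment`, `mean_control`, `log2fc`,
#'   `is_deg`, `direction` (`up`/`down`/`none`).
#' @export
call_degs <- function(rpkm, design, conditions, condition_col = "condition",
                      lfc_cutoff = 2, min_mean = 2, pseudo = 1) {
  rpkm <- as.matrix(rpkm)
  if (!condition_col %in% names(design)) {
    stop("design lacks column '", condition_col, "'")
  }
  labels <- design[[condition_col]]
  if (!all(conditions %in% labels)) {
    stop("unknown condition label(s): ",
         paste(setdiff(conditions, labels), collapse = ", "))
  }
  st <- design$sample[labels == conditions[1]]
  sc <- design$sample[labels == conditions[2]]
  mt <- rowMeans(rpkm[, st, drop = FALSE])
  mc <- rowMeans(rpkm[, sc, drop = FALSE])
  lfc <- log2((mt + pseudo) / (mc + pseudo))
  deg <- abs(lfc) > lfc_cutoff & pmax(mt, mc) >= min_mean
  data.frame(gene = rownames(rpkm), mean_treatment = mt, mean_control = mc,
             log2fc = lfc, is_deg = deg,
             direction = ifelse(!deg, "none", ifelse(lfc > 0, "up", "down")),
             row.names = NULL)
}

#' Pearson correlation with a t-distributed p-value
#'
#' Product-moment correlation; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (two-sided). Zero variance in either vector yields `NA` with the
#' `undefined` flag.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List: `r`, `p`, `n`, `undefined`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n, undefined = FALSE)
}

#' Percentile-thresholded co-expression network
#'
#' For each bait gene, correlates its expression with every other gene and
#' keeps the edges whose Pearson r falls at or below the `lower_pct`-th or at
#' or above the `upper_pct`-th percentile of that bait's own correlation
#' distribution (the per-bait null). Percentiles use the linear-interpolation
#' convention (`stats::quantile` type 7), recorded in the output. Baits with
#' zero variance are flagged degenerate and contribute no edges.
#'
#' @param rpkm Genes x samples RPKM matrix (>= 3 samples).
#' @param baits Character vector of bait gene ids (subset of rownames).
#' @param lower_pct,upper_pct Percentile ranks (defaults 5 and 95).
#' @param null Per-bait (default) or global percentile null.
#' @return List of class `coexpression_network`: `edges` (data.frame `bait`,
#'   `target`, `r`, `sign`), `thresholds` (per bait), `degenerate` (bait ids),
#'   `percentile_convention`.
#' @export
coexpression_network <- function(rpkm, baits, lower_pct = 5, upper_pct = 95,
                                 null = c("per_bait", "global")) {
  null <- match.arg(null)
  rpkm <- as.matrix(rpkm)
  if (ncol(rpkm) < 3) stop("need at least 3 samples")
  if (!all(baits %in% rownames(rpkm))) {
    stop("bait(s) absent from matrix: ",
         paste(setdiff(baits, rownames(rpkm)), collapse = ", "))
  }
  gene_sd <- apply(rpkm, 1, stats::sd)
  edges <- list()
  thresholds <- list()
  degenerate <- character(0)
  all_r <- NULL
  if (null == "global") {
    ok_b <- baits[gene_sd[baits] > 0]
    all_r <- unlist(lapply(ok_b, function(b) {
      targets <- setdiff(rownames(rpkm)[gene_sd > 0], b)
      as.numeric(stats::cor(rpkm[b, ], t(rpkm[targets, , drop = FALSE])))
    }))
  }
  for (b in baits) {
    if (gene_sd[b] == 0) {
      degenerate <- c(degenerate, b)
      next
    }
    targets <- setdiff(rownames(rpkm)[gene_sd > 0], b)
    r <- as.numeric(stats::cor(rpkm[b, ], t(rpkm[targets, , drop = FALSE])))
    null_r <- if (null == "per_bait") r else all_r
    q <- stats::quantile(null_r, c(lower_pct, upper_pct) / 100, type = 7,
                         names = FALSE)
    keep <- r <= q[1] | r >= q[2]
    thresholds[[b]] <- c(lower = q[1], upper = q[2])
    if (any(keep)) {
      edges[[b]] <- data.frame(bait = b, target = targets[keep],
                               r = r[keep],
                               sign = ifelse(r[keep] >= 0, "positive",
                                             "negative"))
    }
  }
  structure(list(
    edges = if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
            else data.frame(bait = character(0), target = character(0),
                            r = numeric(0), sign = character(0)),
    thresholds = thresholds, degenerate = degenerate,
    percentile_convention = "linear interpolation (quantile type 7)",
    null = null), class = "coexpression_network")
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Clusters genes with distance `1 - r` (Pearson) and average linkage.
#' Genes with undefined correlations (zero variance) are excluded and
#' listed in the `excluded` attribute.
#'
#' @param rpkm Genes x samples RPKM matrix (>= 2 usable genes).
#' @return An [stats::hclust] object with attribute `excluded`.
#' @export
hierarchical_cluster <- function(rpkm) {
  rpkm <- as.matrix(rpkm)
  usable <- apply(rpkm, 1, stats::sd) > 0
  excluded <- rownames(rpkm)[!usable]
  m <- rpkm[usable, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 genes with defined correlations")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  attr(hc, "excluded") <- excluded
  hc
}

#' Genome-dosage dependency of expression
#'
#' Correlates each gene's expression with the per-sample progenitor-genome
#' fraction (`a_fraction` in the design; e.g. genotypes AA, CC, AC, AAC,
#' CCA, CCAA have A-genome fractions 1, 0, 0.5, 0.66, 0.33, 0.5). A gene is
#' dosage-dependent iff the two-sided t-test p-value (df = n - 2) is below
#' `alpha` and r is positive. Replicates are treated as independent samples.
#'
#' @param rpkm Genes x samples RPKM matrix (>= 4 samples).
#' @param design data.frame with `sample` and `a_fraction` columns.
#' @param alpha Significance cutoff (default 0.01).
#' @return data.frame: `gene`, `r`, `p`, `dosage_dependent`, `undefined`.
#' @export
dosage_correlation <- function(rpkm, design, alpha = 0.01) {
  rpkm <- as.matrix(rpkm)
  if (is.null(design$a_fraction) || anyNA(design$a_fraction)) {
    stop("design must define a_fraction for every sample")
  }
  a <- design$a_fraction[match(colnames(rpkm), design$sample)]
  if (anyNA(a)) stop("design lacks a_fraction for some matrix samples")
  if (length(a) < 4) stop("need at least 4 samples")
  if (stats::sd(a) == 0) stop("a_fraction is constant across samples")
  res <- lapply(rownames(rpkm), function(g) {
    pr <- pearson_r(rpkm[g, ], a)
    data.frame(gene = g, r = pr$r, p = pr$p,
               dosage_dependent = isTRUE(pr$p < alpha && pr$r > 0),
               undefined = pr$undefined)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Summarize dosage-dependency calls
#'
#' @param dosage Result of [dosage_correlation()].
#' @return List: `n_genes`, `fraction_positive_r` (among defined r),
#'   `fraction_dependent`.
#' @export
dosage_classify <- function(dosage) {
  defined <- !dosage$undefined
  list(n_genes = nrow(dosage),
       fraction_positive_r = mean(dosage$r[defined] > 0),
       fraction_dependent = mean(dosage$dosage_dependent))
}

#' Per-subfamily and per-group expression aggregates
#'
#' Mean RPKM and its standard error over member genes, per sample.
#' Unannotated genes are excluded and listed in the `excluded` attribute.
#'
#' @param rpkm Genes x samples RPKM matrix.
#' @param annotations data.frame with `gene_id`, `subfamily`, `group`.
#' @return data.frame: `level` (`subfamily`/`group`), `set`, `sample`,
#'   `mean_rpkm`, `se`, `n_genes`; attribute `excluded` lists unannotated
#'   gene ids.
#' @export
subfamily_aggregate <- function(rpkm, annotations) {
  rpkm <- as.matrix(rpkm)
  ann <- annotations[match(rownames(rpkm), annotations$gene_id), ]
  excluded <- rownames(rpkm)[is.na(ann$gene_id)]
  keep <- !is.na(ann$gene_id)
  m <- rpkm[keep, , drop = FALSE]
  ann <- ann[keep, , drop = FALSE]
  one_level <- function(level, labels) {
    out <- lapply(unique(labels), function(g) {
      rows <- m[labels == g, , drop = FALSE]
      n <- nrow(rows)
      se <- if (n > 1) apply(rows, 2, stats::sd) / sqrt(n) else
        rep(0, ncol(rows))
      data.frame(level = level, set = g, sample = colnames(rows),
                 mean_rpkm = colMeans(rows), se = se, n_genes = n,
                 row.names = NULL)
    })
    do.call(rbind, out)
  }
  res <- rbind(one_level("subfamily", ann$subfamily),
               one_level("group", ann$group))
  attr(res, "excluded") <- excluded
  res
}
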