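# Group templates parameterized from the family's conserved features: motif
# variants and representative loop-B position, NPA-NPA spacing, ar/R
# selectivity filter, Loop-C residue and group-typical intron counts.
GROUP_TEMPLATES <- data.frame(
  group = c("NIP1", "NIP2", "NIP3", "NIP4", "NIP5", "NIP6", "NIP7",
            "PIP1", "PIP2", "SIP1", "SIP2",
            "TIP1", "TIP2", "TIP3", "TIP4", "TIP5"),
  subfamily = c(rep("NIP", 7), "PIP", "PIP", "SIP", "SIP", rep("TIP", 5)),
  lb_variant = c("NPA", "NPA", "NPA", "NPA", "NPS", "NPA", "NPS",
                 "NPA", "NPA", "NPT", "NPL",
                 "NPA", "NPA", "NPA", "NPA", "NPA"),
  le_variant = c("NPG", "NPA", "NPA", "NPA", "NPV", "NPV", "NPA",
                 "NPA", "NPA", "NPA", "NPA",
                 "NPA", "NPA", "NPA", "NPA", "NPA"),
  lb_pos = c(114, 104, 99, 102, 134, 139, 104, 114, 105, 69, 69,
             86, 83, 93, 79, 87),
  spacing = c(116, 116, 116, 109, 108, 108, 109, 118, 118, 112, 108,
              111, 111, 111, 111, 110),
  h2 = c("W", "V", "W", "W", "A", "A", "A", "F", "F", "T", "S",
         "H", "H", "H", "A", "N"),
  h5 = c("V", "V", "I", "V", "I", "I", "V", "H", "H", "V", "H",
         "I", "I", "I", "I", "V"),
  le1 = c("A", "A", "A", "A", "G", "A", "G", "T", "T", "P", "G",
          "A", "G", "A", "A", "G"),
  le2 = c("R", "R", "R", "R", "R", "R", "R", "R", "R", "I", "A",
          "V", "R", "R", "R", "C"),
  lc = c(rep("F", 7), "F", "F", "F", "F", "F", "H", "F", "H", "Y"),
  introns = c(rep(4L, 7), 3L, 3L, 11L, 2L, rep(2L, 5)),
  stringsAsFactors = FALSE
)

# Froger residues P1-P5 by subfamily (glyceroporin-discriminating positions)
FROGER_BY_SUBFAMILY <- c(PIP = "QSAFW", TIP = "TAAYW", NIP = "FSAYL",
                         SIP = "AAAYW")

TM_RESIDUES <- c("I", "L", "V", "F")  # strongly hydrophobic block alphabet

# background residue frequencies for non-feature positions (Swiss-Prot-like
# natural composition, so simulated proteins land in realistic mass bands)
AA_BACKGROUND_FREQ <- c(A = 0.083, R = 0.055, N = 0.040, D = 0.054,
                        C = 0.014, E = 0.067, Q = 0.039, G = 0.071,
                        H = 0.022, I = 0.059, L = 0.096, K = 0.058,
                        M = 0.024, F = 0.038, P = 0.047, S = 0.066,
                        T = 0.053, W = 0.011, Y = 0.029, V = 0.068)

sample_background <- function(n) {
  sample(names(AA_BACKGROUND_FREQ), n, replace = TRUE,
         prob = AA_BACKGROUND_FREQ)
}

# template geometry shared by generator and annotations: six 21-residue TM
# blocks around the two half-helix motifs
template_layout <- function(lb, spacing) {
  le <- lb + spacing + 3
  list(
    lb = lb, le = le, length = le + 45,
    tm_starts = c(4, lb - 28, lb + 8, lb + 44, le - 28, le + 12),
    tm_len = 21,
    h2 = lb - 12, h5 = le - 12, le1 = le + 4, le2 = le + 6, lc = lb + 33,
    froger = c(lb + 35, le + 35, le + 37, le + 39, le + 41))
}

protected_positions <- function(lay) {
  c(lay$lb:(lay$lb + 2), lay$le:(lay$le + 2), lay$h2, lay$h5, lay$le1,
    lay$le2, lay$lc, lay$froger)
}

build_group_template <- function(tmpl_row) {
  lay <- template_layout(tmpl_row$lb_pos, tmpl_row$spacing)
  s <- sample_background(lay$length)
  for (st in lay$tm_starts) {
    s[st:(st + lay$tm_len - 1)] <- sample(TM_RESIDUES, lay$tm_len,
                                          replace = TRUE)
  }
  s[lay$lb:(lay$lb + 2)] <- strsplit(tmpl_row$lb_variant, "")[[1]]
  s[lay$le:(lay$le + 2)] <- strsplit(tmpl_row$le_variant, "")[[1]]
  s[lay$h2] <- tmpl_row$h2
  s[lay$h5] <- tmpl_row$h5
  s[lay$le1] <- tmpl_row$le1
  s[lay$le2] <- tmpl_row$le2
  s[lay$lc] <- tmpl_row$lc
  s[lay$froger] <- strsplit(FROGER_BY_SUBFAMILY[[tmpl_row$subfamily]], "")[[1]]
  list(sequence = paste(s, collapse = ""), layout = lay)
}

# point-mutate a sequence at `rate`, never touching `protect` positions
mutate_sequence <- function(sequence, rate, protect = integer(0)) {
  if (rate == 0) return(sequence)
  stopifnot(rate >= 0, rate <= 0.2)
  aa <- strsplit(sequence, "")[[1]]
  eligible <- setdiff(seq_along(aa), protect)
  hit <- eligible[stats::runif(length(eligible)) < rate]
  for (p in hit) {
    aa[p] <- sample(setdiff(AA_LETTERS, aa[p]), 1)
  }
  paste(aa, collapse = "")
}

#' Specification for the sequence cohort generator
#'
#' @param groups Subset of template groups to simulate (default: all 16).
#' @param count_per_group Mutated copies per (group, genome) (default 2).
#' @param mutation_rate Per-site point-mutation probability outside protected
#'   feature columns, in `[0, 0.2]` (default 0.05).
#' @param progenitor_divergence Per-site divergence applied once per genome
#'   to derive A- and C-progenitor templates (default 0.03).
#' @param scaffold_fraction Fraction of genes placed on unanchored scaffolds
#'   instead of chromosomes (default 0.15).
#' @param decoys Named counts of decoy classes `fragment`, `single_motif`,
#'   `non_aqp` (defaults 2, 2, 3).
#' @return List of class `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(groups = GROUP_TEMPLATES$group,
                              count_per_group = 2, mutation_rate = 0.05,
                              progenitor_divergence = 0.03,
                              scaffold_fraction = 0.15,
                              decoys = c(fragment = 2, single_motif = 2,
                                         non_aqp = 3)) {
  bad <- setdiff(groups, GROUP_TEMPLATES$group)
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (mutation_rate < 0 || mutation_rate > 0.2) {
    stop("mutation_rate must lie in [0, 0.2]")
  }
  structure(list(groups = groups, count_per_group = count_per_group,
                 mutation_rate = mutation_rate,
                 progenitor_divergence = progenitor_divergence,
                 scaffold_fraction = scaffold_fraction, decoys = decoys),
            class = "sequence_sim_spec")
}

#' Simulate an annotated reference profile
#'
#' One clean template sequence per group, with fully annotated feature
#' positions (motifs, selectivity filter, Loop-C, Froger). Deterministic for
#' a fixed seed.
#'
#' @param spec A [sequence_sim_spec()].
#' @param seed Integer seed.
#' @return Reference profile data.frame (see
#'   [validate_reference_profile()]), plus `genome = "ref"`.
#' @export
simulate_reference_profile <- function(spec = sequence_sim_spec(), seed = 1) {
  set.seed(seed)
  rows <- lapply(spec$groups, function(g) {
    tr <- GROUP_TEMPLATES[GROUP_TEMPLATES$group == g, ]
    tp <- build_group_template(tr)
    lay <- tp$layout
    data.frame(name = paste0("REF_", g), subfamily = tr$subfamily, group = g,
               sequence = tp$sequence, lb_pos = lay$lb, le_pos = lay$le,
               h2_pos = lay$h2, h5_pos = lay$h5, le1_pos = lay$le1,
               le2_pos = lay$le2, lc_pos = lay$lc,
               froger1_pos = lay$froger[1], froger2_pos = lay$froger[2],
               froger3_pos = lay$froger[3], froger4_pos = lay$froger[4],
               froger5_pos = lay$froger[5])
  })
  prof <- do.call(rbind, rows)
  validate_reference_profile(prof)
}

# disrupt every N-P-x occurrence except the one at `keep_pos` (P -> G)
keep_single_motif <- function(sequence, keep_pos) {
  hits <- scan_npa_candidates(sequence)
  for (p in setdiff(hits$position, keep_pos)) {
    substr(sequence, p + 1, p + 1) <- "G"
  }
  sequence
}

#' Simulate an aquaporin-like protein cohort with planted truth
#'
#' Derives A- and C-progenitor variants of each group template, emits
#' `count_per_group` point-mutated copies per (group, genome) with all
#' feature columns protected, plants hydrophobic transmembrane blocks per
#' the template layout, appends decoys (fragments, single-motif proteins,
#' proteins without membrane segments), and builds gene models with
#' group-typical intron counts on chromosomes or unanchored scaffolds.
#'
#' @inheritParams simulate_reference_profile
#' @param profile Reference profile from [simulate_reference_profile()].
#' @return List: `proteins` (named character vector), `gene_models` (named
#'   list), `progenitors` (profile data.frame with `genome` A/C),
#'   `truth` (data.frame with per-entity class, genome, subfamily, group and
#'   planted feature columns).
#' @export
simulate_aqp_sequences <- function(spec = sequence_sim_spec(),
                                   profile = NULL, seed = 1) {
  if (is.null(profile)) profile <- simulate_reference_profile(spec, seed)
  set.seed(seed + 1L)
  chromosomes <- list(A = sprintf("A%02d", 1:10), C = sprintf("C%02d", 1:9))

  progenitors <- list()
  proteins <- character(0)
  models <- list()
  truth <- list()
  counter <- 0L
  scaffold_counter <- 0L

  for (g in spec$groups) {
    tr <- GROUP_TEMPLATES[GROUP_TEMPLATES$group == g, ]
    ref <- profile[profile$group == g, ]
    lay <- template_layout(ref$lb_pos, npa_spacing(ref$lb_pos, ref$le_pos))
    protect <- protected_positions(lay)
    for (genome in c("A", "C")) {
      prog_seq <- mutate_sequence(ref$sequence, spec$progenitor_divergence,
                                  protect)
      prog <- ref
      prog$name <- paste0("PROG_", genome, "_", g)
      prog$sequence <- prog_seq
      prog$genome <- genome
      progenitors[[length(progenitors) + 1L]] <- prog
      for (i in seq_len(spec$count_per_group)) {
        counter <- counter + 1L
        id <- sprintf("sim%s%04d", genome, counter)
        proteins[[id]] <- mutate_sequence(prog_seq, spec$mutation_rate,
                                          protect)
        on_scaffold <- stats::runif(1) < spec$scaffold_fraction
        if (on_scaffold) {
          scaffold_counter <- scaffold_counter + 1L
          chrom <- sprintf("Scaffold%05d", scaffold_counter)
        } else {
          chrom <- sample(chromosomes[[genome]], 1)
        }
        n_exons <- tr$introns + 1L
        gstart <- as.integer(1e5 * counter)
        starts <- gstart + (seq_len(n_exons) - 1L) * 350L
        models[[id]] <- gene_model(id, chrom, sample(c("+", "-"), 1),
                                   cbind(starts, starts + 199L))
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, class = "aqp", genome = genome, subfamily = tr$subfamily,
          group = g, chromosome = chrom, lb_pos = lay$lb, le_pos = lay$le,
          spacing = npa_spacing(lay$lb, lay$le),
          sf = paste0(tr$h2, tr$h5, tr$le1, tr$le2), lc = tr$lc,
          froger = FROGER_BY_SUBFAMILY[[tr$subfamily]],
          introns = tr$introns)
      }
    }
  }

  decoy_truth <- function(id, class) {
    data.frame(id = id, class = class, genome = NA_character_,
               subfamily = NA_character_, group = NA_character_,
               chromosome = NA_character_, lb_pos = NA_integer_,
               le_pos = NA_integer_, spacing = NA_integer_,
               sf = NA_character_, lc = NA_character_,
               froger = NA_character_, introns = NA_integer_)
  }
  dk <- spec$decoys
  for (i in seq_len(dk[["fragment"]])) {
    id <- sprintf("decoyFrag%02d", i)
    src <- build_group_template(GROUP_TEMPLATES[
      (i %% nrow(GROUP_TEMPLATES)) + 1L, ])$sequence
    proteins[[id]] <- substr(src, 1, 80)
    truth[[length(truth) + 1L]] <- decoy_truth(id, "fragment")
  }
  for (i in seq_len(dk[["single_motif"]])) {
    id <- sprintf("decoySingle%02d", i)
    lay <- template_layout(100, 115)
    s <- sample_background(lay$length)
    for (st in lay$tm_starts) {
      s[st:(st + lay$tm_len - 1)] <- sample(TM_RESIDUES, lay$tm_len,
                                            replace = TRUE)
    }
    s[lay$lb:(lay$lb + 2)] <- c("N", "P", "A")
    proteins[[id]] <- keep_single_motif(paste(s, collapse = ""), lay$lb)
    truth[[length(truth) + 1L]] <- decoy_truth(id, "single_motif")
  }
  for (i in seq_len(dk[["non_aqp"]])) {
    id <- sprintf("decoyNonAqp%02d", i)
    proteins[[id]] <- paste(sample_background(260), collapse = "")
    truth[[length(truth) + 1L]] <- decoy_truth(id, "non_aqp")
  }

  list(proteins = proteins, gene_models = models,
       progenitors = do.call(rbind, progenitors),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Specification for the expression-matrix generator
#'
#' Defaults emulate the study designs the pipeline targets: an allopolyploid
#' dosage series (genotypes AA, CC, AC, AAC, CCA, CCAA with A-genome
#' fractions 1, 0, 0.5, 0.66, 0.33, 0.5, two biological replicates), a
#' two-condition drought contrast, and a four-timepoint seed-development
#' series.
#'
#' @param design One of `"dosage"`, `"drought"`, `"seed_development"`.
#' @param n_genes Number of genes (default 120).
#' @param sigma Lognormal noise sd on the log scale (default 0.2).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline expression
#'   parameters in RPKM units (defaults log(20), 0.8).
#' @param replicates Biological replicates per design cell (2 for dosage,
#'   3 otherwise).
#' @param dep_fraction Fraction of dosage-dependent genes (default 0.3).
#' @param dosage_slope Linear dosage slope `mu = b * (1 + slope * a)`
#'   (default 3, calibrated for per-gene detection power near 0.9 at the
#'   default noise).
#' @param n_deg_strong,n_deg_weak Planted differentially expressed genes at
#'   `log2fc` 3 and 1.5 (drought design; defaults 8 and 8).
#' @param n_trajectory Genes per planted rising (TIP3-like) and falling
#'   (PIP1-like) seed trajectory (default 6).
#' @param n_modules,module_size Planted co-expression modules (defaults 2
#'   and 6).
#' @param module_r Target within-module Pearson correlation (default 0.95).
#' @param library_size Mean mapped fragments per sample (default 5e6).
#' @param poisson Draw Poisson counts around the target means (default
#'   `TRUE`); `FALSE` gives deterministic rounded means.
#' @return List of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(design = c("dosage", "drought",
                                           "seed_development"),
                                n_genes = 120, sigma = 0.2,
                                baseline_meanlog = log(20),
                                baseline_sdlog = 0.8,
                                replicates = NULL,
                                dep_fraction = 0.3, dosage_slope = 3,
                                n_deg_strong = 8, n_deg_weak = 8,
                                n_trajectory = 6,
                                n_modules = 2, module_size = 6,
                                module_r = 0.95,
                                library_size = 5e6, poisson = TRUE) {
  design <- match.arg(design)
  if (is.null(replicates)) replicates <- if (design == "dosage") 2L else 3L
  stopifnot(dep_fraction >= 0, dep_fraction <= 1, sigma >= 0)
  structure(list(design = design, n_genes = n_genes, sigma = sigma,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, replicates = replicates,
                 dep_fraction = dep_fraction, dosage_slope = dosage_slope,
                 n_deg_strong = n_deg_strong, n_deg_weak = n_deg_weak,
                 n_trajectory = n_trajectory, n_modules = n_modules,
                 module_size = module_size, module_r = module_r,
                 library_size = library_size, poisson = poisson),
            class = "expression_sim_spec")
}

#' Simulate an expression count matrix with planted truth
#'
#' Baseline lognormal expression per gene; planted effects applied
#' multiplicatively (dosage slope proportional to the A-genome fraction,
#' differential-expression fold changes, monotone seed trajectories, module
#' latent factors achieving the target correlation); lognormal noise; counts
#' drawn as Poisson around the RPKM-implied means given planted gene lengths
#' and library sizes.
#'
#' @param spec An [expression_sim_spec()].
#' @param seed Integer seed.
#' @return List: `counts` (genes x samples integer matrix), `lengths_bp`,
#'   `design` (data.frame with `sample`, design factors, `a_fraction`,
#'   `library_size`), `truth` (per-gene planted labels), `rpkm_target`
#'   (the noise-free RPKM means).
#' @export
simulate_expression <- function(spec = expression_sim_spec(), seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  lengths_bp <- stats::setNames(
    round(stats::runif(spec$n_genes, 1000, 3000)), genes)
  b <- stats::setNames(
    exp(stats::rnorm(spec$n_genes, spec$baseline_meanlog,
                     spec$baseline_sdlog)), genes)

  if (spec$design == "dosage") {
    genotypes <- c("AA", "CC", "AC", "AAC", "CCA", "CCAA")
    a_frac <- c(AA = 1, CC = 0, AC = 0.5, AAC = 0.66, CCA = 0.33, CCAA = 0.5)
    design <- expand.grid(replicate = seq_len(spec$replicates),
                          genotype = genotypes, stringsAsFactors = FALSE)
    design$a_fraction <- a_frac[design$genotype]
    design$condition <- design$genotype
  } else if (spec$design == "drought") {
    design <- expand.grid(replicate = seq_len(spec$replicates),
                          condition = c("control", "drought"),
                          stringsAsFactors = FALSE)
    design$tissue <- "leaf"
    design$a_fraction <- NA_real_
  } else {
    design <- expand.grid(replicate = seq_len(spec$replicates),
                          timepoint = c(2, 4, 6, 8),
                          stringsAsFactors = FALSE)
    design$tissue <- "seed"
    design$condition <- paste0("wap", design$timepoint)
    design$a_fraction <- NA_real_
  }
  design$sample <- sprintf("s%02d", seq_len(nrow(design)))
  design$library_size <- round(spec$library_size *
                                 stats::runif(nrow(design), 0.8, 1.2))

  n_s <- nrow(design)
  truth <- data.frame(gene = genes, dosage_dependent = FALSE,
                      deg = "none", true_log2fc = 0,
                      trajectory = "flat", module = NA_integer_)

  mu <- matrix(b, nrow = spec$n_genes, ncol = n_s,
               dimnames = list(genes, design$sample))

  if (spec$design == "dosage") {
    n_dep <- round(spec$dep_fraction * spec$n_genes)
    dep <- genes[seq_len(n_dep)]
    truth$dosage_dependent <- truth$gene %in% dep
    scale <- outer(rep(1, length(dep)), 1 + spec$dosage_slope *
                     design$a_fraction)
    mu[dep, ] <- mu[dep, ] * scale
  } else if (spec$design == "drought") {
    idx <- seq_len(spec$n_deg_strong + spec$n_deg_weak)
    degs <- genes[idx]
    lfc <- c(rep(3, spec$n_deg_strong), rep(1.5, spec$n_deg_weak))
    truth$deg[idx] <- rep(c("strong", "weak"),
                          c(spec$n_deg_strong, spec$n_deg_weak))
    truth$true_log2fc[idx] <- lfc
    b[degs] <- pmax(b[degs], 5)  # keep planted effects above the call floor
    mu[degs, ] <- b[degs]
    treated <- design$condition == "drought"
    mu[degs, treated] <- b[degs] * 2^lfc
  } else {
    n_t <- spec$n_trajectory
    rising <- genes[seq_len(n_t)]
    falling <- genes[n_t + seq_len(n_t)]
    truth$trajectory[match(rising, genes)] <- "tip3_like"
    truth$trajectory[match(falling, genes)] <- "pip1_like"
    rise <- c(`2` = 0.25, `4` = 1, `6` = 3, `8` = 8)
    fall <- c(`2` = 4, `4` = 3, `6` = 1, `8` = 0.5)
    mu[rising, ] <- outer(b[rising], rise[as.character(design$timepoint)])
    mu[falling, ] <- outer(b[falling], fall[as.character(design$timepoint)])
  }

  if (spec$n_modules > 0 && spec$module_size > 0) {
    lambda <- spec$sigma * sqrt(spec$module_r / (1 - spec$module_r))
    free <- genes[truth$dosage_dependent == FALSE & truth$deg == "none" &
                    truth$trajectory == "flat"]
    free <- rev(free)  # take module genes from the tail of the gene list
    for (m in seq_len(spec$n_modules)) {
      members <- free[(m - 1) * spec$module_size + seq_len(spec$module_size)]
      members <- members[!is.na(members)]
      if (length(members) < 2) next
      truth$module[match(members, genes)] <- m
      f <- stats::rnorm(n_s)
      mu[members, ] <- mu[members, ] *
        exp(outer(rep(lambda, length(members)), f) - lambda^2 / 2)
    }
  }

  if (spec$sigma > 0) {
    noise <- matrix(stats::rnorm(spec$n_genes * n_s, -spec$sigma^2 / 2,
                                 spec$sigma), spec$n_genes, n_s)
    mu_noisy <- mu * exp(noise)
  } else {
    mu_noisy <- mu
  }

  # count mean = RPKM * length_bp * library / 1e9
  lambda_counts <- sweep(sweep(mu_noisy, 1, lengths_bp / 1e3, "*"), 2,
                         design$library_size / 1e6, "*")
  counts <- if (spec$poisson) {
    matrix(stats::rpois(length(lambda_counts), lambda_counts),
           nrow = spec$n_genes, dimnames = dimnames(mu))
  } else {
    round(lambda_counts)
  }

  list(counts = counts, lengths_bp = lengths_bp, design = design,
       truth = truth, rpkm_target = mu)
}
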