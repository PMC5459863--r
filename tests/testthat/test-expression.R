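make_counts <- function() {
  counts <- matrix(c(10, 0, 400, 25,
                     20, 0, 100, 5,
                     30, 0, 900, 50), nrow = 4,
                   dimnames = list(c("gA", "gB", "gC", "gD"),
                                   c("s1", "s2", "s3")))
  list(counts = counts, lengths = c(gA = 1000, gB = 500, gC = 2000,
                                    gD = 1500))
}

test_that("RPKM follows the formula and is scale invariant", {
  # direct formula identity: count 10, length 1000 bp, library 1e6 -> 10
  m <- matrix(10, 1, 1, dimnames = list("g", "s"))
  expect_equal(as.numeric(rpkm_normalize(m, c(g = 1000), totals = 1e6)), 10)

  cm <- make_counts()
  r <- rpkm_normalize(cm$counts, cm$lengths)
  # oracle: direct recomputation per cell
  for (g in rownames(cm$counts)) {
    for (s in colnames(cm$counts)) {
      expect_equal(r[g, s], 1e9 * cm$counts[g, s] /
                     (cm$lengths[[g]] * sum(cm$counts[, s])))
    }
  }
  # doubling every count in a sample leaves its RPKM unchanged
  scaled <- cm$counts
  scaled[, "s3"] <- scaled[, "s3"] * 2
  expect_equal(rpkm_normalize(scaled, cm$lengths)[, "s3"], r[, "s3"])
  # all-zero gene stays zero everywhere
  expect_true(all(r["gB", ] == 0))

  zero_lib <- cm$counts
  zero_lib[, "s1"] <- 0
  expect_error(rpkm_normalize(zero_lib, cm$lengths), "s1")
  expect_error(rpkm_normalize(cm$counts, c(gA = 1000)), "length")
})

test_that("expressed filter is strict at the threshold and idempotent", {
  m <- rbind(at_threshold = c(2, 1.5), just_above = c(2.1, 0),
             silent = c(0.4, 1))
  e <- expressed_filter(m)
  expect_false(e[["at_threshold"]])
  expect_true(e[["just_above"]])
  expect_false(e[["silent"]])
  expect_equal(expressed_filter(m[e, , drop = FALSE]),
               e[e])  # idempotent on the expressed subset
})

test_that("DEG calls combine the fold-change and abundance rules", {
  design <- data.frame(sample = c("t1", "t2", "c1", "c2"),
                       condition = c("T", "T", "C", "C"))
  m <- rbind(zero = c(0, 0, 0, 0),
             up = c(20, 20, 2, 2),
             weak = c(6, 6, 2, 2),
             low = c(1.2, 1.2, 0.1, 0.1))
  colnames(m) <- design$sample
  res <- call_degs(m, design, c("T", "C"))
  expect_equal(res$log2fc[res$gene == "zero"], 0)
  expect_false(res$is_deg[res$gene == "zero"])
  expect_equal(res$log2fc[res$gene == "up"], log2(21 / 3), tolerance = 1e-12)
  expect_true(res$is_deg[res$gene == "up"])
  expect_equal(res$direction[res$gene == "up"], "up")
  expect_false(res$is_deg[res$gene == "weak"])   # |log2fc| below cutoff
  expect_false(res$is_deg[res$gene == "low"])    # abundance floor fails
  expect_error(call_degs(m, design, c("T", "X")), "X")
})

test_that("pearson_r matches a naive two-pass implementation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_true(pearson_r(x, rep(3, 5))$undefined)

  set.seed(71)
  for (k in 1:20) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(length(a))
    got <- pearson_r(a, b)
    mx <- mean(a); my <- mean(b)
    r_naive <- sum((a - mx) * (b - my)) /
      sqrt(sum((a - mx)^2) * sum((b - my)^2))
    expect_equal(got$r, r_naive, tolerance = 1e-12)
    tt <- stats::cor.test(a, b)
    expect_equal(got$p, tt$p.value, tolerance = 1e-9)
  }
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("co-expression edges respect their percentile thresholds", {
  sim <- simulate_expression(expression_sim_spec("drought"), 17)
  rpkm <- rpkm_normalize(sim$counts, sim$lengths_bp,
                         totals = sim$design$library_size)
  mod1 <- sim$truth$gene[which(sim$truth$module == 1)]
  net <- coexpression_network(rpkm, baits = mod1[1])
  # planted co-expressed partners survive the upper threshold
  expect_true(all(mod1[-1] %in% net$edges$target))
  # every retained edge satisfies its bait's threshold by direct re-check
  thr <- net$thresholds[[mod1[1]]]
  expect_true(all(net$edges$r <= thr["lower"] | net$edges$r >= thr["upper"]))

  # gene order invariance
  net2 <- coexpression_network(rpkm[rev(rownames(rpkm)), ], baits = mod1[1])
  e1 <- net$edges[order(net$edges$target), ]
  e2 <- net2$edges[order(net2$edges$target), ]
  expect_equal(e1$target, e2$target)
  expect_equal(e1$r, e2$r)

  # vacuous thresholds (lower = upper = 50) retain every edge; degenerate
  # baits contribute none
  all_edges <- coexpression_network(rpkm, baits = mod1[1], lower_pct = 50,
                                    upper_pct = 50)
  expect_equal(nrow(all_edges$edges), sum(apply(rpkm, 1, sd) > 0) - 1L)
  flat <- rbind(rpkm, flatgene = rep(5, ncol(rpkm)))
  net3 <- coexpression_network(flat, baits = "flatgene")
  expect_equal(net3$degenerate, "flatgene")
  expect_equal(nrow(net3$edges), 0L)
})

test_that("average-linkage clustering separates planted expression blocks", {
  two <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  hc <- hierarchical_cluster(two)
  expect_equal(length(hc$height), 1L)
  expect_equal(hc$height, 1 - cor(two["a", ], two["b", ]))

  sim <- simulate_expression(expression_sim_spec("seed_development"), 17)
  rpkm <- rpkm_normalize(sim$counts, sim$lengths_bp,
                         totals = sim$design$library_size)
  sel <- sim$truth$gene[sim$truth$trajectory != "flat"]
  hc2 <- hierarchical_cluster(rpkm[sel, ])
  expect_true(all(diff(hc2$height) >= -1e-12))  # monotone merge heights
  ct <- stats::cutree(hc2, 2)
  traj <- sim$truth$trajectory[match(names(ct), sim$truth$gene)]
  expect_equal(length(unique(ct[traj == "tip3_like"])), 1L)
  expect_equal(length(unique(ct[traj == "pip1_like"])), 1L)
  expect_false(ct[traj == "tip3_like"][1] == ct[traj == "pip1_like"][1])
})

test_that("dosage dependency requires positive significant correlation", {
  design <- data.frame(sample = sprintf("s%02d", 1:12),
                       a_fraction = rep(c(1, 0, 0.5, 0.66, 0.33, 0.5),
                                        each = 2))
  a <- design$a_fraction
  m <- rbind(prop = 10 * a + 1, anti = 10 * (1 - a) + 1,
             const = rep(4, 12))
  colnames(m) <- design$sample
  res <- dosage_correlation(m, design)
  expect_equal(res$r[res$gene == "prop"], 1)
  expect_true(res$dosage_dependent[res$gene == "prop"])
  # significant but negative correlation is not dosage dependence
  expect_false(res$dosage_dependent[res$gene == "anti"])
  expect_true(res$undefined[res$gene == "const"])
  expect_false(res$dosage_dependent[res$gene == "const"])

  s <- dosage_classify(res)
  expect_equal(s$n_genes, 3L)
  expect_equal(s$fraction_dependent, 1 / 3)

  bad <- design
  bad$a_fraction <- 0.5
  expect_error(dosage_correlation(m, bad), "constant")
  expect_error(dosage_correlation(m[, 1:3], design[1:3, ]), "at least 4")
})

test_that("subfamily aggregation reproduces group means and ignores order", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    subfamily = c("PIP", "PIP", "TIP"),
                    group = c("PIP1", "PIP2", "TIP3"))
  m <- rbind(g1 = c(2, 4), g2 = c(6, 8), g3 = c(1, 1), g4 = c(9, 9))
  colnames(m) <- c("s1", "s2")
  agg <- subfamily_aggregate(m, ann)
  expect_equal(attr(agg, "excluded"), "g4")
  pip_s1 <- agg$mean_rpkm[agg$level == "subfamily" & agg$set == "PIP" &
                            agg$sample == "s1"]
  expect_equal(pip_s1, 4)
  expect_equal(agg$se[agg$level == "subfamily" & agg$set == "PIP" &
                        agg$sample == "s1"], sd(c(2, 6)) / sqrt(2))
  # single-gene group: mean is the gene's value, SE is zero
  expect_equal(agg$mean_rpkm[agg$set == "TIP3" & agg$sample == "s2"], 1)
  expect_equal(agg$se[agg$set == "TIP3" & agg$sample == "s2"], 0)

  agg2 <- subfamily_aggregate(m[c("g3", "g1", "g4", "g2"), ], ann)
  key <- function(x) x[order(x$level, x$set, x$sample),
                       c("mean_rpkm", "se", "n_genes")]
  expect_equal(key(agg2), key(agg), ignore_attr = TRUE)
})
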