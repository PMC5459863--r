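spec_small <- sequence_sim_spec(groups = c("PIP1", "PIP2", "TIP2", "NIP5"),
                                count_per_group = 1)
prof_small <- simulate_reference_profile(spec_small, 2)

test_that("candidate screening excludes fragments and membrane-less decoys", {
  set.seed(53)
  frag <- random_protein(60)
  decoy <- random_protein(260)
  full <- prof_small$sequence[prof_small$group == "PIP1"]
  rep <- screen_candidates(c(frag = frag, aqp = full, decoy = decoy))
  expect_false(rep$kept[rep$id == "frag"])
  expect_match(rep$reasons[rep$id == "frag"], "too_short")
  expect_true(rep$kept[rep$id == "aqp"])
  expect_false(rep$kept[rep$id == "decoy"])
  expect_match(rep$reasons[rep$id == "decoy"], "missing_tm")
  expect_true(all(rep$kept == (rep$reasons == "")))

  # order independence: permuting records permutes reports identically
  rep2 <- screen_candidates(c(decoy = decoy, frag = frag, aqp = full))
  expect_equal(rep[order(rep$id), ], rep2[order(rep2$id), ],
               ignore_attr = TRUE)

  long <- screen_candidates(setNames(random_protein(500), "big"))
  expect_match(long$reasons, "too_long")
})

test_that("classification adopts the best reference and rejects noise", {
  q <- prof_small$sequence[prof_small$group == "TIP2"]
  res <- classify_subfamily(q, prof_small)
  expect_true(res$classified)
  expect_equal(res$group, "TIP2")
  expect_equal(res$identity, 1)

  set.seed(59)
  shuffled <- paste(sample(strsplit(q, "")[[1]]), collapse = "")
  res2 <- classify_subfamily(shuffled, prof_small)
  expect_false(res2$classified)
  expect_true(is.na(res2$subfamily))

  expect_error(classify_subfamily(q, prof_small[0, ]), "empty")
})

test_that("genome labels and paralog letters follow chromosome order", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    group = c("NIP5", "NIP5", "NIP5", "PIP1"))
  models <- list(
    g1 = gene_model("g1", "A03", "+", cbind(5000, 6000)),
    g2 = gene_model("g2", "A02", "+", cbind(1000, 2000)),
    g4 = gene_model("g4", "chrC04", "-", cbind(100, 900)))
  # g3 sits on a scaffold; place it by progenitor similarity
  prog <- prof_small[prof_small$group == "NIP5", ]
  prog <- rbind(prog, prog)
  prog$name <- c("progA", "progC")
  prog$genome <- c("A", "C")
  set.seed(61)
  lay <- aqpscan:::template_layout(prog$lb_pos[2],
                                   npa_spacing(prog$lb_pos[2],
                                               prog$le_pos[2]))
  prog$sequence[2] <- aqpscan:::mutate_sequence(prog$sequence[2], 0.05,
                                                aqpscan:::protected_positions(lay))
  seqs <- c(g1 = prog$sequence[1], g2 = prog$sequence[1],
            g3 = prog$sequence[2], g4 = prog$sequence[1])
  models$g3 <- gene_model("g3", "Scaffold001", "+", cbind(1, 700))
  # chromosome-anchored genome letters and a/b ordering by chromosome
  named <- assign_genome_and_name(ann, models[c("g1", "g2", "g4")],
                                  progenitor_profile = prog,
                                  sequences = seqs)
  expect_equal(named$genome[named$gene_id == "g1"], "A")
  expect_equal(named$genome[named$gene_id == "g4"], "C")
  expect_equal(named$name[named$gene_id == "g2"], "BnaANIP5-1a")  # A02 first
  expect_equal(named$name[named$gene_id == "g1"], "BnaANIP5-1b")

  named2 <- assign_genome_and_name(ann, models, progenitor_profile = prog,
                                   sequences = seqs)
  expect_equal(named2$genome[named2$gene_id == "g3"], "C_random")
  expect_match(named2$name[named2$gene_id == "g3"], "^BnaCNIP5-1")
})

test_that("specificity rules gate silicic acid on filter and spacing", {
  water <- predict_specificity(list(h2 = "F", h5 = "H", le1 = "T",
                                    le2 = "R"), 118)
  expect_true("water" %in% water$substrate[water$tier == 1])
  expect_false("silicic_acid" %in% water$substrate)

  si <- predict_specificity(list(h2 = "G", h5 = "S", le1 = "G", le2 = "R"),
                            108)
  expect_true("silicic_acid" %in% si$substrate[si$tier == 1])
  no_si <- predict_specificity(list(h2 = "G", h5 = "S", le1 = "G",
                                    le2 = "R"), 116)
  expect_false("silicic_acid" %in% no_si$substrate)

  nip2 <- predict_specificity(list(h2 = "A", h5 = "I", le1 = "G",
                                   le2 = "R"), 108)
  expect_true("boric_acid" %in% nip2$substrate[nip2$tier == 1])
  expect_false("silicic_acid" %in% nip2$substrate)

  # undefined residues lower the confidence tier
  und <- predict_specificity(list(h2 = "F", h5 = "H", le1 = "-", le2 = "R"),
                             118)
  expect_true(all(und$tier >= 2) || nrow(und) == 0)

  # property: silicic acid never emitted unless filter is G,S,G,R at 108
  set.seed(67)
  res_letters <- c(aqpscan:::AA_LETTERS, "-")
  for (k in 1:200) {
    sf <- list(h2 = sample(res_letters, 1), h5 = sample(res_letters, 1),
               le1 = sample(res_letters, 1), le2 = sample(res_letters, 1))
    sp <- sample(c(NA, 90:140), 1)
    out <- predict_specificity(sf, sp)
    if ("silicic_acid" %in% out$substrate) {
      expect_equal(unlist(sf, use.names = FALSE), c("G", "S", "G", "R"))
      expect_equal(sp, 108L)
    }
  }
})

test_that("feature table is deterministically ordered and round-trips", {
  empty <- build_feature_table(data.frame(gene_id = character(0)))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene_id", "npa_lb", "distance") %in% names(empty)))

  spec <- sequence_sim_spec(groups = c("PIP1", "TIP2"), count_per_group = 2,
                            decoys = c(fragment = 1, single_motif = 0,
                                       non_aqp = 1))
  prof <- simulate_reference_profile(spec, 21)
  sim <- simulate_aqp_sequences(spec, prof, 21)
  res <- annotate_proteome(sim$proteins, prof, sim$gene_models,
                           sim$progenitors)
  tab <- build_feature_table(res$annotations)
  expect_equal(nrow(tab), sum(res$screen$kept))
  f <- withr::local_tempfile(fileext = ".tsv")
  build_feature_table(res$annotations, f)
  back <- utils::read.delim(f, colClasses = "character")
  expect_equal(back$gene_id, tab$gene_id)
  expect_equal(back$distance, as.character(tab$distance))
})

test_that("neighbor joining recovers additive distances and clades", {
  # three taxa: unique unrooted topology, branch lengths from the
  # three-point closed form
  seqs3 <- setNames(prof_small$sequence[1:3], c("t1", "t2", "t3"))
  nwk <- neighbor_joining_tree(seqs3)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), c("t1", "t2", "t3"))
  d <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    d[i, j] <- d[j, i] <- 1 - global_align(seqs3[[i]], seqs3[[j]],
                                           default_submat())$identity
  }
  cophen <- ape::cophenetic.phylo(tree)[c("t1", "t2", "t3"),
                                        c("t1", "t2", "t3")]
  expect_equal(unname(cophen), unname(d), tolerance = 1e-8)

  # subfamily-templated set: within-group tips pair together
  spec <- sequence_sim_spec(groups = c("PIP1", "NIP5"), count_per_group = 2)
  sim <- simulate_aqp_sequences(spec, simulate_reference_profile(spec, 31),
                                31)
  aqps <- sim$truth$id[sim$truth$class == "aqp"]
  nwk2 <- neighbor_joining_tree(sim$proteins[aqps])
  tr2 <- ape::read.tree(text = nwk2)
  expect_true(all(tr2$edge.length >= 0))
  groups <- sim$truth$group[match(tr2$tip.label, sim$truth$id)]
  rooted <- ape::root(tr2, outgroup = tr2$tip.label[groups == "NIP5"][1],
                      resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted,
                                   tr2$tip.label[groups == "PIP1"]))

  expect_error(neighbor_joining_tree(seqs3[1:2]), "at least 3")
})

test_that("configuration validation names offending keys and ranges", {
  expect_silent(validate_config(default_config()))
  bad <- default_config()
  bad$screening$bogus_key <- 1
  expect_error(validate_config(bad), "bogus_key")
  bad2 <- default_config()
  bad2$expression$dosage_alpha <- 2
  expect_error(validate_config(bad2), "dosage_alpha")

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("screening:", "  min_tm: 6"), f)
  cfg <- load_config(f)
  expect_equal(cfg$screening$min_tm, 6)
  expect_equal(cfg$tm$window, 19)
})

test_that("packaged fixture satisfies its internal consistency checks", {
  v <- validate_bnapus_fixture()
  expect_true(v$ok)
  expect_equal(v$exempt, "BnaCNIP4-1c")

  # fault injection: one corrupted distance is named
  tab <- load_bnapus_table()
  tab$distance[tab$name == "BnaANIP1-2a"] <- 99L
  v2 <- validate_bnapus_fixture(tab)
  expect_false(v2$ok)
  expect_equal(v2$violations$name, "BnaANIP1-2a")
})
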