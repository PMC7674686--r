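test_that("origins fall at the presence MRCA, or at the constrained event", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  cons <- tnfsf_constraints()
  # present everywhere, unconstrained -> root, zero losses
  everywhere <- as_count_matrix(tibble::tibble(species = m$species, g = 1L))
  og <- place_origin("g", everywhere, st)
  expect_equal(og$branch, "vertebrate_ancestor")
  h <- infer_history(everywhere, st)
  expect_equal(sum(h$events$event == "loss"), 0L)
  # TNFSF15: absent in agnathans, constrained to WGD2 on the vertebrate stem
  og15 <- place_origin("TNFSF15", m, st, cons[cons$group == "TNFSF15", ])
  expect_equal(og15$branch, "vertebrate_ancestor")
  expect_equal(og15$event, "WGD2")
  # infeasible: constrained below some of its presences
  bad <- read_constraints(tibble::tibble(group = "TNFSF6", origin = "tandem",
                                         parent_group = "EDA",
                                         branch = "gnathostome_ancestor"),
                          groups = count_groups(m))
  expect_error(place_origin("TNFSF6", m, st, bad[1, ]),
               class = "paralogon_infeasible_error")
})

test_that("unconstrained Dollo loss counts equal the brute-force minimum", {
  for (seed in 1:25) {
    set.seed(seed * 1000)
    n <- sample(4:12, 1)
    st <- random_species_tree(n, seed = seed * 7)
    species <- tree_leaves(st)
    present <- sample(species, sample(1:n, 1))
    m <- presence_matrix(species, present)
    h <- infer_history(m, st)
    oracle <- bf_dollo(st$phylo, sort(present))
    expect_equal(sum(h$events$n[h$events$event == "loss"]), oracle$min_losses)
    # the MRCA placement is among the brute-force argmins
    mrca_name <- h$origins$branch[h$origins$group == "grp"]
    ix <- paralogon:::tree_index(st)
    expect_true(ix$id[[mrca_name]] %in% oracle$argmin)
  }
})

test_that("Wagner copy-number cost equals exhaustive enumeration on small trees", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(3:5, 1)
    st <- random_species_tree(n, seed = seed + 100)
    counts <- sample(0:3, n, replace = TRUE)
    if (all(counts == 0)) counts[1] <- 1L
    ix <- paralogon:::tree_index(st)
    fit <- paralogon:::wagner_dollo_states(ix, ix$root, counts, max_state = 4L)
    want <- bf_wagner_cost(st$phylo, counts, max_state = 4L)
    expect_equal(fit$cost, want)
    expect_equal(fit$states[seq_len(n)], counts)
  }
})

test_that("Wagner cost matches an independent Sankoff parsimony via an origin anchor tip", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:8, 1)
    phy <- ape::rtree(n, rooted = TRUE)
    phy$tip.label <- sprintf("sp%02d", seq_len(n))
    counts <- sample(1:4, n, replace = TRUE)  # all present: the no-regain rule is inert
    # anchor tip with state 1 at the root encodes the origin's entry cost
    anchored <- ape::read.tree(
      text = sprintf("(%s,ANCHOR);", sub(";$", "", ape::write.tree(phy))))
    states <- c(setNames(as.character(counts), phy$tip.label), ANCHOR = "1")
    dat <- phangorn::phyDat(matrix(states[anchored$tip.label], ncol = 1,
                                   dimnames = list(anchored$tip.label, NULL)),
                            type = "USER", levels = as.character(0:5))
    cost_mat <- abs(outer(0:5, 0:5, "-"))
    dimnames(cost_mat) <- list(as.character(0:5), as.character(0:5))
    sank <- phangorn::parsimony(anchored, dat, method = "sankoff", cost = cost_mat)
    st <- read_species_tree(ape::write.tree(phy))
    ix <- paralogon:::tree_index(st)
    fit <- paralogon:::wagner_dollo_states(ix, ix$root, counts, max_state = 5L)
    expect_equal(fit$cost, as.numeric(sank))
  }
})

test_that("the fixture reconstruction reproduces the early-vertebrate event model", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  cons <- tnfsf_constraints()
  h <- infer_history(m, st, cons)
  # Dollo: exactly one origin per group
  expect_equal(sum(h$events$event == "origin"), 24L)
  expect_equal(nrow(h$origins), 24L)
  # leaf repertoires reproduce the matrix exactly
  for (sp in m$species) {
    rep <- ancestral_repertoire(h, sp)
    want <- counts_long(m) |> dplyr::filter(.data$species == sp, .data$count > 0)
    expect_equal(setNames(rep$count, rep$group)[sort(rep$group)],
                 setNames(want$count, want$group)[sort(want$group)])
  }
  # the six agnathan-stem losses
  ag <- h$events |> dplyr::filter(.data$branch == "agnathan_ancestor",
                                  .data$event == "loss")
  expect_setequal(ag$group, c("TNFSF1/2", "TNFSF10", "TNFSF11", "TNFSF12",
                              "TNFSF13", "TNFSF15"))
  # no event precedes a group's origin
  ix <- paralogon:::tree_index(st)
  for (i in seq_len(nrow(h$events))) {
    g <- h$events$group[i]
    ob <- h$origins$branch[h$origins$group == g]
    expect_true(paralogon:::is_ancestor(ix, ix$id[[ob]], ix$id[[h$events$branch[i]]]))
  }
})

test_that("ancestral repertoires have the deduced sizes", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  cons <- tnfsf_constraints()
  h <- infer_history(m, st, cons)
  expect_equal(nrow(ancestral_repertoire(h, "vertebrate_ancestor")), 15L)
  homo_total <- count_totals(m)$total[m$species == "Homo_sapiens"]
  expect_equal(nrow(ancestral_repertoire(h, "gnathostome_ancestor")), homo_total + 1L)
  expect_equal(progenitor_count(h, cons), 3L)
  expect_equal(post_wgd_gene_count(h, cons), 13L)
  expect_error(ancestral_repertoire(h, "atlantis"), class = "paralogon_lookup_error")
  # leaf repertoire equals its matrix row
  latro <- ancestral_repertoire(h, "Latimeria_chalumnae")
  expect_equal(nrow(latro), 19L)
})

test_that("without constraints the progenitor and post-WGD counts fall back to the root", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  h <- infer_history(m, st, NULL)
  root_groups <- h$origins$group[h$origins$branch == "vertebrate_ancestor"]
  expect_equal(progenitor_count(h, NULL), length(root_groups))
  expect_equal(post_wgd_gene_count(h, NULL),
               sum(ancestral_repertoire(h, "vertebrate_ancestor")$count))
})

test_that("adding a constraint never decreases the total event count", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  cons <- tnfsf_constraints()
  free <- infer_history(m, st, NULL)
  constrained <- infer_history(m, st, cons)
  expect_gte(sum(constrained$events$n), sum(free$events$n))
  # and per group
  for (g in count_groups(m)) {
    ef <- sum(free$events$n[free$events$group == g])
    ec <- sum(constrained$events$n[constrained$events$group == g])
    expect_gte(ec, ef)
  }
})

test_that("an all-zero matrix with no constraints yields an empty history", {
  st <- tnfsf_tree()
  zero <- as_count_matrix(tibble::tibble(species = tree_leaves(st), g = 0L))
  h <- infer_history(zero, st)
  expect_equal(nrow(h$origins), 0L)
  expect_equal(nrow(h$events), 0L)
})

test_that("the conservation summary reproduces the published breakdown", {
  st <- tnfsf_tree()
  m <- tnfsf_counts()
  cs <- conservation_summary(m, st, "Homo_sapiens")
  expect_setequal(cs$universal, c("TNFSF6", "EDA"))
  expect_equal(length(cs$absent_in_reference), 7L)
  expect_setequal(cs$absent_in_reference,
                  c("BALM", "TNFSF-New", "TNFSF-Fish1", "TNFSF-Fish2",
                    "TNFSF-Fish3", "TNFSF-Fish4", "TNFSF-Fish5"))
  expect_equal(cs$n_groups, 24L)
  per <- cs$per_species
  expect_equal(per$n_groups[per$species == "Latimeria_chalumnae"], 19L)
  expect_equal(per$n_genes[per$species == "Petromyzon_marinus"], 7L)
  expect_setequal(cs$outgroup, agnathan_species)
  # hagfish TNFSF5 keeps the shared set at seven table-derived groups
  expect_equal(length(cs$shared_not_universal), 7L)
  expect_true("TNFSF5" %in% cs$shared_not_universal)
})

test_that("a one-species matrix treats all its groups as universally present", {
  st <- read_species_tree("(A,B)r;")
  m <- as_count_matrix(tibble::tibble(species = "A", g1 = 1L, g2 = 2L))
  cs <- conservation_summary(m, st, reference_species = "A")
  expect_setequal(cs$universal, c("g1", "g2"))
})
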