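make_track <- function(starts, ids, species = "sp1", scaffold = "chr1",
                       fams = ids) {
  read_gene_track(tibble::tibble(species = species, scaffold = scaffold,
                                 start = starts, end = starts + 1000L,
                                 strand = "+", gene_id = ids, family = fams))
}

test_that("neighbourhoods honour windows, expansion and scaffold ends", {
  tr <- make_track(c(0, 2000, 4000, 6000, 8000) * 100L, sprintf("g%d", 1:5))
  # g3 with 200kb window: g2 and g4 are within; g1/g5 are 400kb-600kb away
  nb <- neighborhood(tr, "g3", k_genes = 2, window_bp = 250000, max_window_bp = 1e6)
  expect_setequal(nb$gene_id, c("g2", "g4"))
  expect_false(attr(nb, "one_sided"))
  # narrow window forces expansion towards the nearest gene per side
  nb2 <- neighborhood(tr, "g3", k_genes = 2, window_bp = 1000, max_window_bp = 1e6)
  expect_setequal(nb2$gene_id, c("g2", "g4"))
  # scaffold end: one-sided and flagged
  nb3 <- neighborhood(tr, "g1", k_genes = 2, window_bp = 250000, max_window_bp = 1e6)
  expect_true(all(nb3$side == "right"))
  expect_true(attr(nb3, "one_sided"))
  expect_error(neighborhood(tr, "absent"), class = "paralogon_lookup_error")
})

test_that("neighbourhood extraction matches a brute-force interval scan", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    starts <- sort(sample.int(3e5, n)) * 1L
    tr <- read_gene_track(tibble::tibble(species = "sp", scaffold = "c",
                                         start = starts, end = starts + 50L,
                                         strand = "+", gene_id = sprintf("g%02d", 1:n),
                                         family = NA_character_))
    focal <- sample(tr$gene_id, 1)
    k <- sample(1:3, 1)
    win <- sample(c(5e3, 2e4, 1e5), 1)
    nb <- neighborhood(tr, focal, k_genes = k, window_bp = win, max_window_bp = win)
    frow <- tr[tr$gene_id == focal, ]
    scan_side <- function(left) {
      cand <- tr[if (left) tr$rank < frow$rank else tr$rank > frow$rank, ]
      gap <- if (left) pmax(0L, frow$start - cand$end) else pmax(0L, cand$start - frow$end)
      cand <- cand[gap <= win, ]
      cand <- cand[order(abs(cand$rank - frow$rank)), ]
      utils::head(cand$gene_id, k)
    }
    expect_setequal(nb$gene_id, c(scan_side(TRUE), scan_side(FALSE)))
  }
})

test_that("evidence classes follow the adjacency-then-chromosome hierarchy", {
  ta <- make_track(c(0, 2000, 4000), c("a1", "A", "a2"), species = "spA",
                   fams = c("F1", "FOCAL", "F2"))
  # same position: both flanking orthologs conserved
  tb <- make_track(c(0, 2000, 4000), c("b1", "B", "b2"), species = "spB",
                   fams = c("F1", "FOCAL", "F2"))
  ev <- shared_neighbor_evidence(ta, tb, "A", "B")
  expect_equal(ev$class, "same_position")
  expect_equal(ev$shared_neighbors, "F1,F2")
  expect_equal(ev$p, chance_probability(20000, 4))
  # same chromosome: orthologs on B's scaffold but not adjacent
  tb2 <- make_track(c(0, 2000, 4000, 6000), c("x1", "x2", "B", "b2"), species = "spB",
                    fams = c("F1", "ZZ", "FOCAL", "QQ"))
  ev2 <- shared_neighbor_evidence(ta, tb2, "A", "B")
  expect_equal(ev2$class, "same_chromosome")
  # nothing shared
  tb3 <- make_track(c(0, 2000, 4000), c("y1", "B", "y2"), species = "spB",
                    fams = c("P", "FOCAL", "Q"))
  expect_equal(shared_neighbor_evidence(ta, tb3, "A", "B")$class, "none")
  # empty neighbourhood (isolated gene) is undetermined, never none
  tb4 <- make_track(0L, "B", species = "spB", fams = "FOCAL")
  expect_equal(shared_neighbor_evidence(ta, tb4, "A", "B")$class, "undetermined")
})

test_that("the chance-collision probability matches its closed form and bounds", {
  expect_equal(chance_probability(20000, 4), 1 / 5000)
  expect_equal(chance_probability(10, 0), 0)
  expect_equal(chance_probability(2, 10), 1)
  expect_error(chance_probability(0, 4), class = "paralogon_domain_error")
  expect_error(chance_probability(100, -1), class = "paralogon_domain_error")
  # non-increasing in genome size, linear in slots below the cap
  sizes <- c(1000, 5000, 20000, 1e5)
  expect_true(all(diff(vapply(sizes, chance_probability, 1, neighbor_slots = 4)) <= 0))
  expect_equal(chance_probability(20000, 8), 2 * chance_probability(20000, 4))
})

test_that("Monte-Carlo placement of a marked gene agrees with the analytic probability", {
  set.seed(99)
  n_draws <- 1e5
  N <- 20000
  slots <- 4
  hits <- sample.int(N, n_draws, replace = TRUE) <= slots
  phat <- mean(hits)
  se <- sqrt(phat * (1 - phat) / n_draws)
  expect_lt(abs(phat - chance_probability(N, slots)), 3 * se + 1e-12)
})

test_that("corroboration multiplies independent evidence and keeps the class order", {
  ev <- tibble::tibble(group = "G", species = "spA",
                       class = c("same_position", "same_position"),
                       p = c(2e-4, 2e-4))
  out <- corroborate(ev, alpha = 1e-3)
  expect_equal(out$combined_p, 4e-8)
  expect_true(out$corroborated)
  expect_equal(out$verdict, "same_position")

  und <- corroborate(tibble::tibble(group = "G", species = "s",
                                    class = "undetermined", p = NA_real_))
  expect_equal(und$verdict, "undetermined")
  expect_false(und$corroborated)

  chr <- corroborate(tibble::tibble(group = "G", species = "s",
                                    class = "same_chromosome", p = 0.05))
  expect_equal(chr$verdict, "same_chromosome")
})

test_that("conserved simulated neighbourhoods always yield same-position evidence", {
  st <- tnfsf_tree()
  sim <- simulate_history(simulation_config(seed = 13, loss_rate = 0,
                                            rearrangement_rate = 0,
                                            genome_gene_count = 120), st)
  tr <- simulate_tracks(sim)
  sp <- unique(tr$species)
  pair <- sim$copies |> dplyr::filter(.data$copy == "c0001",
                                      .data$species %in% sp[1:4])
  for (i in seq_len(nrow(pair) - 1)) {
    ev <- shared_neighbor_evidence(tr[tr$species == pair$species[i], ],
                                   tr[tr$species == pair$species[i + 1], ],
                                   "c0001", "c0001",
                                   genome_gene_count = 120)
    expect_equal(ev$class, "same_position")
  }
})
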