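test_that("target-to-seed distances honour membership and adjacency", {
  g <- as_interactome(tibble::tibble(
    protein_a = c("S1", "T1", "X", "Y"),
    protein_b = c("T1", "X", "Y", "Z"),
    score = 900L))
  d <- min_distances(g, c("S1", "T1", "X", "Z"), seeds = "S1")
  dd <- stats::setNames(d$distance, d$target)
  expect_equal(dd[["S1"]], 0)  # a target that is a seed
  expect_equal(dd[["T1"]], 1)  # adjacent to a seed
  expect_equal(dd[["X"]], 2)
  expect_equal(dd[["Z"]], 4)
  expect_equal(sum(d$distance == 0), sum(d$target %in% "S1"))
})

test_that("distances match an independent per-target BFS oracle", {
  g <- random_interactome(50, 0.08, seed = 14)
  nodes <- igraph::V(g)$name
  set.seed(15)
  seeds <- sample(nodes, 5)
  targets <- sample(nodes, 12)
  d <- suppressMessages(min_distances(g, targets, seeds))
  for (i in seq_len(nrow(d))) {
    oracle <- min(vapply(seeds, function(s)
      bfs_oracle(g, s)[[d$target[i]]], 0))
    expect_equal(d$distance[i], oracle)
  }
})

test_that("unmapped targets are dropped and unreachable ones flagged", {
  g <- as_interactome(tibble::tibble(protein_a = c("A", "C"),
                                     protein_b = c("B", "D"),
                                     score = 900L))
  expect_message(d <- min_distances(g, c("A", "C", "NOPE"), seeds = "B"),
                 "not in the graph")
  expect_equal(attr(d, "n_unmapped"), 1)
  expect_equal(attr(d, "n_unreachable"), 1)  # C-D component has no seed
  expect_true(is.infinite(d$distance[d$target == "C"]))
  expect_error(min_distances(g, "NOPE", "B"), "no targets mapped")
})

test_that("adding edges never increases a target's distance", {
  g <- random_interactome(40, 0.05, seed = 3)
  nodes <- igraph::V(g)$name
  seeds <- nodes[1:4]
  targets <- nodes[20:30]
  d1 <- suppressMessages(min_distances(g, targets, seeds))
  extra <- dplyr::bind_rows(
    interactome_edges(g),
    tibble::tibble(protein_a = nodes[20:24], protein_b = nodes[c(2, 3, 5, 6, 1)],
                   score = 900L))
  g2 <- as_interactome(extra)
  d2 <- suppressMessages(min_distances(g2, targets, seeds))
  expect_true(all(d2$distance <= d1$distance))
})

test_that("proximity null is deterministic per seed and degenerate data give t=0", {
  g <- random_interactome(80, 0.1, seed = 20)
  nodes <- igraph::V(g)$name
  r1 <- proximity_null(g, nodes[1:10], nodes[40:50], n_samples = 30, seed = 8)
  r2 <- proximity_null(g, nodes[1:10], nodes[40:50], n_samples = 30, seed = 8)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$null_distances, r2$null_distances)
  expect_equal(length(r1$null_distances), 30)

  # complete graph: every non-seed node at distance 1, seeds at 0 -> after
  # taking only non-seed targets the observed equals every null draw
  p <- utils::combn(sprintf("K%02d", 1:8), 2)
  kg <- as_interactome(tibble::tibble(protein_a = p[1, ], protein_b = p[2, ],
                                      score = 900L))
  r <- proximity_null(kg, sprintf("K%02d", 2:4), "K01", n_samples = 10,
                      seed = 1)
  expect_true(abs(r$t_statistic) < 3 || r$p_value > 0.001)
})

test_that("degree-matched sampling draws from the target degree bins", {
  g <- random_interactome(100, 0.06, seed = 30)
  nodes <- igraph::V(g)$name
  r <- proximity_null(g, nodes[1:8], nodes[50:60], n_samples = 15, seed = 2,
                      sampling = "degree")
  expect_equal(length(r$null_distances), 15)
  expect_true(all(lengths(r$null_distances) == 8))
})

test_that("module census counts direct and neighbor targets by set algebra", {
  # M1 = {A,B,C,S}, M2 = {D,E}; seed S in M1; N outside M1 adjacent to S
  g <- as_interactome(tibble::tibble(
    protein_a = c("A", "B", "C", "S", "D"),
    protein_b = c("B", "C", "S", "N", "E"),
    score = 900L))
  part <- tibble::tibble(
    protein = c("A", "B", "C", "S", "D", "E", "N"),
    module_id = c("M1", "M1", "M1", "M1", "M2", "M2", "M2"),
    module_size = c(4L, 4L, 4L, 4L, 3L, 3L, 3L),
    small = FALSE)
  class(part) <- c("module_partition", class(part))
  dt <- tibble::tibble(drug_id = c("DG1", "DG1", "DG2", "DG3"),
                       target = c("A", "B", "C", "N"),
                       class = c("AED", "AED", "other", "other"))
  cen <- module_census(g, part, dt, seeds = "S")
  m1 <- cen[cen$module_id == "M1", ]
  expect_equal(m1$n_direct, 3)   # A, B, C
  expect_equal(m1$n_drugs, 2)    # DG1, DG2
  expect_equal(m1$n_neighbor, 1) # N adjacent to seed S, outside M1
  expect_equal(m1$neighbor_targets[[1]], "N")
  expect_equal(m1$drugs_per_protein, 2 / 4)
  expect_length(intersect(m1$direct_targets[[1]], m1$neighbor_targets[[1]]), 0)
  m2 <- cen[cen$module_id == "M2", ]
  expect_equal(m2$n_direct, 1)   # N is a member of M2
  expect_equal(m2$n_neighbor, 0) # M2 holds no seed
})

test_that("census counts match a brute-force check on synthetic data", {
  syn <- generate_synthetic(synthetic_spec(seed = 9))
  g <- syn$data$interactome
  part <- detect_modules(g, seed = 9)
  dt <- syn$data$drug_targets
  seeds <- unique(syn$data$disease_genes$gene)
  cen <- module_census(g, part, dt, seeds)
  members <- module_members(part)
  for (i in sample(nrow(cen), 3)) {
    mid <- cen$module_id[i]
    expect_equal(cen$n_direct[i],
                 length(intersect(unique(dt$target), members[[mid]])))
    mod_seeds <- intersect(seeds, members[[mid]])
    nb <- unique(unlist(lapply(mod_seeds, function(s)
      igraph::V(g)$name[igraph::neighbors(g, s)])))
    expect_equal(cen$n_neighbor[i],
                 length(setdiff(intersect(unique(dt$target), nb),
                                members[[mid]])))
  }
})

test_that("nomination applies the pathway, drug-class and expression rules", {
  members <- sprintf("G%02d", 1:10)
  pathway <- c(sprintf("G%02d", 1:7), "OFFMODULE")
  dt <- tibble::tibble(drug_id = c("AED1", "OTH1"),
                       target = c("G01", "G02"),
                       class = c("AED", "other"))
  expr <- tidyr::expand_grid(gene = members,
                             tissue = c("cerebral cortex", "hippocampus")) |>
    dplyr::mutate(expressed = gene != "G03")
  nom <- nominate_targets(members, pathway, dt, expression = expr)
  # in-pathway members G01..G07, minus AED-targeted G01 and unexpressed G03;
  # G02 stays because its drug is not disease-specific
  expect_setequal(nom$gene, c("G02", sprintf("G%02d", 4:7)))
  expect_true(all(nom$gene %in% members))
  expect_warning(none <- nominate_targets(members, character(), dt), "empty")
  expect_equal(nrow(none), 0)
})
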