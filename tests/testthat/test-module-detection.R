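test_that("two bridged cliques are split into their two cliques", {
  g <- two_clique_graph(10)
  part <- detect_modules(g, max_size = 400, min_size = 5, seed = 1)
  expect_equal(dplyr::n_distinct(part$module_id), 2)
  members <- module_members(part)
  expect_setequal(members[[1]], sprintf("A%02d", 1:10))
  expect_setequal(members[[2]], sprintf("B%02d", 1:10))
  expect_false(any(part$small))
})

test_that("a module below min_size is retained but flagged small", {
  path3 <- as_interactome(tibble::tibble(protein_a = c("A", "B"),
                                         protein_b = c("B", "C"),
                                         score = 900L))
  part <- detect_modules(path3, max_size = 400, min_size = 5, seed = 1)
  expect_equal(dplyr::n_distinct(part$module_id), 1)
  expect_true(all(part$small))
})

test_that("partition covers every protein exactly once and respects max_size", {
  syn <- generate_synthetic(synthetic_spec(seed = 21))
  g <- syn$data$interactome
  part <- detect_modules(g, max_size = 80, min_size = 5, seed = 4)
  expect_setequal(part$protein, igraph::V(g)$name)
  expect_equal(anyDuplicated(part$protein), 0L)
  sizes <- dplyr::distinct(part, module_id, module_size)
  expect_equal(sum(sizes$module_size), igraph::vcount(g))
  # oversize communities were recursively split (or reported unsplittable)
  oversize <- sizes$module_id[sizes$module_size > 80]
  expect_true(all(oversize %in% attr(part, "unsplittable")))
})

test_that("the same seed reproduces the identical partition", {
  g <- random_interactome(120, 0.08, seed = 2)
  p1 <- detect_modules(g, seed = 9)
  p2 <- detect_modules(g, seed = 9)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("module-graph weights equal brute-force cross-edge counts over a*b", {
  g <- random_interactome(60, 0.12, seed = 6)
  part <- detect_modules(g, max_size = 30, min_size = 2, seed = 3)
  mg <- module_graph(g, part)
  memb <- stats::setNames(part$module_id, part$protein)
  edges <- interactome_edges(g)
  for (i in seq_len(nrow(mg))) {
    ma <- mg$module_a[i]; mb <- mg$module_b[i]
    brute <- sum((memb[edges$protein_a] == ma & memb[edges$protein_b] == mb) |
                 (memb[edges$protein_a] == mb & memb[edges$protein_b] == ma))
    expect_equal(mg$n_edges[i], brute)
    expect_equal(mg$weight[i], brute / (mg$size_a[i] * mg$size_b[i]))
  }
  expect_true(all(mg$weight > 0 & mg$weight <= 1))
})

test_that("a complete bipartite module pair has weight one, no cross edges none", {
  p <- utils::combn(c("A1", "A2", "B1", "B2", "B3"), 2)
  all_edges <- tibble::tibble(protein_a = p[1, ], protein_b = p[2, ],
                              score = 900L)
  in_a <- function(x) startsWith(x, "A")
  cross <- all_edges[in_a(all_edges$protein_a) != in_a(all_edges$protein_b), ]
  g <- as_interactome(cross)
  part <- tibble::tibble(protein = c("A1", "A2", "B1", "B2", "B3"),
                         module_id = c("M1", "M1", "M2", "M2", "M2"),
                         module_size = c(2L, 2L, 3L, 3L, 3L),
                         small = FALSE)
  mg <- module_graph(g, part)
  expect_equal(nrow(mg), 1)
  expect_equal(mg$weight, 1)

  within_only <- as_interactome(tibble::tibble(
    protein_a = c("A1", "B1"), protein_b = c("A2", "B2"), score = 900L))
  part2 <- part[part$protein %in% c("A1", "A2", "B1", "B2"), ]
  part2$module_size <- c(2L, 2L, 2L, 2L)
  expect_equal(nrow(module_graph(within_only, part2)), 0)
})

test_that("module degree ranking matches an independent sort oracle", {
  # star: hub H linked to 4 leaves
  mg <- tibble::tibble(module_a = c("H", "H", "H", "H"),
                       module_b = c("L1", "L2", "L3", "L4"),
                       n_edges = 1L, size_a = 5L, size_b = 5L,
                       weight = 0.04)
  top <- top_degree_modules(mg, 5)
  expect_equal(top$module_id[1], "H")
  expect_equal(top$degree[1], 4)

  set.seed(8)
  rand <- tibble::tibble(module_a = sprintf("M%d", sample(10, 25, TRUE)),
                         module_b = sprintf("M%d", sample(10, 25, TRUE))) |>
    dplyr::filter(module_a != module_b) |>
    dplyr::distinct() |>
    dplyr::mutate(n_edges = 1L, size_a = 5L, size_b = 5L, weight = 0.04)
  top <- top_degree_modules(rand, 100)
  oracle <- sort(table(c(rand$module_a, rand$module_b)), decreasing = TRUE)
  expect_equal(sort(top$degree, decreasing = TRUE), unname(sort(as.integer(oracle), decreasing = TRUE)))
  expect_equal(stats::setNames(top$degree, top$module_id)[names(oracle)],
               stats::setNames(as.integer(oracle), names(oracle)))
})

test_that("singleton components become their own flagged modules", {
  g <- as_interactome(tibble::tibble(protein_a = c("A", "C"),
                                     protein_b = c("B", "D"),
                                     score = 900L))
  g2 <- igraph::add_vertices(g, 1, name = "LONER")
  class(g2) <- class(g)
  part <- detect_modules(g2, max_size = 400, min_size = 3, seed = 1)
  expect_true("LONER" %in% part$protein)
  expect_equal(part$module_size[part$protein == "LONER"], 1L)
  expect_true(all(part$small))
})
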