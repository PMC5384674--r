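test_that("relative risk reproduces the worked module example", {
  st <- module_rr(45, 305, 921, 12084)
  expect_equal(round(st$rr, 2), 1.94)
})

test_that("a module at background density has rr 1 and chi-square 0", {
  st <- module_rr(10, 100, 50, 500)  # 10/100 == 50/500
  expect_equal(st$rr, 1)
  expect_equal(st$chi2, 0, tolerance = 1e-10)
})

test_that("chi-square matches the direct sum((O-E)^2/E) formula on random tables", {
  set.seed(5)
  for (i in 1:25) {
    N <- sample(200:2000, 1)
    m <- sample(20:(N / 2), 1)
    S <- sample(10:(N - m), 1)
    k <- sample(0:min(m, S), 1)
    if (N - m < S - k) next
    st <- module_rr(k, m, S, N)
    O <- matrix(c(k, m - k, S - k, N - m - (S - k)), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(st$chi2, sum((O - E)^2 / E), tolerance = 1e-9)
    expect_equal(st$p_raw, stats::pchisq(st$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("rr is invariant under common scaling of all four counts", {
  a <- module_rr(12, 60, 90, 600)
  b <- module_rr(36, 180, 270, 1800)
  expect_equal(a$rr, b$rr)
})

test_that("rr filtering is boundary-inclusive and anchor mode matches fixed mode", {
  stats_tbl <- dplyr::bind_rows(
    module_rr(45, 305, 921, 12084, module_id = "ANCHOR"),
    module_rr(19, 100, 921, 12084, module_id = "JUST_BELOW"),  # rr 2.49? no
    module_rr(15, 100, 921, 12084, module_id = "ABOVE"))
  stats_tbl$rr[stats_tbl$module_id == "JUST_BELOW"] <- 1.93
  sel <- select_disease_modules(stats_tbl, rr_threshold = 1.94)
  expect_false("JUST_BELOW" %in% sel$module_id)
  anchored <- select_disease_modules(stats_tbl, anchor_module = "ANCHOR")
  fixed <- select_disease_modules(
    stats_tbl, rr_threshold = stats_tbl$rr[stats_tbl$module_id == "ANCHOR"])
  expect_equal(anchored, fixed)
  expect_error(select_disease_modules(stats_tbl, anchor_module = "NOPE"),
               "absent")
  # output is a subset, non-increasing in the threshold
  s1 <- select_disease_modules(stats_tbl, rr_threshold = 1)
  s2 <- select_disease_modules(stats_tbl, rr_threshold = 2)
  expect_true(all(s2$module_id %in% s1$module_id))
  expect_lte(nrow(s2), nrow(s1))
})

test_that("planted disease modules pass the rr filter and decoys do not", {
  # ten disease blocks with 5x the seed density of the ten decoy blocks
  syn <- generate_synthetic(synthetic_spec(
    seed = 2, n_blocks = 20, block_size = 50,
    p_within = 0.4, p_between = 0.003,
    diseases = dplyr::bind_rows(
      tibble::tibble(disease_id = sprintf("DIS%d", 1:10),
                     home_block = 1:10, n_genes = 10L, leak_rate = 0),
      tibble::tibble(disease_id = sprintf("BG%d", 1:10),
                     home_block = 11:20, n_genes = 2L, leak_rate = 0))))
  part <- detect_modules(syn$data$interactome, seed = 2)
  seeds <- unique(syn$data$disease_genes$gene)
  st <- module_disease_stats(part, seeds, background = "all_modules")
  truth <- syn$truth$blocks
  planted_mods <- vapply(1:10, function(b) {
    names(which.max(table(
      part$module_id[part$protein %in% truth$protein[truth$block == b]])))
  }, "")
  sel <- select_disease_modules(st, rr_threshold = 1)
  expect_setequal(sel$module_id, unique(planted_mods))
})

test_that("disease-to-module mapping recovers concentrated and null layouts", {
  part <- tibble::tibble(
    protein = sprintf("P%02d", 1:20),
    module_id = rep(c("M1", "M2"), each = 10),
    module_size = 10L, small = FALSE)
  class(part) <- c("module_partition", class(part))
  conc <- tibble::tibble(disease_id = "D1", gene = sprintf("P%02d", 1:4))
  map <- disease_to_modules(conc, part)
  expect_equal(map$module_id, "M1")
  expect_equal(map$rr, max(map$rr))
  # exactly uniform spread: rr = 1 in both modules, nothing above 1
  unif <- tibble::tibble(disease_id = "D2",
                         gene = c("P01", "P02", "P11", "P12"))
  expect_equal(nrow(disease_to_modules(unif, part, rr_threshold = 1)), 0)
})

test_that("two-disease planted homes are recovered in the module map", {
  syn <- generate_synthetic(synthetic_spec(
    seed = 6,
    diseases = tibble::tibble(disease_id = c("DIS1", "DIS2"),
                              home_block = c(1L, 3L), n_genes = 30L,
                              leak_rate = 0)))
  part <- detect_modules(syn$data$interactome, seed = 6)
  map <- disease_to_modules(syn$data$disease_genes, part, rr_threshold = 1)
  truth <- syn$truth$blocks
  home_mod <- function(b) names(which.max(table(
    part$module_id[part$protein %in% truth$protein[truth$block == b]])))
  top <- map |> dplyr::group_by(disease_id) |>
    dplyr::slice_max(rr, n = 1) |> dplyr::ungroup()
  expect_equal(top$module_id[top$disease_id == "DIS1"], home_mod(1))
  expect_equal(top$module_id[top$disease_id == "DIS2"], home_mod(3))
})

test_that("Jaccard similarity between diseases follows set arithmetic", {
  dg <- tibble::tibble(
    disease_id = c(rep("D1", 3), rep("D2", 3), rep("D3", 3), rep("D4", 3)),
    gene = c("A", "B", "C",  "B", "C", "D",  "A", "B", "C",  "X", "Y", "Z"))
  j <- jaccard_between_diseases(dg)
  pick <- function(a, b) j$jaccard[j$disease_a == a & j$disease_b == b]
  expect_equal(pick("D1", "D2"), 0.5)   # {A,B,C} vs {B,C,D}: 2/4
  expect_equal(pick("D1", "D3"), 1.0)   # identical
  expect_equal(pick("D1", "D4"), 0.0)   # disjoint
})
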