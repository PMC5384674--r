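#' Relative risk and chi-square association of one module with a seed set
#'
#' The relative risk of a module is the ratio of its in-module seed-gene
#' density to the background density: `RR = (k/m) / (S/N)`, where `k` of
#' the module's `m` proteins are seed genes, and `S` of the `N` background
#' proteins are seed genes. Association is additionally tested by a
#' chi-square test (1 df, no continuity correction by default) on the 2x2
#' table `[[k, m-k], [S-k, N-m-(S-k)]]`.
#'
#' @param k Seed genes inside the module.
#' @param m Module size.
#' @param S Total seed genes in the background.
#' @param N Total proteins in the background.
#' @param yates Apply Yates continuity correction? Default `FALSE`.
#' @param module_id Optional label.
#' @return One-row tibble: `module_id`, `m`, `k`, `S`, `N`, `rr`, `chi2`,
#'   `p_raw`.
#' @examples
#' module_rr(45, 305, 921, 12084)  # rr = 1.94 to 2 decimals
#' @export
module_rr <- function(k, m, S, N, yates = FALSE, module_id = NA_character_) {
  if (S <= 0 || N <= 0) abort("S and N must be positive")
  stopifnot(m >= 1, k <= m, k <= S, N >= m, N - m >= S - k)
  rr <- (k / m) / (S / N)
  tab <- matrix(c(k, m - k, S - k, N - m - (S - k)), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("inconsistent counts for the 2x2 table")
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
  } else {
    chi2 <- 0
    p <- 1
  }
  tibble(module_id = module_id, m = as.integer(m), k = as.integer(k),
         S = as.integer(S), N = as.integer(N), rr = rr, chi2 = chi2,
         p_raw = p)
}

#' Per-module disease association statistics
#'
#' Maps a seed-gene set onto a module partition and computes, for every
#' module containing at least one seed gene, the relative risk and
#' chi-square statistics of [module_rr()], plus a Bonferroni-corrected
#' p-value over the number of modules tested. The default background
#' (`"modules_with_seeds"`) counts only proteins and seeds inside modules
#' that contain at least one seed gene; `"all_modules"` uses the whole
#' partition. Modules flagged small are excluded by default.
#'
#' @param partition A `module_partition`.
#' @param seeds Character vector of seed genes.
#' @param background `"modules_with_seeds"` (default) or `"all_modules"`;
#'   ignored when `S` and `N` are given explicitly.
#' @param S,N Optional explicit background counts.
#' @param include_small Include modules flagged `small`? Default `FALSE`.
#' @inheritParams module_rr
#' @return Tibble of per-module statistics sorted by `rr` descending, with
#'   `p_corrected = min(1, p_raw * n_modules_tested)`.
#' @export
module_disease_stats <- function(partition, seeds,
                                 background = c("modules_with_seeds",
                                                "all_modules"),
                                 S = NULL, N = NULL, yates = FALSE,
                                 include_small = FALSE) {
  background <- match.arg(background)
  seeds <- unique(toupper(seeds))
  part <- if (include_small) partition else partition[!partition$small, ]
  part <- as_tibble(part)
  counts <- part %>%
    group_by(.data$module_id) %>%
    summarise(m = n(), k = sum(.data$protein %in% seeds), .groups = "drop")
  with_seed <- counts[counts$k >= 1L, ]
  if (nrow(with_seed) == 0L) {
    warn("no module contains a seed gene")
    return(tibble(module_id = character(), m = integer(), k = integer(),
                  S = integer(), N = integer(), rr = double(),
                  chi2 = double(), p_raw = double(), p_corrected = double()))
  }
  if (is.null(S) || is.null(N)) {
    if (background == "modules_with_seeds") {
      S <- sum(with_seed$k)
      N <- sum(with_seed$m)
    } else {
      S <- sum(counts$k)
      N <- sum(counts$m)
    }
  }
  n_tested <- nrow(with_seed)
  out <- purrr::pmap_dfr(with_seed, function(module_id, m, k) {
    module_rr(k, m, S, N, yates = yates, module_id = module_id)
  }) %>%
    mutate(p_corrected = pmin(1, .data$p_raw * n_tested)) %>%
    arrange(desc(.data$rr), .data$module_id)
  attr(out, "n_modules_tested") <- n_tested
  out
}

#' Filter significant disease modules by relative risk
#'
#' Either a fixed `rr_threshold` or the relative risk of a named anchor
#' module (the convention of taking, as the cutoff, the RR of the last
#' module that survives a conservative chi-square filter) selects the
#' disease modules.
#'
#' @param stats Tibble from [module_disease_stats()].
#' @param rr_threshold Fixed cutoff; modules with `rr >= rr_threshold` pass.
#' @param anchor_module Module id whose `rr` is used as the threshold
#'   (overrides `rr_threshold`).
#' @return Subset of `stats`, sorted by `rr` descending.
#' @export
select_disease_modules <- function(stats, rr_threshold = NULL,
                                   anchor_module = NULL) {
  if (nrow(stats) == 0L) abort("empty statistics table")
  if (!is.null(anchor_module)) {
    hit <- stats$rr[stats$module_id == anchor_module]
    if (length(hit) == 0L) abort(sprintf("anchor module %s absent", anchor_module))
    rr_threshold <- hit[[1L]]
  }
  if (is.null(rr_threshold)) abort("supply rr_threshold or anchor_module")
  stats %>% filter(.data$rr >= rr_threshold) %>% arrange(desc(.data$rr))
}

#' Map disease subtypes to their associated modules
#'
#' For each disease, its mapped genes play the role of the seed set and
#' every module holding at least one of them is scored by relative risk
#' against the whole-partition background; modules with `rr > rr_threshold`
#' are reported.
#'
#' @param dg_map Disease-gene tibble ([load_disease_genes()]).
#' @param partition A `module_partition`.
#' @param rr_threshold Modules with `rr` strictly above this pass
#'   (default 1.0).
#' @param include_small Include modules flagged small? Default `FALSE`.
#' @return Tibble `disease_id`, `module_id`, `rr`, `k`, `m`, sorted by
#'   disease then `rr` descending.
#' @export
disease_to_modules <- function(dg_map, partition, rr_threshold = 1.0,
                               include_small = FALSE) {
  part <- if (include_small) partition else partition[!partition$small, ]
  part <- as_tibble(part)
  N <- nrow(part)
  out <- purrr::map_dfr(split(dg_map$gene, dg_map$disease_id), function(genes) {
    genes <- unique(toupper(genes))
    mapped <- part %>% filter(.data$protein %in% genes)
    if (nrow(mapped) == 0L) {
      warn("disease with no genes mapped to the partition")
      return(tibble(module_id = character(), rr = double(), k = integer(),
                    m = integer()))
    }
    S <- nrow(mapped)
    mapped %>%
      group_by(.data$module_id, .data$module_size) %>%
      summarise(k = n(), .groups = "drop") %>%
      mutate(rr = (.data$k / .data$module_size) / (S / N)) %>%
      filter(.data$rr > rr_threshold) %>%
      select(module_id = "module_id", rr = "rr", k = "k", m = "module_size")
  }, .id = "disease_id")
  out %>% arrange(.data$disease_id, desc(.data$rr), .data$module_id)
}

#' Jaccard similarity of gene sets between disease subtypes
#'
#' `J(A, B) = |genes_A intersect genes_B| / |genes_A union genes_B|` for
#' every unordered pair of diseases.
#'
#' @param dg_map Disease-gene tibble.
#' @return Tibble `disease_a`, `disease_b`, `jaccard`.
#' @export
jaccard_between_diseases <- function(dg_map) {
  sets <- lapply(split(dg_map$gene, dg_map$disease_id),
                 function(g) unique(toupper(g)))
  ids <- sort(names(sets))
  if (length(ids) < 2L) abort("need at least two diseases")
  pairs <- combn(ids, 2L)
  tibble(
    disease_a = pairs[1L, ],
    disease_b = pairs[2L, ],
    jaccard = purrr::map2_dbl(pairs[1L, ], pairs[2L, ], function(a, b) {
      length(intersect(sets[[a]], sets[[b]])) /
        length(union(sets[[a]], sets[[b]]))
    })
  )
}
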