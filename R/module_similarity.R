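#' Functional profiles from enrichment results
#'
#' Turns a module's significant enrichment records into a vector over
#' annotation terms, with entries `-log(p_corrected)` (natural log; the
#' base is irrelevant to cosine similarity, which is scale-invariant).
#' Non-significant terms contribute 0 and are dropped from the long table.
#' Corrected p-values are floored at `p_floor` before the log so that
#' underflowed values (reported as `< 1e-100` by enrichment tools) stay
#' finite.
#'
#' @param records Enrichment tibble (rows from [enrich_module()] bound over
#'   modules and namespaces).
#' @param alpha Significance cutoff on `p_corrected` (default 0.05).
#' @param p_floor Underflow floor for `p_corrected` (default 1e-300).
#' @return Tibble `module_id`, `namespace`, `term_id`, `value` (> 0).
#' @export
functional_profiles <- function(records, alpha = 0.05, p_floor = 1e-300) {
  records %>%
    filter(.data$p_corrected < alpha) %>%
    mutate(value = -log(pmax(.data$p_corrected, p_floor))) %>%
    select("module_id", "namespace", "term_id", "value")
}

#' Cosine similarity of two non-negative term vectors
#'
#' Vectors are named by term id; the union of names defines the shared
#' coordinate space and absent terms contribute 0. If either vector is
#' all-zero (or empty) the similarity is 0 by convention. Because profile
#' values are non-negative the result lies in `[0, 1]`.
#'
#' @param a,b Named numeric vectors of non-negative term weights.
#' @return Cosine similarity in `[0, 1]`.
#' @examples
#' cosine_similarity(c(t1 = 1, t2 = 2), c(t2 = 2, t3 = 1))  # 0.8
#' @export
cosine_similarity <- function(a, b) {
  terms <- union(names(a), names(b))
  if (length(terms) == 0L) return(0)
  av <- bv <- numeric(length(terms))
  names(av) <- names(bv) <- terms
  av[names(a)] <- a
  bv[names(b)] <- b
  na <- sqrt(sum(av^2))
  nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) return(0)
  sum(av * bv) / (na * nb)
}

#' Combined GO/pathway functional-similarity score
#'
#' Half the weight goes to the mean of the three GO-namespace similarities
#' and half to the pathway similarity:
#' `0.5 * ((bp + cc + mf) / 3) + 0.5 * pathway`.
#'
#' @param sim_bp,sim_cc,sim_mf,sim_pathway Per-namespace cosine
#'   similarities, each in `[0, 1]` (vectorized).
#' @return Combined score in `[0, 1]`.
#' @examples
#' combined_score(0.615, 0.557, 0.814, 0.364)  # 0.513 to 3 decimals
#' @export
combined_score <- function(sim_bp, sim_cc, sim_mf, sim_pathway) {
  vals <- c(sim_bp, sim_cc, sim_mf, sim_pathway)
  if (any(vals < 0 | vals > 1)) abort("similarities must lie in [0, 1]")
  0.5 * ((sim_bp + sim_cc + sim_mf) / 3) + 0.5 * sim_pathway
}

#' Pairwise functional similarity between modules
#'
#' Computes, for every unordered pair of modules present in the profiles,
#' the cosine similarity of their enrichment profiles in each namespace
#' (a module without a profile in a namespace contributes the zero vector,
#' giving similarity 0) and the combined score.
#'
#' @param profiles Long profile tibble from [functional_profiles()].
#' @return Tibble `module_a`, `module_b`, `sim_bp`, `sim_cc`, `sim_mf`,
#'   `sim_pathway`, `combined`, sorted by `combined` descending.
#' @export
module_similarity <- function(profiles) {
  mods <- sort(unique(profiles$module_id))
  if (length(mods) < 2L) {
    return(tibble(module_a = character(), module_b = character(),
                  sim_bp = double(), sim_cc = double(), sim_mf = double(),
                  sim_pathway = double(), combined = double()))
  }
  vec_of <- function(mod, ns) {
    sub <- profiles[profiles$module_id == mod & profiles$namespace == ns, ]
    setNames(sub$value, sub$term_id)
  }
  vecs <- lapply(c(BP = "BP", CC = "CC", MF = "MF", pathway = "pathway"),
                 function(ns) lapply(setNames(mods, mods), vec_of, ns = ns))
  pairs <- combn(mods, 2L)
  out <- tibble(
    module_a = pairs[1L, ],
    module_b = pairs[2L, ],
    sim_bp = purrr::map2_dbl(pairs[1L, ], pairs[2L, ],
                             ~cosine_similarity(vecs$BP[[.x]], vecs$BP[[.y]])),
    sim_cc = purrr::map2_dbl(pairs[1L, ], pairs[2L, ],
                             ~cosine_similarity(vecs$CC[[.x]], vecs$CC[[.y]])),
    sim_mf = purrr::map2_dbl(pairs[1L, ], pairs[2L, ],
                             ~cosine_similarity(vecs$MF[[.x]], vecs$MF[[.y]])),
    sim_pathway = purrr::map2_dbl(pairs[1L, ], pairs[2L, ],
                                  ~cosine_similarity(vecs$pathway[[.x]],
                                                     vecs$pathway[[.y]]))
  ) %>%
    mutate(combined = combined_score_vec(.data$sim_bp, .data$sim_cc,
                                         .data$sim_mf, .data$sim_pathway)) %>%
    arrange(desc(.data$combined), .data$module_a, .data$module_b)
  out
}

combined_score_vec <- function(bp, cc, mf, pw) {
  0.5 * ((bp + cc + mf) / 3) + 0.5 * pw
}

#' Cluster modules on the thresholded functional-similarity graph
#'
#' Builds a weighted graph on modules with an edge wherever the combined
#' similarity reaches `min_combined`, then applies weighted Louvain
#' modularity clustering. Modules with no qualifying edge are left
#' unclustered (`cluster = NA`) and counted separately, mirroring analyses
#' in which only the functionally similar subset of disease modules falls
#' into clusters.
#'
#' @param sim_records Tibble from [module_similarity()].
#' @param min_combined Edge threshold on the combined score (default 0.05).
#' @param seed Integer seed for the clustering.
#' @return Tibble `module_id`, `cluster` (integer or `NA`), with attribute
#'   `n_unclustered`.
#' @export
cluster_modules <- function(sim_records, min_combined = 0.05, seed = 1L) {
  mods <- sort(unique(c(sim_records$module_a, sim_records$module_b)))
  keep <- sim_records %>% filter(.data$combined >= min_combined)
  if (nrow(keep) == 0L || length(mods) == 0L) {
    out <- tibble(module_id = mods, cluster = NA_integer_)
    attr(out, "n_unclustered") <- length(mods)
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    keep %>% select("module_a", "module_b", weight = "combined"),
    directed = FALSE, vertices = mods)
  set.seed(seed)
  deg <- igraph::degree(g)
  connected <- igraph::V(g)$name[deg > 0]
  sub <- igraph::induced_subgraph(g, connected)
  cl <- igraph::cluster_louvain(sub, weights = igraph::E(sub)$weight)
  memb <- setNames(as.integer(igraph::membership(cl)), igraph::V(sub)$name)
  out <- tibble(module_id = mods,
                cluster = unname(memb[mods]))
  attr(out, "n_unclustered") <- sum(is.na(out$cluster))
  out
}
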