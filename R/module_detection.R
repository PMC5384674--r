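#' Detect size-bounded topological modules by iterative modularity optimization
#'
#' Runs Louvain modularity maximization on the interactome and recursively
#' re-partitions any community larger than `max_size` on its induced
#' subgraph, so that enrichment analysis operates on communities of workable
#' size. Recursion stops for a community once it fits under `max_size` or
#' the algorithm refuses to split it further (such communities are kept and
#' reported as unsplittable). Communities smaller than `min_size` are
#' retained but flagged `small = TRUE`; downstream enrichment conventionally
#' excludes them rather than forcing merges the algorithm never proposed.
#'
#' @param g An `interactome`.
#' @param max_size Largest acceptable module size (default 400).
#' @param min_size Smallest module size not flagged as small (default 5).
#' @param seed Integer seed; the partition is deterministic for a fixed seed
#'   and input.
#' @param weighted Use confidence scores as Louvain edge weights? Default
#'   `FALSE`: after confidence filtering the graph is treated as binary
#'   topology.
#' @return A `module_partition` tibble: `protein`, `module_id`,
#'   `module_size`, `small`. Module ids `M1, M2, ...` are assigned in order
#'   of each module's lexicographically smallest member. Attributes:
#'   `n_source_nodes`, `unsplittable` (module ids), `seed`.
#' @export
detect_modules <- function(g, max_size = 400, min_size = 5, seed = 1L,
                           weighted = FALSE) {
  if (igraph::vcount(g) == 0L) abort("empty graph")
  stopifnot(max_size > min_size, min_size >= 1)
  set.seed(seed)
  unsplittable_mins <- character()
  finals <- list()

  split_rec <- function(sub) {
    w <- if (weighted) igraph::E(sub)$score else NULL
    # node order fixed by sorted vertex names for reproducibility
    perm <- order(igraph::V(sub)$name)
    sub <- igraph::permute(sub, order(perm))
    cl <- igraph::cluster_louvain(sub, weights = w)
    groups <- split(igraph::V(sub)$name, igraph::membership(cl))
    if (length(groups) == 1L) {
      finals[[length(finals) + 1L]] <<- groups[[1L]]
      if (length(groups[[1L]]) > max_size) {
        unsplittable_mins[length(unsplittable_mins) + 1L] <<- min(groups[[1L]])
      }
      return(invisible())
    }
    for (memb in groups) {
      if (length(memb) <= max_size) {
        finals[[length(finals) + 1L]] <<- memb
      } else {
        split_rec(igraph::induced_subgraph(sub, memb))
      }
    }
  }

  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    members <- igraph::V(g)$name[comp$membership == ci]
    if (length(members) == 1L) {
      finals[[length(finals) + 1L]] <- members
    } else {
      split_rec(igraph::induced_subgraph(g, members))
    }
  }

  mins <- vapply(finals, min, "")
  finals <- finals[order(mins)]
  ids <- paste0("M", seq_along(finals))
  unsplit_ids <- ids[sort(mins) %in% unsplittable_mins]
  if (length(unsplit_ids)) {
    inform(sprintf("unsplittable module(s) above max_size: %s",
                   paste(unsplit_ids, collapse = ", ")))
  }
  out <- tibble(
    protein = unlist(lapply(finals, sort), use.names = FALSE),
    module_id = rep(ids, lengths(finals)),
    module_size = rep(lengths(finals), lengths(finals))
  ) %>%
    mutate(small = .data$module_size < min_size)
  attr(out, "n_source_nodes") <- igraph::vcount(g)
  attr(out, "unsplittable") <- unsplit_ids
  attr(out, "seed") <- seed
  class(out) <- c("module_partition", class(out))
  out
}

#' Per-module member lists from a partition
#'
#' @param partition A `module_partition`.
#' @return Named list of character vectors, one per module id.
#' @export
module_members <- function(partition) {
  split(partition$protein, partition$module_id)
}

#' Build the weighted module-level graph
#'
#' Collapses the interactome to the module level. For every pair of modules
#' joined by at least one interaction the edge weight is `c / (a * b)`,
#' where `c` is the number of interactions crossing between the two modules
#' and `a`, `b` are their member counts; the weight is 1 exactly when every
#' possible cross pair interacts.
#'
#' @param g The `interactome` the partition was computed on.
#' @param partition A `module_partition` covering `g`'s proteins.
#' @return A `module_graph` tibble: `module_a`, `module_b`, `n_edges`,
#'   `size_a`, `size_b`, `weight`, sorted by weight descending.
#' @export
module_graph <- function(g, partition) {
  memb <- setNames(partition$module_id, partition$protein)
  if (!all(igraph::V(g)$name %in% names(memb))) {
    abort("partition does not cover all proteins of the graph")
  }
  sizes <- partition %>% distinct(.data$module_id, .data$module_size)
  size_of <- setNames(sizes$module_size, sizes$module_id)
  el <- igraph::as_edgelist(g)
  ma <- unname(memb[el[, 1L]])
  mb <- unname(memb[el[, 2L]])
  cross <- ma != mb
  if (!any(cross)) {
    out <- tibble(module_a = character(), module_b = character(),
                  n_edges = integer(), size_a = integer(),
                  size_b = integer(), weight = double())
  } else {
    a <- pmin(ma[cross], mb[cross])
    b <- pmax(ma[cross], mb[cross])
    out <- tibble(module_a = a, module_b = b) %>%
      count(.data$module_a, .data$module_b, name = "n_edges") %>%
      mutate(size_a = unname(size_of[.data$module_a]),
             size_b = unname(size_of[.data$module_b]),
             weight = .data$n_edges / (.data$size_a * .data$size_b)) %>%
      arrange(desc(.data$weight), .data$module_a, .data$module_b)
  }
  class(out) <- c("module_graph", class(out))
  out
}

#' Rank modules by degree in the module graph
#'
#' Module degree is the number of other modules a module shares at least one
#' interaction with; high-degree modules are the topological hubs of the
#' disease-module network.
#'
#' @param mg A `module_graph`.
#' @param k Number of top modules to return; if larger than the number of
#'   connected modules, all are returned.
#' @return Tibble `module_id`, `degree`, sorted by degree descending with
#'   ties broken by module id.
#' @export
top_degree_modules <- function(mg, k = 10L) {
  if (nrow(mg) == 0L) abort("empty module graph")
  deg <- tibble(module_id = c(mg$module_a, mg$module_b)) %>%
    count(.data$module_id, name = "degree") %>%
    arrange(desc(.data$degree), .data$module_id)
  head(deg, min(k, nrow(deg)))
}

#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  sizes <- x %>% distinct(.data$module_id, .data$module_size, .data$small)
  tibble(n_modules = nrow(sizes),
         n_proteins = nrow(x),
         n_small = sum(sizes$small),
         max_module_size = max(sizes$module_size),
         n_unsplittable = length(attr(x, "unsplittable")))
}
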