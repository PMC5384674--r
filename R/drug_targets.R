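#' Read a drug-target table
#'
#' Expects a tab-delimited file `drug_id<TAB>target<TAB>class` (class
#' optional, e.g. `AED` for antiepileptic drugs vs `other`); a header row
#' is skipped when present.
#'
#' @param path Path to the TSV file.
#' @return Tibble `drug_id`, `target`, `class`, one row per distinct pair.
#' @export
load_drug_targets <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, fill = TRUE, quote = "")
  if (ncol(raw) < 2L) abort("drug-target table needs at least two columns")
  if (tolower(trimws(raw[1, 1])) %in% c("drug_id", "drug")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  cls <- if (ncol(raw) >= 3L) trimws(raw[[3L]]) else "other"
  cls[!nzchar(cls)] <- "other"
  tibble(drug_id = trimws(raw[[1L]]),
         target = toupper(trimws(raw[[2L]])),
         class = cls) %>%
    distinct(.data$drug_id, .data$target, .keep_all = TRUE)
}

# minimum hop distance from every graph node to the nearest seed
dist_to_seed_set <- function(g, seeds) {
  seeds <- intersect(unique(toupper(seeds)), igraph::V(g)$name)
  if (length(seeds) == 0L) abort("no seed genes mapped to the graph")
  d <- igraph::distances(g, v = seeds, weights = NA)
  apply(d, 2L, min)
}

#' Minimum hop distances from drug targets to the nearest disease seed gene
#'
#' Distances are unweighted shortest-path hop counts (breadth-first search;
#' equivalently Dijkstra on unit edge costs): the number of molecular steps
#' between a drug's target and the nearest disease cause. A target that is
#' itself a seed gene has distance 0. Targets absent from the graph are
#' dropped with a message; targets with no path to any seed are reported
#' with `Inf` and excluded from summary statistics.
#'
#' @param g An `interactome`.
#' @param targets Character vector of drug-target gene symbols.
#' @param seeds Character vector of disease seed genes.
#' @return Tibble `target`, `distance`, with attributes `n_unmapped` and
#'   `n_unreachable`.
#' @export
min_distances <- function(g, targets, seeds) {
  targets <- unique(toupper(targets))
  mapped <- intersect(targets, igraph::V(g)$name)
  n_unmapped <- length(targets) - length(mapped)
  if (length(mapped) == 0L) abort("no targets mapped to the graph")
  if (n_unmapped > 0L) {
    inform(sprintf("%d/%d targets not in the graph were dropped",
                   n_unmapped, length(targets)))
  }
  node_d <- dist_to_seed_set(g, seeds)
  out <- tibble(target = sort(mapped),
                distance = unname(node_d[sort(mapped)]))
  n_unreachable <- sum(is.infinite(out$distance))
  if (n_unreachable > 0L) {
    inform(sprintf("%d target(s) unreachable from any seed", n_unreachable))
  }
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_unreachable") <- n_unreachable
  out
}

#' Network proximity of drug targets to seed genes against a randomized null
#'
#' Compares the observed target-to-seed distance distribution with the
#' distances of `n_samples` random protein sets of the same size drawn from
#' the graph (uniformly by default, or degree-matched: each random protein
#' is drawn from the logarithmic degree bin of the target it replaces).
#' Significance is assessed by a two-sample two-sided t-test of the
#' observed distances against the pooled null distances; classic
#' pooled-variance Student by default, Welch by flag.
#'
#' @inheritParams min_distances
#' @param n_samples Number of randomized protein sets (default 100).
#' @param seed Integer seed; results are deterministic per seed.
#' @param sampling `"uniform"` (default) or `"degree"` (degree-matched).
#' @param var_equal Pooled-variance Student t-test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return A `proximity_result`: list with `observed` (tibble `target`,
#'   `distance`), `null_distances` (list of numeric vectors, one per
#'   sample), `t_statistic`, `p_value`, `n_samples`, `sampling`, `seed`.
#'   Use [tidy()] for per-target rows and [glance()] for the test summary.
#' @export
proximity_null <- function(g, targets, seeds, n_samples = 100, seed = 1L,
                           sampling = c("uniform", "degree"),
                           var_equal = TRUE) {
  sampling <- match.arg(sampling)
  observed <- min_distances(g, targets, seeds)
  n_draw <- nrow(observed)
  nodes <- igraph::V(g)$name
  if (n_draw > length(nodes)) abort("sample size exceeds node count")
  node_d <- dist_to_seed_set(g, seeds)
  set.seed(seed)
  if (sampling == "degree") {
    degs <- igraph::degree(g)
    bin <- floor(log2(pmax(degs, 1)))
    bins <- split(nodes, bin)
    target_bins <- bin[observed$target]
    null_distances <- lapply(seq_len(n_samples), function(i) {
      draw <- vapply(as.character(target_bins), function(b) {
        pool <- bins[[b]]
        pool[sample.int(length(pool), 1L)]
      }, "")
      unname(node_d[draw])
    })
  } else {
    null_distances <- lapply(seq_len(n_samples), function(i) {
      unname(node_d[sample(nodes, n_draw)])
    })
  }
  obs <- observed$distance[is.finite(observed$distance)]
  pooled <- unlist(null_distances)
  pooled <- pooled[is.finite(pooled)]
  tt <- tryCatch(
    t.test(obs, pooled, var.equal = var_equal),
    error = function(e) list(statistic = c(t = 0), p.value = 1)
  )
  structure(list(observed = observed,
                 null_distances = null_distances,
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_samples = n_samples,
                 sampling = sampling,
                 seed = seed),
            class = "proximity_result")
}

#' @method tidy proximity_result
#' @export
tidy.proximity_result <- function(x, ...) {
  x$observed
}

#' @method glance proximity_result
#' @export
glance.proximity_result <- function(x, ...) {
  obs <- x$observed$distance[is.finite(x$observed$distance)]
  pooled <- unlist(x$null_distances)
  pooled <- pooled[is.finite(pooled)]
  tibble(n_targets = nrow(x$observed),
         mean_observed = mean(obs),
         mean_null = mean(pooled),
         t_statistic = x$t_statistic,
         p_value = x$p_value,
         n_samples = x$n_samples,
         sampling = x$sampling)
}

#' @export
print.proximity_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<proximity_result> %d targets; mean distance %.3f vs ",
                     "null %.3f (%d samples, %s); t = %.3f, p = %.3g\n"),
              g$n_targets, g$mean_observed, g$mean_null, g$n_samples,
              g$sampling, g$t_statistic, g$p_value))
  invisible(x)
}

#' Per-module census of drug targets and drugs
#'
#' For every module: the drug targets that are members (direct targets),
#' the targets sitting at hop distance exactly 1 from any of the module's
#' own seed genes while not being members (neighbor targets), the number of
#' distinct drugs with at least one direct target in the module, and that
#' count normalized by module size.
#'
#' @param g An `interactome`.
#' @param partition A `module_partition` covering `g`.
#' @param drug_targets Tibble from [load_drug_targets()].
#' @param seeds Character vector of disease seed genes.
#' @return Tibble `module_id`, `module_size`, `n_direct`, `n_neighbor`,
#'   `n_drugs`, `drugs_per_protein`, plus list columns `direct_targets`
#'   and `neighbor_targets`; sorted by `n_direct` descending.
#' @export
module_census <- function(g, partition, drug_targets, seeds) {
  seeds <- unique(toupper(seeds))
  targets <- unique(drug_targets$target)
  members <- module_members(partition)
  census <- purrr::imap_dfr(members, function(memb, mid) {
    direct <- sort(intersect(targets, memb))
    mod_seeds <- intersect(intersect(seeds, memb), igraph::V(g)$name)
    neigh <- character()
    if (length(mod_seeds) > 0L) {
      nb <- unique(unlist(lapply(igraph::adjacent_vertices(g, mod_seeds),
                                 function(v) igraph::V(g)$name[v])))
      neigh <- sort(setdiff(intersect(targets, nb), memb))
    }
    drugs <- unique(drug_targets$drug_id[drug_targets$target %in% direct])
    tibble(module_id = mid, module_size = length(memb),
           n_direct = length(direct), n_neighbor = length(neigh),
           n_drugs = length(drugs),
           drugs_per_protein = length(drugs) / length(memb),
           direct_targets = list(direct), neighbor_targets = list(neigh))
  })
  census %>% arrange(desc(.data$n_direct), .data$module_id)
}

#' Nominate novel candidate drug targets within a disease module
#'
#' A module member qualifies as a candidate when (1) it lies in the
#' module's most enriched pathway, (2) no antiepileptic drug already
#' targets it, and (3, when an expression table is supplied) it is
#' expressed in at least one of the required tissues — a candidate absent
#' from both the cerebral cortex and the hippocampus cannot act on the
#' seizure-relevant circuitry and is excluded.
#'
#' @param module_members Character vector, the module's proteins.
#' @param top_pathway_genes Character vector, member genes of the module's
#'   most enriched pathway.
#' @param drug_targets Tibble from [load_drug_targets()].
#' @param aed_drug_ids Drug ids considered disease-specific (defaults to
#'   drugs with `class == "AED"` in `drug_targets`).
#' @param expression Optional tibble `gene`, `tissue`, `expressed`
#'   (logical or `"yes"`/`"no"`).
#' @param required_tissues Tissues in which a candidate must be expressed
#'   (any one suffices). Default cerebral cortex and hippocampus.
#' @return Tibble `gene`, sorted; zero rows (with a warning) when the top
#'   pathway is empty.
#' @export
nominate_targets <- function(module_members, top_pathway_genes, drug_targets,
                             aed_drug_ids = NULL, expression = NULL,
                             required_tissues = c("cerebral cortex",
                                                  "hippocampus")) {
  module_members <- unique(toupper(module_members))
  top_pathway_genes <- unique(toupper(top_pathway_genes))
  if (length(top_pathway_genes) == 0L) {
    warn("empty top pathway; no candidates")
    return(tibble(gene = character()))
  }
  if (is.null(aed_drug_ids)) {
    aed_drug_ids <- unique(drug_targets$drug_id[drug_targets$class == "AED"])
  }
  aed_targets <- unique(drug_targets$target[
    drug_targets$drug_id %in% aed_drug_ids])
  cand <- setdiff(intersect(module_members, top_pathway_genes), aed_targets)
  if (!is.null(expression) && length(cand) > 0L) {
    expr <- as_tibble(expression)
    expr$gene <- toupper(trimws(expr$gene))
    expr$tissue <- tolower(trimws(expr$tissue))
    if (!is.logical(expr$expressed)) {
      expr$expressed <- tolower(trimws(expr$expressed)) %in%
        c("yes", "true", "1")
    }
    ok <- expr %>%
      filter(.data$tissue %in% tolower(required_tissues), .data$expressed) %>%
      pull(.data$gene) %>%
      unique()
    cand <- intersect(cand, ok)
  }
  tibble(gene = sort(cand))
}
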