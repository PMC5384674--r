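#' Pipeline configuration
#'
#' Collects every input path and tunable parameter of the end-to-end
#' analysis. All randomness downstream funnels through `seed`.
#'
#' @param edges Path to the PPI edge-list file.
#' @param disease_genes Path to the disease-gene TSV.
#' @param gene_sets Named list of GMT paths for namespaces `BP`, `CC`,
#'   `MF`, `pathway` (any subset).
#' @param drug_targets Path to the drug-target TSV (optional).
#' @param expression Path to the expression TSV (optional).
#' @param score_threshold Confidence cutoff for interactions (default 700).
#' @param min_size,max_size Module size bounds (defaults 5 and 400).
#' @param alpha Enrichment significance level (default 0.05).
#' @param rr_threshold Fixed relative-risk cutoff for disease modules.
#' @param anchor_module Module whose RR supplies the cutoff instead.
#' @param null_samples Randomized samples for the proximity null
#'   (default 100).
#' @param min_combined Edge threshold of the similarity graph
#'   (default 0.05).
#' @param use_largest_component Restrict the analysis to the largest
#'   connected component? Default `FALSE`.
#' @param required_tissues Tissues required for candidate nomination.
#' @param seed Master seed (default 17).
#' @param out_dir Output directory for the report bundle.
#' @return A `netmod_config` list.
#' @export
netmod_config <- function(edges, disease_genes, gene_sets,
                          drug_targets = NULL, expression = NULL,
                          score_threshold = 700, min_size = 5,
                          max_size = 400, alpha = 0.05,
                          rr_threshold = 1.0, anchor_module = NULL,
                          null_samples = 100, min_combined = 0.05,
                          use_largest_component = FALSE,
                          required_tissues = c("cerebral cortex",
                                               "hippocampus"),
                          seed = 17L, out_dir = tempfile("netmod_run_")) {
  stopifnot(score_threshold >= 0, max_size > min_size,
            alpha > 0, alpha <= 1, null_samples >= 1)
  structure(list(edges = edges, disease_genes = disease_genes,
                 gene_sets = gene_sets, drug_targets = drug_targets,
                 expression = expression,
                 score_threshold = score_threshold, min_size = min_size,
                 max_size = max_size, alpha = alpha,
                 rr_threshold = rr_threshold, anchor_module = anchor_module,
                 null_samples = null_samples, min_combined = min_combined,
                 use_largest_component = use_largest_component,
                 required_tissues = required_tissues,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "netmod_config")
}

# 32-bit FNV-1a over the serialized config (minus the output directory,
# so reruns into different directories hash identically), for provenance
config_hash <- function(config) {
  fields <- unclass(config)
  fields$out_dir <- NULL
  bytes <- utf8ToInt(paste(deparse(fields), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    # 32-bit modular multiply by the FNV prime in 16-bit halves, so every
    # intermediate stays below 2^53 and the hash is exact
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_stage <- function(df, path, hash, seed) {
  df <- as_tibble(df)
  listcols <- vapply(df, is.list, TRUE)
  df[listcols] <- lapply(df[listcols], function(col)
    vapply(col, paste, "", collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# netmod config=%s seed=%d", hash, seed), con)
  suppressWarnings(
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  invisible(path)
}

#' Run the full disease-module analysis
#'
#' Executes the pipeline end to end: load and filter the interactome,
#' detect size-bounded modules, score disease association (relative risk
#' and chi-square), enrich the selected disease modules in every supplied
#' namespace, build functional profiles and the combined similarity table,
#' cluster the similarity graph, quantify drug-target proximity against a
#' randomized null, census drugs per module, and nominate novel candidate
#' targets per selected module. Per-stage TSVs (each headed by a comment
#' line naming the config hash and seed), a run log, and a summary are
#' written to `config$out_dir`.
#'
#' @param config A [netmod_config()].
#' @return Invisibly, a named list of all stage results plus `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "netmod_config"))
  hash <- config_hash(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logged <- unclass(config)
  logged$out_dir <- NULL
  log_lines <- c(sprintf("# netmod config=%s seed=%d", hash, config$seed),
                 utils::capture.output(utils::str(logged)))
  writeLines(log_lines, log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  emit <- function(df, file) {
    write_stage(df, file.path(config$out_dir, file), hash, config$seed)
  }

  g <- stage("load_interactome", {
    g <- load_interactome(config$edges, config$score_threshold)
    if (igraph::vcount(g) == 0L) stop("empty graph after filtering")
    if (config$use_largest_component) g <- largest_component(g)
    g
  })
  dg <- stage("load_disease_genes", load_disease_genes(config$disease_genes))
  seeds <- unique(dg$gene)

  partition <- stage("detect_modules",
                     detect_modules(g, max_size = config$max_size,
                                    min_size = config$min_size,
                                    seed = config$seed))
  emit(partition, "modules.tsv")
  mg <- stage("module_graph", module_graph(g, partition))
  emit(mg, "module_graph.tsv")

  stats <- stage("disease_association", module_disease_stats(partition, seeds))
  emit(stats, "disease_module_stats.tsv")
  selected <- stage("select_disease_modules",
                    select_disease_modules(
                      stats, rr_threshold = config$rr_threshold,
                      anchor_module = config$anchor_module))
  emit(selected, "selected_modules.tsv")
  dis_map <- stage("disease_to_modules",
                   disease_to_modules(dg, partition))
  emit(dis_map, "disease_module_map.tsv")

  colls <- stage("load_gene_sets", {
    lapply(setNames(names(config$gene_sets), names(config$gene_sets)),
           function(ns) read_gmt(config$gene_sets[[ns]], namespace = ns))
  })
  members <- module_members(partition)
  enr <- stage("enrichment", {
    purrr::map_dfr(selected$module_id, function(mid) {
      purrr::map_dfr(colls, function(coll) {
        suppressWarnings(enrich_module(members[[mid]], coll,
                                       alpha = config$alpha,
                                       module_id = mid))
      })
    })
  })
  emit(enr, "enrichment.tsv")

  profiles <- stage("functional_profiles",
                    functional_profiles(enr, alpha = config$alpha))
  sim <- stage("module_similarity", module_similarity(profiles))
  emit(sim, "similarity.tsv")
  clusters <- stage("cluster_modules",
                    cluster_modules(sim, min_combined = config$min_combined,
                                    seed = config$seed))
  emit(clusters, "clusters.tsv")

  proximity <- NULL
  census <- NULL
  candidates <- tibble(module_id = character(), gene = character())
  if (!is.null(config$drug_targets)) {
    dt <- stage("load_drug_targets", load_drug_targets(config$drug_targets))
    proximity <- stage("proximity",
                       suppressMessages(proximity_null(
                         g, dt$target, seeds,
                         n_samples = config$null_samples,
                         seed = config$seed)))
    emit(tidy(proximity), "proximity_observed.tsv")
    emit(glance(proximity), "proximity_summary.tsv")
    census <- stage("module_census",
                    module_census(g, partition, dt, seeds))
    emit(census, "census.tsv")
    expr <- NULL
    if (!is.null(config$expression)) {
      expr <- stage("load_expression", {
        e <- utils::read.table(config$expression, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE, quote = "")
        names(e)[1:3] <- c("gene", "tissue", "expressed")
        e
      })
    }
    candidates <- stage("nominate_targets", {
      mod_ids <- if (is.null(colls$pathway)) character() else selected$module_id
      purrr::map_dfr(mod_ids, function(mid) {
        pw <- enr %>% filter(.data$module_id == mid)
        top <- top_term(pw, "pathway")
        if (nrow(top) == 0L || !top$significant) {
          return(tibble(module_id = character(), gene = character()))
        }
        pw_genes <- colls$pathway$sets[[top$term_id]]
        nom <- suppressWarnings(nominate_targets(
          members[[mid]], pw_genes, dt, expression = expr,
          required_tissues = config$required_tissues))
        if (nrow(nom) == 0L) {
          return(tibble(module_id = character(), gene = character()))
        }
        tibble(module_id = mid, gene = nom$gene)
      })
    })
    emit(candidates, "candidates.tsv")
  }

  summary <- tibble(
    n_proteins = igraph::vcount(g),
    n_interactions = igraph::ecount(g),
    n_modules = dplyr::n_distinct(partition$module_id),
    n_selected_modules = nrow(selected),
    n_significant_terms = sum(enr$significant),
    n_clustered = sum(!is.na(clusters$cluster)),
    n_candidates = nrow(candidates),
    proximity_p = if (is.null(proximity)) NA_real_ else proximity$p_value
  )
  emit(summary, "summary.tsv")

  invisible(list(interactome = g, disease_genes = dg, partition = partition,
                 module_graph = mg, stats = stats, selected = selected,
                 disease_module_map = dis_map, enrichment = enr,
                 profiles = profiles, similarity = sim, clusters = clusters,
                 proximity = proximity, census = census,
                 candidates = candidates, summary = summary,
                 config_hash = hash, out_dir = config$out_dir))
}
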