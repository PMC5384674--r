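#' Specification for a synthetic study with planted ground truth
#'
#' Describes a synthetic interactome and its companion inputs so that every
#' pipeline stage can be exercised against known truth: an assortative
#' stochastic-block-model graph whose blocks play the role of topological
#' modules; disease gene sets concentrated in chosen home blocks; annotation
#' terms planted inside blocks against a larger annotated background;
#' drug targets placed at controlled hop distance from the disease seeds;
#' and a tissue-expression table.
#'
#' Default conditions: five blocks of 100 proteins, within-block edge
#' probability 0.3, between-block 0.01; a within-block edge receives a
#' high-confidence score (700-999) with probability 0.9 and a between-block
#' edge with probability 0.3, low-confidence edges scoring 150-699; two
#' diseases of 40 genes each homed in distinct blocks with a 5% leak rate;
#' one planted term of size 30 per block and namespace plus 10 random decoy
#' terms, over an annotated universe padded to 2000 genes; four drugs (two
#' antiepileptic-class) with 5 targets each at hop distance at most 1 from
#' the seeds.
#'
#' @param n_blocks Number of planted blocks.
#' @param block_sizes Integer vector of block sizes (recycled from
#'   `block_size` when omitted).
#' @param block_size Common block size used when `block_sizes` is `NULL`.
#' @param p_within,p_between Within/between-block edge probabilities.
#' @param p_high_within,p_high_between Probability that a within/between
#'   edge scores in the high-confidence range.
#' @param high_range,low_range Inclusive integer score ranges.
#' @param diseases Tibble `disease_id`, `home_block`, `n_genes`,
#'   `leak_rate`.
#' @param term_size Size of each planted term.
#' @param n_decoy_terms Random decoy terms per namespace.
#' @param background_size Total annotated universe size (graph proteins
#'   padded with unconnected background genes).
#' @param drugs Tibble `drug_id`, `class`, `n_targets`, `max_hop`.
#' @param unexpressed_genes Genes reported unexpressed in every tissue.
#' @param tissues Tissues of the expression table.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_blocks = 5, block_sizes = NULL, block_size = 100,
                           p_within = 0.3, p_between = 0.01,
                           p_high_within = 0.9, p_high_between = 0.3,
                           high_range = c(700L, 999L),
                           low_range = c(150L, 699L),
                           diseases = NULL, term_size = 30,
                           n_decoy_terms = 10, background_size = 2000,
                           drugs = NULL, unexpressed_genes = character(),
                           tissues = c("cerebral cortex", "hippocampus"),
                           seed = 1L) {
  if (is.null(block_sizes)) block_sizes <- rep(block_size, n_blocks)
  stopifnot(length(block_sizes) == n_blocks, all(block_sizes >= 1),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1)
  if (is.null(diseases)) {
    diseases <- tibble(disease_id = c("DIS1", "DIS2"),
                       home_block = c(1L, 2L),
                       n_genes = c(40L, 40L),
                       leak_rate = c(0.05, 0.05))
  }
  if (any(diseases$leak_rate == 0 &
          diseases$n_genes > block_sizes[diseases$home_block])) {
    abort("infeasible: n_genes exceeds home block size with zero leak")
  }
  if (is.null(drugs)) {
    drugs <- tibble(drug_id = paste0("DRUG", 1:4),
                    class = c("AED", "AED", "other", "other"),
                    n_targets = rep(5L, 4),
                    max_hop = rep(1L, 4))
  }
  structure(list(n_blocks = n_blocks, block_sizes = block_sizes,
                 p_within = p_within, p_between = p_between,
                 p_high_within = p_high_within,
                 p_high_between = p_high_between,
                 high_range = high_range, low_range = low_range,
                 diseases = diseases, term_size = term_size,
                 n_decoy_terms = n_decoy_terms,
                 background_size = background_size, drugs = drugs,
                 unexpressed_genes = toupper(unexpressed_genes),
                 tissues = tissues, seed = seed),
            class = "synthetic_spec")
}

#' Generate the synthetic study inputs
#'
#' Draws the interactome, disease-gene table, GMT collections (BP, CC, MF,
#' pathway), drug-target table and expression table described by a
#' [synthetic_spec()], optionally writing them in exactly the formats the
#' pipeline consumes. Regenerating with the same spec (same seed) yields
#' byte-identical files.
#'
#' @param spec A `synthetic_spec`.
#' @param outdir Optional directory; when given, writes `ppi_edges.txt`,
#'   `disease_genes.tsv`, `go_bp.gmt`, `go_cc.gmt`, `go_mf.gmt`,
#'   `pathways.gmt`, `drug_targets.tsv`, `expression.tsv`.
#' @return List with `data` (in-memory inputs: `edges`, `interactome`,
#'   `disease_genes`, `collections`, `drug_targets`, `expression`) and
#'   `truth` (planted ground truth: `blocks`, `disease_genes`,
#'   `planted_terms`, `target_distances`), plus `paths` when `outdir` is
#'   given.
#' @export
generate_synthetic <- function(spec, outdir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- sum(spec$block_sizes)
  block <- rep(seq_len(spec$n_blocks), spec$block_sizes)
  proteins <- sprintf("P%04d", seq_len(n))
  truth_blocks <- tibble(protein = proteins, block = block)

  # ---- edges: Bernoulli per pair, assortative; confidence by score law
  pairs <- combn(n, 2L)
  same <- block[pairs[1L, ]] == block[pairs[2L, ]]
  p_edge <- ifelse(same, spec$p_within, spec$p_between)
  keep <- runif(ncol(pairs)) < p_edge
  ia <- pairs[1L, keep]; ib <- pairs[2L, keep]; within <- same[keep]
  p_high <- ifelse(within, spec$p_high_within, spec$p_high_between)
  high <- runif(length(ia)) < p_high
  score <- integer(length(ia))
  score[high] <- sample(spec$high_range[1L]:spec$high_range[2L],
                        sum(high), replace = TRUE)
  score[!high] <- sample(spec$low_range[1L]:spec$low_range[2L],
                         sum(!high), replace = TRUE)
  edges <- tibble(protein_a = proteins[ia], protein_b = proteins[ib],
                  score = score)

  # ---- disease genes concentrated in home blocks
  dg <- purrr::pmap_dfr(spec$diseases,
                        function(disease_id, home_block, n_genes, leak_rate) {
    home <- proteins[block == home_block]
    away <- proteins[block != home_block]
    n_leak <- rbinom(1L, n_genes, leak_rate)
    n_leak <- min(n_leak, length(away))
    n_home <- min(n_genes - n_leak, length(home))
    tibble(disease_id = disease_id,
           gene = c(sample(home, n_home), sample(away, n_leak)))
  })

  # ---- annotation collections: one planted term per block + decoys
  universe <- c(proteins,
                sprintf("BG%04d", seq_len(max(0, spec$background_size - n))))
  make_coll <- function(ns) {
    planted <- lapply(seq_len(spec$n_blocks), function(b) {
      pool <- proteins[block == b]
      sample(pool, min(spec$term_size, length(pool)))
    })
    names(planted) <- sprintf("%s_BLOCK%d", ns, seq_len(spec$n_blocks))
    decoys <- lapply(seq_len(spec$n_decoy_terms), function(i) {
      sample(universe, spec$term_size)
    })
    names(decoys) <- sprintf("%s_DECOY%d", ns, seq_len(spec$n_decoy_terms))
    gene_set_collection(c(planted, decoys), namespace = ns,
                        universe = universe)
  }
  collections <- lapply(c(BP = "BP", CC = "CC", MF = "MF",
                          pathway = "pathway"), make_coll)
  planted_terms <- tibble(
    namespace = rep(c("BP", "CC", "MF", "pathway"), each = spec$n_blocks),
    term_id = unlist(lapply(c("BP", "CC", "MF", "pathway"), function(ns)
      sprintf("%s_BLOCK%d", ns, seq_len(spec$n_blocks)))),
    home_block = rep(seq_len(spec$n_blocks), 4L))

  # ---- drug targets at controlled hop distance from the seed set
  g <- as_interactome(edges, score_threshold = 700)
  seeds_all <- unique(dg$gene)
  node_d <- dist_to_seed_set(g, seeds_all)
  dt <- purrr::pmap_dfr(spec$drugs,
                        function(drug_id, class, n_targets, max_hop) {
    pool <- names(node_d)[is.finite(node_d) & node_d <= max_hop]
    tibble(drug_id = drug_id, class = class,
           target = sample(pool, min(n_targets, length(pool))))
  }) %>% select("drug_id", "target", "class")
  target_distances <- tibble(target = dt$target,
                             distance = unname(node_d[dt$target]))

  # ---- expression table
  expr_genes <- sort(unique(c(proteins, spec$unexpressed_genes)))
  expression <- tidyr::expand_grid(gene = expr_genes,
                                   tissue = spec$tissues) %>%
    mutate(expressed = !(.data$gene %in% spec$unexpressed_genes))

  out <- list(
    data = list(edges = edges, interactome = g, disease_genes = dg,
                collections = collections, drug_targets = dt,
                expression = expression),
    truth = list(blocks = truth_blocks, disease_genes = dg,
                 planted_terms = planted_terms,
                 target_distances = target_distances)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      edges = file.path(outdir, "ppi_edges.txt"),
      disease_genes = file.path(outdir, "disease_genes.tsv"),
      gmt = setNames(file.path(outdir, c("go_bp.gmt", "go_cc.gmt",
                                         "go_mf.gmt", "pathways.gmt")),
                     c("BP", "CC", "MF", "pathway")),
      drug_targets = file.path(outdir, "drug_targets.tsv"),
      expression = file.path(outdir, "expression.tsv")
    )
    utils::write.table(edges, paths$edges, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(dg, paths$disease_genes, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    for (ns in names(collections)) write_gmt(collections[[ns]], paths$gmt[[ns]])
    utils::write.table(dt, paths$drug_targets, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(
      expression %>% mutate(expressed = ifelse(.data$expressed, "yes", "no")),
      paths$expression, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    out$paths <- paths
  }
  out
}
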