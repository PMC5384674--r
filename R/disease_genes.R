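#' Read a disease-gene association table
#'
#' Expects a delimited file whose first two columns are `disease_id` and
#' `gene` (a header containing those names is used when present; extra
#' metadata columns such as MeSH unique IDs are carried along). Associations
#' are deduplicated and gene symbols uppercased.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `"\t"` by default, `","` accepted.
#' @return Tibble with columns `disease_id` and `gene`, one row per distinct
#'   association.
#' @export
load_disease_genes <- function(path, sep = "\t") {
  if (length(readLines(path)) == 0L) {
    warn("empty disease-gene file; returning an empty map")
    return(tibble(disease_id = character(), gene = character()))
  }
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE, fill = TRUE,
                           blank.lines.skip = TRUE, quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    if (nrow(raw) == 0L) {
      warn("empty disease-gene file; returning an empty map")
      return(tibble(disease_id = character(), gene = character()))
    }
    abort("disease-gene table needs at least two columns (disease_id, gene)")
  }
  if (tolower(trimws(raw[1, 1])) %in% c("disease_id", "disease")) {
    raw <- raw[-1L, , drop = FALSE]
  }
  out <- tibble(disease_id = trimws(raw[[1L]]),
                gene = toupper(trimws(raw[[2L]]))) %>%
    filter(nzchar(.data$disease_id), nzchar(.data$gene)) %>%
    distinct()
  inform(sprintf("disease-gene map: %d associations, %d diseases, %d genes",
                 nrow(out), dplyr::n_distinct(out$disease_id),
                 dplyr::n_distinct(out$gene)))
  out
}

#' Number of disease subtypes associated with each gene
#'
#' Counts, per gene, the distinct disease identifiers it is associated with.
#' Most curated disease genes associate with a single subtype; pleiotropic
#' genes (e.g. a sodium-channel subunit shared by ten epilepsy subtypes)
#' stand out at the top of this table.
#'
#' @param dg_map Disease-gene tibble as returned by [load_disease_genes()].
#' @return Tibble `gene`, `n_diseases`, sorted by `n_diseases` descending
#'   then gene.
#' @export
gene_multiplicity <- function(dg_map) {
  if (nrow(dg_map) == 0L) abort("empty disease-gene map")
  dg_map %>%
    distinct(.data$disease_id, .data$gene) %>%
    count(.data$gene, name = "n_diseases") %>%
    arrange(desc(.data$n_diseases), .data$gene)
}

#' Validate a curated gene list against an external reference list
#'
#' Measures how strongly a curated gene set overlaps an independent
#' reference list relative to chance: the fold enrichment is the observed
#' overlap divided by the overlap expected if the reference genes were drawn
#' uniformly from a universe of `universe_size` genes, and the p-value is
#' the one-sided (upper-tail) binomial probability of an overlap at least as
#' large, with `n = |reference|` trials and success probability
#' `|genes| / universe_size`.
#'
#' @param genes Character vector, the curated gene list.
#' @param reference Character vector, the external reference list.
#' @param universe_size Total number of genes the lists are drawn from
#'   (e.g. the number of protein-coding genes).
#' @return One-row tibble: `n_genes`, `n_reference`, `n_overlap`,
#'   `expected`, `fold`, `p_value`, `universe_size`.
#' @examples
#' validate_against_reference(paste0("G", 1:50), paste0("G", 26:75), 1000)
#' @export
validate_against_reference <- function(genes, reference, universe_size) {
  if (universe_size <= 0) abort("universe_size must be positive")
  genes <- unique(toupper(genes))
  reference <- unique(toupper(reference))
  if (universe_size < length(union(genes, reference))) {
    abort("universe_size smaller than the union of the two lists")
  }
  k <- length(intersect(genes, reference))
  expected <- length(reference) * length(genes) / universe_size
  p <- pbinom(k - 1, size = length(reference),
              prob = length(genes) / universe_size, lower.tail = FALSE)
  tibble(n_genes = length(genes), n_reference = length(reference),
         n_overlap = k, expected = expected,
         fold = if (expected > 0) k / expected else NA_real_,
         p_value = p, universe_size = universe_size)
}
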