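#' Read a GMT gene-set file into a collection
#'
#' GMT lines are `term_id<TAB>description<TAB>gene1<TAB>gene2...`. The
#' annotation universe of the collection is the union of all member genes.
#'
#' @param path Path to a GMT file.
#' @param namespace One of `"BP"`, `"CC"`, `"MF"`, `"pathway"`.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, namespace = c("BP", "CC", "MF", "pathway")) {
  namespace <- match.arg(namespace)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort(sprintf("malformed GMT line %d: fewer than 3 fields",
                  which(lengths(parts) < 3L)[1L]))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) abort("duplicate term ids in GMT file")
  sets <- lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
  names(sets) <- ids
  gene_set_collection(sets,
                      descriptions = setNames(vapply(parts, `[[`, "", 2L), ids),
                      namespace = namespace)
}

#' Construct a gene-set collection in memory
#'
#' @param sets Named list of character vectors (term id -> member genes).
#' @param descriptions Optional named character vector of term descriptions.
#' @param namespace Annotation namespace.
#' @param universe Optional annotated-gene universe; defaults to the union
#'   of all member genes.
#' @return A `gene_set_collection` (list with `namespace`, `sets`,
#'   `descriptions`, `universe`).
#' @export
gene_set_collection <- function(sets, descriptions = NULL,
                                namespace = c("BP", "CC", "MF", "pathway"),
                                universe = NULL) {
  namespace <- match.arg(namespace)
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(descriptions)) {
    descriptions <- setNames(names(sets), names(sets))
  }
  structure(list(namespace = namespace, sets = sets,
                 descriptions = descriptions, universe = universe),
            class = "gene_set_collection")
}

#' Write a collection to a GMT file
#'
#' @param coll A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$sets), function(id) {
    paste(c(id, coll$descriptions[[id]], coll$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %s: %d terms, %d annotated genes\n",
              x$namespace, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' The probability of drawing at least `k` annotated genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' This is the over-representation p-value used throughout the enrichment
#' analysis.
#'
#' @param k Observed overlap (vectorized).
#' @param n Query size.
#' @param K Term size.
#' @param N Universe size.
#' @return Probability in `(0, 1]`.
#' @examples
#' hypergeom_upper(4, 4, 5, 10)  # 5/210
#' @export
hypergeom_upper <- function(k, n, K, N) {
  if (any(k < 0 | k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(n, K) <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of a gene set against a collection
#'
#' For a module's member genes, restricts the query to genes annotated in
#' the collection, tests every term with nonzero overlap by the upper-tail
#' hypergeometric probability, and applies Bonferroni correction. The
#' Bonferroni family size defaults to the number of terms actually tested
#' (nonzero overlap, the behaviour of module-level GO tools); set
#' `multiplicity = "all"` to correct over every term in the collection.
#'
#' @param members Character vector of query genes (a module's members).
#' @param coll A `gene_set_collection`.
#' @param alpha Significance level on the corrected p-value (default 0.05).
#' @param multiplicity `"nonzero"` (default) or `"all"`.
#' @param universe Optional explicit universe (e.g. all interactome
#'   proteins); defaults to the collection's annotated universe.
#' @param module_id Optional label carried into the output.
#' @return Tibble of enrichment records: `module_id`, `term_id`,
#'   `description`, `namespace`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_corrected`, `significant`; sorted by `p_corrected` then `term_id`.
#' @export
enrich_module <- function(members, coll, alpha = 0.05,
                          multiplicity = c("nonzero", "all"),
                          universe = NULL, module_id = NA_character_) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(inherits(coll, "gene_set_collection"))
  uni <- if (is.null(universe)) coll$universe else unique(toupper(universe))
  query <- intersect(unique(toupper(members)), uni)
  empty <- tibble(module_id = character(), term_id = character(),
                  description = character(), namespace = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_raw = double(), p_corrected = double(),
                  significant = logical())
  if (length(query) == 0L) {
    warn("no query genes in the annotation universe")
    return(empty)
  }
  N <- length(uni)
  n <- length(query)
  ks <- vapply(coll$sets, function(s) length(intersect(s, query)), 0L)
  Ks <- vapply(coll$sets, function(s) length(intersect(s, uni)), 0L)
  keep <- ks >= 1L
  if (!any(keep)) return(empty)
  m <- if (multiplicity == "nonzero") sum(keep) else length(coll$sets)
  p_raw <- hypergeom_upper(ks[keep], n, Ks[keep], N)
  out <- tibble(
    module_id = module_id,
    term_id = names(coll$sets)[keep],
    description = unname(coll$descriptions[names(coll$sets)[keep]]),
    namespace = coll$namespace,
    k = unname(ks[keep]), n = n, K = unname(Ks[keep]), N = N,
    p_raw = unname(p_raw),
    p_corrected = pmin(1, unname(p_raw) * m)
  ) %>%
    mutate(significant = .data$p_corrected < alpha) %>%
    arrange(.data$p_corrected, .data$term_id)
  attr(out, "bonferroni_m") <- m
  out
}

#' Top enriched term of a namespace
#'
#' @param records Enrichment tibble from [enrich_module()] (possibly
#'   row-bound over modules and namespaces).
#' @param namespace Namespace to look in.
#' @return One-row tibble (minimum corrected p, ties by term id), or a
#'   zero-row tibble when the namespace has no records.
#' @export
top_term <- function(records, namespace) {
  sub <- records %>% filter(.data$namespace == !!namespace)
  if (nrow(sub) == 0L) return(sub)
  sub %>% arrange(.data$p_corrected, .data$term_id) %>% head(1L)
}
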