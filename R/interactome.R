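#' Read and filter a confidence-weighted protein interaction network
#'
#' Parses a STRING-style edge list (one interaction per line:
#' `proteinA proteinB combined_score`, whitespace- or tab-delimited; a header
#' line is skipped automatically when its third field is non-numeric) and
#' returns the undirected network restricted to interactions at or above a
#' confidence threshold. Scores of 700 and above are conventionally regarded
#' as the high-confidence subset of STRING, hence the default.
#'
#' Protein identifiers are normalized to uppercase with surrounding
#' whitespace stripped. Duplicate lines (in either orientation) collapse to a
#' single edge keeping the maximum score; self-loops are dropped with a
#' message reporting how many.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold Integer in `[0, 1000]`; edges with
#'   `score >= score_threshold` are kept (inclusive).
#' @param aliases Optional two-column data frame (or path to a tab-delimited
#'   file) mapping input identifiers to preferred symbols; applied before
#'   deduplication.
#' @return An `interactome`: an undirected [igraph::graph] with an integer
#'   `score` edge attribute and vertices in lexicographic order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A B 800", "B A 750", "B C 650", "C D 900"), tf)
#' g <- load_interactome(tf, score_threshold = 700)
#' glance(g)
#' @export
load_interactome <- function(path, score_threshold = 700, aliases = NULL) {
  stopifnot(is.numeric(score_threshold), length(score_threshold) == 1,
            score_threshold >= 0)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first_data <- 1L
  if (length(lines) >= 1L) {
    fields <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
    if (length(fields) >= 3L && is.na(suppressWarnings(as.numeric(fields[[3L]])))) {
      first_data <- 2L  # header row
    }
  }
  edges <- parse_edge_lines(lines, first_data)
  as_interactome(edges, score_threshold = score_threshold, aliases = aliases)
}

parse_edge_lines <- function(lines, first_data) {
  if (first_data > length(lines)) {
    return(tibble(protein_a = character(), protein_b = character(),
                  score = integer()))
  }
  idx <- seq.int(first_data, length(lines))
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    abort(sprintf("malformed edge line %d: fewer than 3 fields",
                  idx[which(nf < 3L)[1L]]))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(s) || any(s != floor(s))) {
    bad <- which(is.na(s) | s != floor(s))[1L]
    abort(sprintf("malformed edge line %d: score is not an integer", idx[bad]))
  }
  tibble(protein_a = a, protein_b = b, score = as.integer(s))
}

#' Build an interactome from an in-memory edge table
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`, `score`.
#' @inheritParams load_interactome
#' @return An `interactome` object.
#' @export
as_interactome <- function(edges, score_threshold = 0, aliases = NULL) {
  edges <- as_tibble(edges)[, c("protein_a", "protein_b", "score")]
  edges$protein_a <- toupper(trimws(edges$protein_a))
  edges$protein_b <- toupper(trimws(edges$protein_b))
  if (!is.null(aliases)) {
    if (is.character(aliases) && length(aliases) == 1L) {
      aliases <- utils::read.table(aliases, header = FALSE, sep = "\t",
                                   col.names = c("alias", "preferred"),
                                   stringsAsFactors = FALSE)
    }
    map <- setNames(toupper(trimws(aliases[[2L]])), toupper(trimws(aliases[[1L]])))
    hit_a <- edges$protein_a %in% names(map)
    hit_b <- edges$protein_b %in% names(map)
    edges$protein_a[hit_a] <- unname(map[edges$protein_a[hit_a]])
    edges$protein_b[hit_b] <- unname(map[edges$protein_b[hit_b]])
  }
  n_loops <- sum(edges$protein_a == edges$protein_b)
  if (n_loops > 0) {
    inform(sprintf("dropped %d self-loop(s)", n_loops))
    edges <- edges[edges$protein_a != edges$protein_b, ]
  }
  # canonical unordered orientation, then max-score collapse of duplicates
  swap <- edges$protein_a > edges$protein_b
  tmp <- edges$protein_a[swap]
  edges$protein_a[swap] <- edges$protein_b[swap]
  edges$protein_b[swap] <- tmp
  edges <- edges %>%
    group_by(.data$protein_a, .data$protein_b) %>%
    summarise(score = max(.data$score), .groups = "drop")
  edges <- edges[edges$score >= score_threshold, ]
  if (nrow(edges) == 0L) {
    warn("no edges at or above the score threshold; returning an empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    verts <- sort(unique(c(edges$protein_a, edges$protein_b)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
  }
  class(g) <- c("interactome", class(g))
  g
}

#' Write an interactome back to an edge-list file
#'
#' @param g An `interactome`.
#' @param path Output path; tab-delimited `protein_a  protein_b  score`
#'   with a header line.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(g, path) {
  e <- interactome_edges(g)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge table of an interactome
#'
#' @param g An `interactome`.
#' @return Tibble with `protein_a`, `protein_b`, `score`, canonical
#'   orientation (`protein_a < protein_b`), sorted.
#' @export
interactome_edges <- function(g) {
  if (igraph::ecount(g) == 0L) {
    return(tibble(protein_a = character(), protein_b = character(),
                  score = integer()))
  }
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  tibble(protein_a = a, protein_b = b,
         score = as.integer(igraph::E(g)$score)) %>%
    arrange(.data$protein_a, .data$protein_b)
}

#' Restrict an interactome to its largest connected component
#'
#' Ties between equally sized components are broken in favour of the
#' component containing the lexicographically smallest protein identifier.
#'
#' @param g A nonempty `interactome`.
#' @return The induced `interactome` on the largest component.
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0L) abort("empty graph")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(i) {
      min(igraph::V(g)$name[comp$membership == i])
    }, "")
    best <- best[order(firsts)][1L]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  class(sub) <- c("interactome", class(sub))
  sub
}

#' @method glance interactome
#' @export
glance.interactome <- function(x, ...) {
  tibble(n_proteins = igraph::vcount(x),
         n_interactions = igraph::ecount(x),
         n_components = if (igraph::vcount(x)) igraph::components(x)$no else 0L)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d proteins, %d interactions\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}
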