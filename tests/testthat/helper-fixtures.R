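# Small in-code fixtures shared across the test files.

# write an edge-list file from vectors and return its path
edge_file <- function(a, b, score, header = NULL) {
  tf <- tempfile(fileext = ".txt")
  lines <- paste(a, b, score)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, tf)
  tf
}

# interactome made of two k-cliques joined by a single bridge edge
two_clique_graph <- function(k = 10) {
  clique_edges <- function(prefix) {
    nodes <- sprintf("%s%02d", prefix, seq_len(k))
    p <- utils::combn(nodes, 2)
    tibble::tibble(protein_a = p[1, ], protein_b = p[2, ], score = 900L)
  }
  edges <- dplyr::bind_rows(
    clique_edges("A"), clique_edges("B"),
    tibble::tibble(protein_a = "A01", protein_b = "B01", score = 900L))
  suppressWarnings(as_interactome(edges))
}

# Erdos-Renyi interactome with all edges above the confidence cutoff
random_interactome <- function(n, p, seed) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  nodes <- sprintf("N%03d", seq_len(n))
  suppressWarnings(as_interactome(tibble::tibble(
    protein_a = nodes[pairs[1, keep]],
    protein_b = nodes[pairs[2, keep]],
    score = 900L)))
}

# independent breadth-first search oracle: hop distance from one source
bfs_oracle <- function(g, source) {
  nodes <- igraph::V(g)$name
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  frontier <- source
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) {
      nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# independent union-find oracle for connected components
union_find_components <- function(edges, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$protein_a[i]); rb <- find(edges$protein_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(nodes, find, "")
}

# exhaustive hypergeometric upper tail by enumerating every n-subset
enum_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)  # annotated items are 1..K
  mean(overlaps >= k)
}
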