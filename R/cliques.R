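# TAD interaction graph, maximal clique enumeration, per-TAD clique stats.

#' Build the TAD interaction graph
#'
#' Nodes are TAD ids, edges the significant TAD pairs. The graph is simple:
#' duplicate pairs collapse to one edge and self-pairs are rejected.
#'
#' @param pairs Tibble with `tad_a`/`tad_b` columns; when a `significant`
#'   column is present (as returned by [call_significant_interactions()]),
#'   only significant rows become edges.
#' @param nodes Optional character vector of all node ids, so TADs without
#'   significant partners are retained as isolated nodes; defaults to the ids
#'   seen in `pairs`.
#' @return A `tad_graph` object (list with `nodes` and canonical `edges`).
#' @export
build_tad_graph <- function(pairs, nodes = NULL) {
  edges <- as_tibble(pairs)
  if ("significant" %in% names(edges)) {
    edges <- edges %>% filter(.data$significant)
  }
  edges <- edges %>% select("tad_a", "tad_b")
  if (any(edges$tad_a == edges$tad_b)) {
    abort("self-pair in input: a TAD cannot interact with itself")
  }
  a <- pmin(edges$tad_a, edges$tad_b)
  b <- pmax(edges$tad_a, edges$tad_b)
  edges <- distinct(tibble(tad_a = a, tad_b = b)) %>%
    arrange(.data$tad_a, .data$tad_b)
  nodes <- sort(unique(c(nodes, edges$tad_a, edges$tad_b)))
  structure(list(nodes = nodes, edges = edges), class = "tad_graph")
}

#' @export
print.tad_graph <- function(x, ...) {
  cat(sprintf("<tad_graph> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

adjacency_matrix <- function(graph) {
  n <- length(graph$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$tad_a, graph$nodes)
    ib <- match(graph$edges$tad_b, graph$nodes)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  adj
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch with pivoting: at each recursion the pivot is the vertex (of
#' the candidate or excluded set) with the most neighbors among the
#' candidates, and only candidates outside the pivot's neighborhood are
#' branched on. Isolated nodes are reported as maximal cliques of size 1.
#'
#' @param graph A `tad_graph` from [build_tad_graph()].
#' @return List of cliques, each a sorted character vector of TAD ids, in
#'   lexicographic order of their members.
#' @export
maximal_cliques <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0) return(list())
  adj <- adjacency_matrix(graph)
  out <- vector("list", 64)
  n_out <- 0

  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      n_out <<- n_out + 1
      out[[n_out]] <<- r
      return(invisible())
    }
    px <- c(p, x)
    deg_in_p <- vapply(px, function(u) sum(adj[u, p]), numeric(1))
    pivot <- px[which.max(deg_in_p)] # ties: first in node order
    branch <- p[!adj[pivot, p]]
    for (v in branch) {
      bk(c(r, v), p[adj[v, p]], x[adj[v, x]])
      p <- setdiff(p, v)
      x <- c(x, v)
    }
    invisible()
  }

  bk(integer(0), seq_len(n), integer(0))
  cliques <- purrr::map(out[seq_len(n_out)], ~ sort(graph$nodes[.x]))
  cliques[order(purrr::map_chr(cliques, paste, collapse = "\r"))]
}

#' Per-TAD clique statistics and categories
#'
#' For every node: its degree, the size `k` of the largest maximal clique it
#' belongs to, the ratio `k / (degree + 1)` (1 for singletons, smaller the
#' more a TAD interacts outside its clique), and a reporting category:
#' `singleton` (k = 1), `binary` (k = 2), `clique_3` .. `clique_7`, and
#' `clique_8plus` (k >= 8).
#'
#' @param graph A `tad_graph`.
#' @param cliques Maximal cliques of `graph`; computed when `NULL`.
#' @return Tibble: `tad_id`, `degree`, `max_clique_size`, `ratio`, `category`.
#' @export
assign_clique_stats <- function(graph, cliques = NULL) {
  cliques <- cliques %||% maximal_cliques(graph)
  deg <- setNames(rep(0L, length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(graph$edges$tad_a, graph$edges$tad_b))
    deg[names(tab)] <- as.integer(tab)
  }
  k <- setNames(rep(1L, length(graph$nodes)), graph$nodes)
  for (cl in cliques) {
    k[cl] <- pmax(k[cl], length(cl))
  }
  tibble(
    tad_id = graph$nodes,
    degree = unname(deg),
    max_clique_size = unname(k)
  ) %>%
    mutate(
      ratio = .data$max_clique_size / (.data$degree + 1),
      category = clique_category(.data$max_clique_size)
    )
}

clique_category <- function(k) {
  factor(
    dplyr::case_when(
      k <= 1 ~ "singleton",
      k == 2 ~ "binary",
      k >= 8 ~ "clique_8plus",
      TRUE ~ paste0("clique_", k)
    ),
    levels = c("singleton", "binary", paste0("clique_", 3:7), "clique_8plus")
  )
}

#' @method tidy tad_graph
#' @export
tidy.tad_graph <- function(x, ...) {
  x$edges
}

#' @method glance tad_graph
#' @export
glance.tad_graph <- function(x, ...) {
  cl <- maximal_cliques(x)
  sizes <- lengths(cl)
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_maximal_cliques = length(cl),
    max_clique_size = if (length(sizes)) max(sizes) else 0L,
    n_cliques_ge3 = sum(sizes >= 3)
  )
}
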