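# normalize any of the package's graph objects to an edge table + node set
graph_parts <- function(graph) {
  if (inherits(graph, "sf_digraph")) {
    list(nodes = graph$nodes, edges = graph$edges)
  } else if (inherits(graph, "sf_hon")) {
    e <- graph$edges[, c("source_node", "target_node", "weight")]
    names(e) <- c("source", "target", "weight")
    list(nodes = graph$nodes$node, edges = e)
  } else stop("expected an sf_digraph or sf_hon")
}

#' Local and average clustering coefficient
#'
#' The neighbourhood of a node is the union of its in- and out-neighbours;
#' its clustering coefficient is the number of directed edges among the
#' neighbours divided by `k * (k - 1)` (the number of possible directed
#' edges). Nodes with fewer than two neighbours score 0. The average is taken
#' over all nodes.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @param node node label (for `local_cc`).
#' @return `local_cc`: a single proportion. `avg_cc`: the mean over all nodes.
#' @export
local_cc <- function(graph, node) {
  g <- graph_parts(graph)
  if (!node %in% g$nodes) stop("unknown node: ", node)
  unname(local_cc_all(g)[node])
}

#' @rdname local_cc
#' @export
avg_cc <- function(graph) {
  g <- graph_parts(graph)
  if (!length(g$nodes)) return(0)
  mean(local_cc_all(g))
}

local_cc_all <- function(g) {
  nodes <- g$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$edges)) adj[cbind(g$edges$source, g$edges$target)] <- TRUE
  und <- adj | t(adj)
  out <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n)) {
    nb <- which(und[i, ])
    k <- length(nb)
    if (k < 2L) next
    out[i] <- sum(adj[nb, nb]) / (k * (k - 1))
  }
  out
}

#' Graph density
#'
#' `variant = "as_printed"` follows the published formula
#' `|E| / (|V| * |V| / 2)`; `variant = "directed_standard"` is the usual
#' directed density `|E| / (|V| * (|V| - 1))`. A single-node (or empty) graph
#' has density 0.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @param variant density convention.
#' @return a ratio.
#' @export
graph_density <- function(graph, variant = c("as_printed", "directed_standard")) {
  variant <- match.arg(variant)
  g <- graph_parts(graph)
  nv <- length(g$nodes); ne <- nrow(g$edges)
  if (nv <= 1L) return(0)
  switch(variant,
         as_printed = ne / (nv * nv / 2),
         directed_standard = ne / (nv * (nv - 1)))
}

#' Betweenness centrality and Freeman centralization
#'
#' Shortest paths are computed on edge lengths `1 / weight` (inverted
#' transfer probabilities; `length = "minus_log"` uses `-log(weight)`
#' instead). Zero-weight edges are excluded from traversal. Per-node
#' betweenness counts the fraction of shortest paths between ordered pairs
#' `s != v != t` passing through `v`, normalized by `(n - 1)(n - 2) / 2`.
#' Centralization is `2 * sum(max(C') - C'_i) / (n - 1)`.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @param length `"inverse"` (default) or `"minus_log"` edge length.
#' @return `betweenness_centrality`: named numeric vector of normalized
#'   betweenness. `centralization`: a single value.
#' @export
betweenness_centrality <- function(graph, length = c("inverse", "minus_log")) {
  length <- match.arg(length)
  g <- graph_parts(graph)
  n <- length(g$nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  e <- g$edges[g$edges$weight > 0, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(e, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  w <- switch(length, inverse = 1 / e$weight, minus_log = -log(e$weight))
  raw <- igraph::betweenness(ig, directed = TRUE,
                             weights = if (nrow(e)) w else NULL)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  stats::setNames(as.numeric(raw) / norm, g$nodes)[g$nodes]
}

#' @rdname betweenness_centrality
#' @export
centralization <- function(graph, length = c("inverse", "minus_log")) {
  cb <- betweenness_centrality(graph, length)
  n <- length(cb)
  if (n < 2L) return(0)
  2 * sum(max(cb) - cb) / (n - 1)
}

#' Weakly and strongly connected component counts
#'
#' Weak components ignore edge direction; strong components require mutual
#' directed reachability.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @return list with `n_weak` and `n_strong`.
#' @export
components_count <- function(graph) {
  g <- graph_parts(graph)
  if (!length(g$nodes)) return(list(n_weak = 0L, n_strong = 0L))
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  list(n_weak = igraph::count_components(ig, mode = "weak"),
       n_strong = igraph::count_components(ig, mode = "strong"))
}

#' Summary statistics of a risk network
#'
#' Node/edge counts, average degree (`|E| / |V|`), average clustering
#' coefficient, density (both variants), normalized betweenness (mean and
#' per-node), Freeman centralization and component counts.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @return list of class `sf_graph_stats`.
#' @export
graph_stats <- function(graph) {
  g <- graph_parts(graph)
  cb <- betweenness_centrality(graph)
  comp <- components_count(graph)
  structure(list(
    n_nodes = length(g$nodes),
    n_edges = nrow(g$edges),
    avg_degree = if (length(g$nodes)) nrow(g$edges) / length(g$nodes) else 0,
    avg_cc = avg_cc(graph),
    density = graph_density(graph, "as_printed"),
    density_directed = graph_density(graph, "directed_standard"),
    avg_betweenness = if (length(cb)) mean(cb) else 0,
    betweenness = cb,
    centralization = centralization(graph),
    n_weak_cc = comp$n_weak,
    n_strong_cc = comp$n_strong
  ), class = "sf_graph_stats")
}

#' @export
print.sf_graph_stats <- function(x, ...) {
  cat("<sf_graph_stats>\n")
  cat(sprintf("  nodes %d, edges %d, avg degree %.4g\n",
              x$n_nodes, x$n_edges, x$avg_degree))
  cat(sprintf("  avg clustering coefficient %.4g, density %.4g (as printed), %.4g (directed)\n",
              x$avg_cc, x$density, x$density_directed))
  cat(sprintf("  avg betweenness %.4g, centralization %.4g\n",
              x$avg_betweenness, x$centralization))
  cat(sprintf("  components: %d weak, %d strong\n", x$n_weak_cc, x$n_strong_cc))
  invisible(x)
}

#' Realm-level flow matrix
#'
#' Mean inter-port risk aggregated to biogeographic realms: cell
#' `(target realm, source realm)` is the mean of the collapsed pair risks over
#' all ordered cross-port pairs (absent pairs count as risk 0; self-pairs are
#' excluded), min-max normalized over the whole matrix. When all cells are
#' equal the normalization is degenerate and the matrix is set to zero (with
#' attribute `degenerate = TRUE`).
#'
#' @param pairs collapsed pair-risk data.frame (`source`, `target`, `weight`),
#'   e.g. `collapse_to_ports(hon)$pairs`.
#' @param ports port table with `realm_id`.
#' @return matrix (rows = target realms, columns = source realms) in `[0, 1]`.
#' @export
realm_flow <- function(pairs, ports) {
  realms <- sort(unique(ports$realm_id))
  np <- table(factor(ports$realm_id, levels = realms))
  if (any(np == 0)) warning("realm(s) with no ports: ",
                            paste(realms[np == 0], collapse = ", "))
  sr <- ports$realm_id[match(pairs$source, ports$port_id)]
  tr <- ports$realm_id[match(pairs$target, ports$port_id)]
  if (anyNA(sr) || anyNA(tr)) stop("pair references a port absent from the port table")
  sums <- matrix(0, length(realms), length(realms), dimnames = list(realms, realms))
  for (i in seq_len(nrow(pairs))) {
    sums[tr[i], sr[i]] <- sums[tr[i], sr[i]] + pairs$weight[i]
  }
  npv <- as.numeric(np)
  # ordered cross pairs: n_s * n_t off-diagonal, n * (n - 1) within a realm
  denom <- outer(npv, npv)
  diag(denom) <- npv * (npv - 1)
  denom[denom == 0] <- NA
  m <- sums / denom
  m[is.na(m)] <- 0
  rng <- range(m)
  if (rng[2] > rng[1]) {
    m <- (m - rng[1]) / (rng[2] - rng[1])
    attr(m, "degenerate") <- FALSE
  } else {
    m[] <- 0
    attr(m, "degenerate") <- TRUE
  }
  m
}

#' Per-ship-type voyage risk summary
#'
#' Share of voyages (%) and five-number summary plus mean of the voyage-level
#' introduction probabilities, per ship type.
#'
#' @param vrisks output of [voyage_risks()].
#' @return data.frame with `ship_type`, `n`, `share_pct`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`, sorted by decreasing median risk.
#' @export
ship_type_summary <- function(vrisks) {
  stopifnot("prob" %in% names(vrisks))
  sp <- split(vrisks$prob, vrisks$ship_type)
  out <- do.call(rbind, lapply(names(sp), function(ty) {
    q <- stats::quantile(sp[[ty]], c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(ship_type = ty, n = length(sp[[ty]]),
               share_pct = 100 * length(sp[[ty]]) / nrow(vrisks),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               mean = mean(sp[[ty]]))
  }))
  out <- out[order(-out$median, out$ship_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Temporal co-variation of higher-order structure and risk
#'
#' For a list of network snapshots, counts higher-order nodes (order >= 2) and
#' the mean edge risk per snapshot, and reports the Pearson correlation
#' between the two series. With fewer than 3 snapshots, or a constant series,
#' the correlation is undefined and reported as `NA` with a flag.
#'
#' @param snapshots list of `sf_hon` (or `sf_digraph`) objects.
#' @return list with `series` (data.frame `n_higher_order`, `mean_risk`) and
#'   `pearson_r` (possibly `NA`), plus `flag` describing degeneracy.
#' @export
temporal_summary <- function(snapshots) {
  stopifnot(is.list(snapshots), length(snapshots) >= 1L)
  rows <- lapply(snapshots, function(s) {
    g <- graph_parts(s)
    nho <- if (inherits(s, "sf_hon")) sum(s$nodes$order >= 2L) else 0L
    data.frame(n_higher_order = nho,
               mean_risk = if (nrow(g$edges)) mean(g$edges$weight) else 0)
  })
  series <- do.call(rbind, rows)
  flag <- NULL
  r <- NA_real_
  if (nrow(series) < 3L) {
    flag <- "fewer than 3 snapshots; correlation undefined"
  } else if (stats::sd(series$n_higher_order) == 0 || stats::sd(series$mean_risk) == 0) {
    flag <- "constant series; correlation undefined"
  } else {
    r <- stats::cor(series$n_higher_order, series$mean_risk)
  }
  list(series = series, pearson_r = r, flag = flag)
}
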