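#' Weighted directed risk graph
#'
#' Light container for the first-order and All-Paths networks: an edge table
#' `(source, target, weight)` with weights in `[0, 1]`, no self-loops, plus
#' the node set and build metadata.
#'
#' @param edges data.frame with `source`, `target`, `weight`.
#' @param nodes character vector of node labels (defaults to edge endpoints);
#'   isolated declared nodes are kept.
#' @param kind build kind: `"FON"`, `"ALLPATHS"` or `"HON"`.
#' @param vector introduction vector tag (`"ballast"`, `"biofouling"` or `NA`).
#' @return object of class `sf_digraph`.
#' @export
sf_digraph <- function(edges, nodes = NULL, kind = "FON", vector = NA_character_) {
  edges <- as.data.frame(edges)[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$source == edges$target)) stop("self-loops are not allowed")
  if (any(edges$weight < 0 | edges$weight > 1)) stop("edge weights must be in [0, 1]")
  if (anyDuplicated(edge_key(edges$source, edges$target)))
    stop("duplicate edges")
  nodes <- sort(unique(c(edges$source, edges$target, nodes)))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, kind = kind, vector = vector),
            class = "sf_digraph")
}

#' @export
print.sf_digraph <- function(x, ...) {
  cat(sprintf("<sf_digraph:%s%s> %d nodes, %d edges\n", x$kind,
              if (is.na(x$vector)) "" else paste0("/", x$vector),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view (used by the standard metrics)
as_igraph <- function(graph) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.sf_digraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' Build the first-order species-flow network (SF-FON)
#'
#' One node per physical port with at least one incident pair; one directed
#' edge per ordered port pair, weighted by the pairwise spread risk
#' `p_spread`. Zero-weight edges (for example same-ecoregion pairs) are
#' dropped by default.
#'
#' @param pair_risks output of [pair_risks()].
#' @param drop_zero drop edges with zero weight (default `TRUE`).
#' @return an `sf_digraph` of kind `"FON"`.
#' @export
build_fon <- function(pair_risks, drop_zero = TRUE) {
  e <- data.frame(source = pair_risks$source, target = pair_risks$dest,
                  weight = pair_risks$p_spread)
  nodes <- unique(c(e$source, e$target))
  if (drop_zero) e <- e[e$weight > 0, , drop = FALSE]
  vec <- if (nrow(pair_risks)) pair_risks$vector[1L] else NA_character_
  sf_digraph(e, nodes = nodes, kind = "FON", vector = vec)
}

#' Build the All-Paths baseline network
#'
#' Connects every ordered pair of visits along each trajectory, without any
#' significance filtering: for every trajectory and every index pair `a < b`
#' (with `b - a <= max_span`), the subpath spread risk (the Bernoulli union of
#' the consecutive edge risks along the subpath) contributes one Bernoulli
#' term to the ordered pair `(port_a, port_b)`; contributions for the same
#' pair across (and within) trajectories are combined by the same union.
#' Repeated traversals of the same index pair are distinct terms. The result
#' contains every first-order edge plus indirect edges; the weight of any pair
#' is always at least the first-order weight, which is the mechanism by which
#' this baseline over-estimates overall spread risk.
#'
#' @param trajectories `sf_trajectories` or list of port-id vectors.
#' @param edge_risk named risk vector from [edge_risks()].
#' @param max_span maximum index span `b - a` (default `Inf`, the entire
#'   trajectory).
#' @param drop_zero drop zero-weight edges (default `TRUE`).
#' @return an `sf_digraph` of kind `"ALLPATHS"`. Consecutive pairs traversed
#'   without a defined edge risk are treated as risk 0 and counted in the
#'   `missing_edges` attribute.
#' @export
build_all_paths <- function(trajectories, edge_risk, max_span = Inf,
                            drop_zero = TRUE) {
  seqs <- as_port_sequences(trajectories)
  stopifnot(max_span >= 1)
  parts <- vector("list", length(seqs))
  n_missing <- 0L
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]
    m <- length(s)
    if (m < 2L) next
    r <- edge_risk_of(edge_risk, s[-m], s[-1L])
    n_missing <- n_missing + sum(is.na(edge_risk[edge_key(s[-m], s[-1L])]))
    # prefix log-survival: path risk over a..b is 1 - exp(S[b] - S[a])
    S <- c(0, cumsum(log1p(-r)))
    a <- rep.int(1:(m - 1L), pmin(m, 1:(m - 1L) + max_span) - (1:(m - 1L)))
    b <- unlist(lapply(1:(m - 1L), function(i) (i + 1L):min(m, i + max_span)),
                use.names = FALSE)
    parts[[k]] <- data.table::data.table(source = s[a], target = s[b],
                                         lsurv = S[b] - S[a])
  }
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (!length(parts)) {
    return(sf_digraph(data.frame(source = character(), target = character(),
                                 weight = numeric()), kind = "ALLPATHS"))
  }
  dt <- data.table::rbindlist(parts)
  dt <- dt[dt$source != dt$target, ]
  agg <- dt[, list(weight = 1 - exp(sum(lsurv))), by = c("source", "target")]
  e <- as.data.frame(agg)
  nodes <- unique(unlist(seqs, use.names = FALSE))
  if (drop_zero) e <- e[e$weight > 0, , drop = FALSE]
  g <- sf_digraph(e, nodes = nodes, kind = "ALLPATHS")
  attr(g, "missing_edges") <- n_missing
  g
}

#' Read / write a graph edge list
#'
#' CSV schema `source_port,dest_port,weight`, sorted, weights printed with 12
#' significant digits. Reloading reproduces the graph.
#'
#' @param graph an `sf_digraph`.
#' @param path CSV file path.
#' @param kind,vector metadata for the reloaded graph.
#' @return `read_edges` returns an `sf_digraph`.
#' @export
write_edges <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(source_port = e$source, dest_port = e$target,
                    weight = formatC(e$weight, digits = 12, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path, kind = "FON", vector = NA_character_) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sf_digraph(data.frame(source = as.character(x$source_port),
                        target = as.character(x$dest_port),
                        weight = as.numeric(x$weight)),
             kind = kind, vector = vector)
}
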