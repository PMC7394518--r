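#' Stationary visit rates and edge flows of the risk random walk
#'
#' Power iteration on the out-weight-normalized walk with uniform
#' teleportation (probability `teleport`); dangling nodes redistribute their
#' rate uniformly. Edge flows are the non-teleport component
#' `p_i * w_ij / s_i * (no teleportation recorded)`, i.e. teleportation is
#' used only to make the stationary distribution well defined, not counted as
#' inter-module flow ("unrecorded teleportation").
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @param teleport teleportation probability in (0, 1), default 0.15.
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter maximum iterations (default 1e4); non-convergence is an
#'   error reporting the residual.
#' @return list with `rates` (named, sums to 1) and `flows` (data.frame
#'   `source`, `target`, `flow`).
#' @export
stationary_flow <- function(graph, teleport = 0.15, tol = 1e-12, max_iter = 1e4) {
  stopifnot(teleport > 0, teleport < 1)
  g <- graph_parts(graph)
  nodes <- g$nodes
  n <- length(nodes)
  stopifnot(n >= 1L)
  e <- g$edges[g$edges$weight > 0, , drop = FALSE]
  si <- match(e$source, nodes); ti <- match(e$target, nodes)
  outw <- stats::setNames(numeric(n), nodes)
  if (nrow(e)) {
    ow <- tapply(e$weight, e$source, sum)
    outw[names(ow)] <- ow
  }
  trans <- if (nrow(e)) e$weight / outw[e$source] else numeric(0)
  p <- rep(1 / n, n)
  converged <- FALSE
  residual <- NA_real_
  for (it in seq_len(max_iter)) {
    inflow <- numeric(n)
    if (nrow(e)) {
      rs <- rowsum(p[si] * trans, ti)
      inflow[as.integer(rownames(rs))] <- rs
    }
    dangling <- sum(p[outw == 0])
    pn <- teleport / n + (1 - teleport) * (inflow + dangling / n)
    residual <- sum(abs(pn - p))
    p <- pn
    if (residual < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("stationary flow did not converge in %d iterations (residual %.3g)",
                 max_iter, residual))
  rates <- stats::setNames(as.numeric(p) / sum(p), nodes)
  flows <- data.frame(source = e$source, target = e$target,
                      flow = rates[e$source] * trans)
  rownames(flows) <- NULL
  list(rates = rates, flows = flows)
}

# entropy-sum helper: sum x*log2(x) over positive entries
plogp <- function(x) {
  x <- x[x > 0]
  sum(x * log2(x))
}

#' Two-level map equation
#'
#' Description length (bits per step) of a random walk encoded with a
#' two-level codebook under the given partition:
#' `L = q log2 q - 2 sum_m q_m log2 q_m + sum_m (p_m + q_m) log2(p_m + q_m)
#'  - sum_i p_i log2 p_i`, with `p_m` the total visit rate and `q_m` the exit
#' flow of module `m`. When all nodes share one module the index codebook
#' vanishes and `L` equals the entropy of the visit rates.
#'
#' @param partition named integer/character vector: node -> module id (or an
#'   `sf_partition`).
#' @param flow output of [stationary_flow()].
#' @return description length in bits.
#' @export
map_equation <- function(partition, flow) {
  if (inherits(partition, "sf_partition")) partition <- partition$assignment
  rates <- flow$rates
  stopifnot(all(names(rates) %in% names(partition)))
  mod <- as.character(partition[names(rates)])
  mods <- unique(mod)
  p_m <- tapply(rates, mod, sum)[mods]
  if (any(p_m <= 0)) stop("empty module in partition")
  q_m <- stats::setNames(rep(0, length(mods)), mods)
  fl <- flow$flows
  if (nrow(fl)) {
    cross <- mod[match(fl$source, names(rates))] != mod[match(fl$target, names(rates))]
    if (any(cross)) {
      ex <- tapply(fl$flow[cross], mod[match(fl$source[cross], names(rates))], sum)
      q_m[names(ex)] <- ex
    }
  }
  q <- sum(q_m)
  (if (q > 0) q * log2(q) else 0) - 2 * plogp(q_m) +
    plogp(p_m + q_m) - plogp(rates)
}

#' Flow-based clustering by map-equation minimization
#'
#' Greedy optimization of the two-level map equation: nodes start in their own
#' modules; repeated sweeps move each node (in seeded random order) to the
#' neighbouring module that most decreases the description length, followed by
#' module aggregation, until no move helps. The best of `n_restarts` seeded
#' restarts is returned; identical seeds give identical partitions.
#'
#' @param graph `sf_digraph` or `sf_hon`.
#' @param seed integer seed for reproducibility (default 1).
#' @param n_restarts number of restarts (default 10).
#' @param teleport,tol,max_iter passed to [stationary_flow()].
#' @return an object of class `sf_partition`: list with `assignment` (named
#'   vector node -> cluster id, consecutive integers), `port_membership`
#'   (list port -> sorted unique cluster ids; only for `sf_hon` input),
#'   `objective` (bits), `flow`.
#' @export
infomap_cluster <- function(graph, seed = 1L, n_restarts = 10L,
                            teleport = 0.15, tol = 1e-12, max_iter = 1e4) {
  g <- graph_parts(graph)
  nodes <- g$nodes
  n <- length(nodes)
  stopifnot(n >= 1L)
  flow <- stationary_flow(graph, teleport, tol, max_iter)
  rates <- flow$rates
  fl <- flow$flows
  si <- match(fl$source, nodes); ti <- match(fl$target, nodes)

  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  for (r in seq_len(n_restarts)) {
    res <- mapeq_greedy(n, rates, fl$flow, si, ti)
    if (is.null(best) || res$L < best$L - 1e-12) best <- res
  }
  memb <- best$membership
  # relabel clusters to consecutive integers in order of first appearance
  ids <- match(memb, unique(memb))
  assignment <- stats::setNames(ids, nodes)
  port_membership <- NULL
  if (inherits(graph, "sf_hon")) {
    port_membership <- lapply(split(assignment, graph$port_of[nodes]),
                              function(x) sort(unique(unname(x))))
  }
  structure(list(assignment = assignment, port_membership = port_membership,
                 objective = best$L, flow = flow),
            class = "sf_partition")
}

# one greedy local-move + aggregation run over the flow graph
mapeq_greedy <- function(n, rates, eflow, si, ti) {
  # current state at the finest level
  memb <- seq_len(n)
  repeat {
    memb <- local_moves(memb, rates, eflow, si, ti)
    # aggregate modules and rerun moves on the module graph
    agg <- match(memb, unique(memb))
    nm <- max(agg)
    if (nm == length(memb)) break
    arates <- as.numeric(rowsum(unname(rates), agg))
    asrc <- agg[si]; atgt <- agg[ti]
    keep <- asrc != atgt
    if (!any(keep)) break
    key <- paste(asrc[keep], atgt[keep])
    af <- rowsum(eflow[keep], key)
    sp <- strsplit(rownames(af), " ", fixed = TRUE)
    asi <- vapply(sp, function(x) as.integer(x[1L]), integer(1L))
    ati <- vapply(sp, function(x) as.integer(x[2L]), integer(1L))
    memb2 <- local_moves(seq_len(nm), arates, as.numeric(af), asi, ati)
    if (all(memb2 == seq_len(nm))) { memb <- agg; break }
    memb <- memb2[agg]
  }
  L <- mapeq_value(memb, rates, eflow, si, ti)
  list(membership = memb, L = L)
}

mapeq_value <- function(memb, rates, eflow, si, ti) {
  mods <- unique(memb)
  p_m <- as.numeric(rowsum(unname(rates), match(memb, mods)))
  q_m <- numeric(length(mods))
  cross <- memb[si] != memb[ti]
  if (any(cross)) {
    ex <- rowsum(eflow[cross], match(memb[si][cross], mods))
    q_m[as.integer(rownames(ex))] <- ex
  }
  q <- sum(q_m)
  (if (q > 0) q * log2(q) else 0) - 2 * plogp(q_m) + plogp(p_m + q_m) - plogp(rates)
}

# sweep nodes in random order, moving each to the adjacent module that most
# reduces L, until a full sweep makes no move
local_moves <- function(memb, rates, eflow, si, ti) {
  n <- length(memb)
  if (!length(si)) return(memb)
  L <- mapeq_value(memb, rates, eflow, si, ti)
  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      cand <- unique(c(memb[ti[si == v]], memb[si[ti == v]]))
      cand <- setdiff(cand, memb[v])
      if (!length(cand)) next
      bestL <- L; bestm <- memb[v]
      for (m in cand) {
        old <- memb[v]; memb[v] <- m
        Lm <- mapeq_value(memb, rates, eflow, si, ti)
        memb[v] <- old
        if (Lm < bestL - 1e-12) { bestL <- Lm; bestm <- m }
      }
      if (bestm != memb[v]) {
        memb[v] <- bestm
        L <- bestL
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

#' @export
print.sf_partition <- function(x, ...) {
  cat(sprintf("<sf_partition> %d nodes in %d clusters; map equation %.6g bits\n",
              length(x$assignment), length(unique(x$assignment)), x$objective))
  invisible(x)
}

#' Physical-port cluster membership report
#'
#' A port's clusters are the clusters of all its higher-order (and
#' first-order) nodes; a port belongs to multiple clusters when its nodes are
#' split across clusters. Reports the per-port cluster sets, the share of
#' multi-cluster ports, and the port coverage of the largest clusters.
#'
#' @param partition `sf_partition` from [infomap_cluster()].
#' @param hon the `sf_hon` the partition was computed on.
#' @param top_k how many top clusters to report coverage for (default 5).
#' @return list with `port_clusters` (data.frame `port_id`, `cluster_ids`
#'   (";"-joined), `n_clusters`), `multi_share` (fraction of ports in >= 2
#'   clusters) and `top_coverage` (fraction of ports touched by the `top_k`
#'   largest clusters by port count).
#' @export
membership_report <- function(partition, hon, top_k = 5L) {
  stopifnot(inherits(partition, "sf_partition"), inherits(hon, "sf_hon"))
  assignment <- partition$assignment
  ports <- hon$port_of[names(assignment)]
  pc <- lapply(split(unname(assignment), ports), function(x) sort(unique(x)))
  port_clusters <- data.frame(
    port_id = names(pc),
    cluster_ids = vapply(pc, paste, character(1L), collapse = ";"),
    n_clusters = lengths(pc), stringsAsFactors = FALSE)
  rownames(port_clusters) <- NULL
  multi_share <- mean(port_clusters$n_clusters >= 2L)
  cl_ports <- table(unlist(lapply(seq_along(pc), function(i) pc[[i]])))
  top <- names(sort(cl_ports, decreasing = TRUE))[seq_len(min(top_k, length(cl_ports)))]
  covered <- vapply(pc, function(x) any(as.character(x) %in% top), logical(1L))
  list(port_clusters = port_clusters, multi_share = multi_share,
       top_coverage = mean(covered))
}
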