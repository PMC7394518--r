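# Brute-force oracles, independent of the package implementation paths.

# random weighted digraph as an sf_digraph (weights in (0.1, 1), no ties in
# practice, no self-loops)
rand_digraph <- function(n, p = 0.3) {
  nodes <- paste0("n", seq_len(n))
  src <- rep(nodes, each = n)
  tgt <- rep(nodes, n)
  keep <- src != tgt & stats::runif(n * n) < p
  e <- data.frame(source = src[keep], target = tgt[keep],
                  weight = stats::runif(sum(keep), 0.1, 1))
  sf_digraph(e, nodes = nodes)
}

graph_adj <- function(g) {
  n <- length(g$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) adj[cbind(g$edges$source, g$edges$target)] <- TRUE
  adj
}

# Eq-9-style clustering coefficient by explicit neighbour-pair enumeration
oracle_local_cc <- function(g, node) {
  adj <- graph_adj(g)
  nb <- g$nodes[adj[node, ] | adj[, node]]
  nb <- setdiff(nb, node)
  k <- length(nb)
  if (k < 2) return(0)
  cnt <- 0
  for (a in nb) for (b in nb) if (a != b && adj[a, b]) cnt <- cnt + 1
  cnt / (k * (k - 1))
}

# betweenness by exhaustive simple-path enumeration on lengths 1/weight
oracle_betweenness <- function(g, tol = 1e-9) {
  nodes <- g$nodes
  n <- length(nodes)
  e <- g$edges[g$edges$weight > 0, , drop = FALSE]
  out_edges <- split(seq_len(nrow(e)), factor(e$source, levels = nodes))
  acc <- stats::setNames(numeric(n), nodes)
  paths_to <- NULL
  enumerate <- function(v, t, visited, len, path) {
    if (v == t) {
      paths_to[[length(paths_to) + 1L]] <<- list(len = len, path = path)
      return(invisible())
    }
    for (ei in out_edges[[v]]) {
      w <- e$target[ei]
      if (w %in% visited) next
      enumerate(w, t, c(visited, w), len + 1 / e$weight[ei], c(path, w))
    }
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths_to <- list()
    enumerate(s, t, s, 0, s)
    if (!length(paths_to)) next
    lens <- vapply(paths_to, `[[`, numeric(1), "len")
    best <- min(lens)
    sp <- paths_to[lens <= best + tol]
    sigma <- length(sp)
    for (pp in sp) {
      mids <- setdiff(pp$path, c(s, t))
      acc[mids] <- acc[mids] + 1 / sigma
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  acc / norm
}

# component counts via boolean reachability closure
oracle_components <- function(g) {
  adj <- graph_adj(g)
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- reach | (reach %*% (reach + 0) > 0)
  strong <- reach & t(reach)
  und <- adj | t(adj) | diag(TRUE, n)
  wreach <- und
  for (k in seq_len(n)) wreach <- wreach | (wreach %*% (wreach + 0) > 0)
  count_classes <- function(m) {
    seen <- rep(FALSE, n); cnt <- 0
    for (i in seq_len(n)) {
      if (seen[i]) next
      cnt <- cnt + 1
      seen[m[i, ]] <- TRUE
    }
    cnt
  }
  list(n_weak = count_classes(wreach), n_strong = count_classes(strong))
}

# union of independent Bernoulli risks by direct product
oracle_union <- function(p) 1 - prod(1 - p)

# normalized mutual information between two labelings
nmi <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  mi <- 0
  for (i in seq_len(nrow(pij))) for (j in seq_len(ncol(pij))) {
    if (pij[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
  }
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pi_); hb <- h(pj_)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / sqrt(ha * hb)
}

# planted two-block flow network: dense strong within-block edges, one weak
# bridge in each direction
planted_two_block <- function(n_per = 10, p_within = 0.7) {
  blocks <- list(paste0("a", seq_len(n_per)), paste0("b", seq_len(n_per)))
  e <- list()
  for (blk in blocks) {
    for (x in blk) for (y in blk) {
      if (x != y && stats::runif(1) < p_within)
        e[[length(e) + 1L]] <- data.frame(source = x, target = y,
                                          weight = stats::runif(1, 0.6, 1))
    }
  }
  e[[length(e) + 1L]] <- data.frame(source = "a1", target = "b1", weight = 0.02)
  e[[length(e) + 1L]] <- data.frame(source = "b2", target = "a2", weight = 0.02)
  g <- sf_digraph(do.call(rbind, e), nodes = unlist(blocks))
  truth <- stats::setNames(rep(1:2, each = n_per), unlist(blocks))
  list(graph = g, truth = truth)
}

# a tiny fully-specified world shared by io/risk tests
tiny_world <- function() {
  ports <- data.frame(
    port_id = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    name = paste("port", 1:5),
    latitude = c(0, 10, 40, -30, 35),
    longitude = c(0, 20, 90, -60, 150),
    temperature = c(28, 26, 12, 22, 14),
    salinity = c(35, 33, 30, 34, 31),
    ecoregion_id = c("e1", "e2", "e3", "e1", "e3"),
    realm_id = c("r1", "r1", "r2", "r1", "r2"),
    region_id = c("R1", "R1", "R2", "R1", "R2"),
    stringsAsFactors = FALSE)
  eco <- ecoregion_graph(cbind(c("e1"), c("e2")), ports = ports)
  ships <- data.frame(ship_id = c("s1", "s2"),
                      ship_type = c("Container", "Bulk"),
                      gwt = c(20000, 50000), stringsAsFactors = FALSE)
  voyages <- data.frame(
    ship_id = c("s1", "s1", "s2"),
    source = c("AAA", "BBB", "CCC"),
    dest = c("BBB", "CCC", "EEE"),
    sail_date = as.Date(c("2012-05-01", "2012-05-10", "2012-05-02")),
    arrival_date = as.Date(c("2012-05-06", "2012-05-20", "2012-05-09")),
    discharge = c(NA, 500, NA), stringsAsFactors = FALSE)
  list(ports = ports, eco = eco, ships = ships, voyages = voyages)
}
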