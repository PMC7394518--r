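#' Spread probability of a port path
#'
#' The union of the per-edge spread risks along a path `p1 -> p2 -> ... -> pk`:
#' `1 - prod(1 - r_ij)` over consecutive pairs. Edges absent from the lookup
#' contribute risk 0. For a 2-port path this is the edge risk itself; any edge
#' of risk 1 makes the path risk 1; prepending a port can only increase the
#' value (union over a superset of edges).
#'
#' @param path character vector of port ids, length `>= 2`.
#' @param edge_risk named risk vector from [edge_risks()].
#' @return probability in `[0, 1]`.
#' @examples
#' r <- c("C -> A" = 0.1, "A -> E" = 0.2)
#' path_risk(c("C", "A", "E"), r)  # 0.28
#' @export
path_risk <- function(path, edge_risk) {
  m <- length(path)
  if (m < 2L) stop("a path needs at least 2 ports")
  r <- edge_risk_of(edge_risk, path[-m], path[-1L])
  prob_union(r)
}

# ---- rule extraction ------------------------------------------------------

SEP <- "\t"

# counts of (context of k ports, next port) windows across all sequences
window_counts <- function(seqs, k) {
  parts <- lapply(seqs, function(s) {
    m <- length(s)
    if (m < k + 1L) return(NULL)
    e <- embed(s, k + 1L)  # row: (newest ... oldest)
    ctx <- if (k == 1L) e[, 2L] else
      do.call(paste, c(lapply((k + 1L):2L, function(j) e[, j]), sep = SEP))
    data.table::data.table(ctx = ctx, nxt = e[, 1L])
  })
  parts <- parts[!vapply(parts, is.null, logical(1L))]
  if (!length(parts))
    return(data.table::data.table(ctx = character(), nxt = character(),
                                  N = integer()))
  data.table::rbindlist(parts)[, list(N = .N), by = c("ctx", "nxt")]
}

drop_oldest <- function(ctx) sub("^[^\t]*\t", "", ctx)

# path risk of (context ports..., next): vectorized over rows
rule_path_risk <- function(ctx, nxt, edge_risk) {
  vapply(seq_along(ctx), function(i) {
    path_risk(c(strsplit(ctx[i], SEP, fixed = TRUE)[[1L]], nxt[i]), edge_risk)
  }, numeric(1L))
}

#' Extract significant higher-order dependency rules
#'
#' Scans ship trajectories for contexts (recent port histories) whose
#' next-port behaviour genuinely depends on more history than the first-order
#' view, and emits rules `context -> next` carrying the spread probability of
#' the context-plus-next path (the edge-risk union of [path_risk()]).
#'
#' All first-order rules with support `>= min_support` are included. A context
#' of order `k` is extended by one more previous port when the extended
#' context (i) occurs at least `min_support` times, (ii) stays within
#' `max_order`, and (iii) passes the chosen significance criterion; extension
#' applies recursively. Rules are emitted for every (valid context, next) pair
#' observed at least `min_support` times. Output is deterministic given the
#' inputs.
#'
#' Significance criteria:
#' \describe{
#'   \item{`"lrt"` (default)}{a likelihood-ratio (G) test of the extended
#'     context's empirical next-port distribution against its parent context's
#'     distribution; the extension is significant when the chi-square p-value
#'     falls below `alpha`. Higher-order rules are then emitted only for next
#'     ports whose share under the extended context itself differs from the
#'     parent share (1-df G test at the same `alpha`), so a dependent context
#'     does not drag its unremarkable next ports in as rules. This criterion
#'     lets recurring genuine dependencies through while holding the
#'     false-discovery rate on memoryless traffic near `alpha`.}
#'   \item{`"kld"`}{the self-scaling divergence criterion of the HON
#'     framework: extend when `KLD(D_ext || D_parent)` (bits) exceeds
#'     `order_new / log2(1 + support_ext)`.}
#'   \item{`"relative"`}{extend a rule when its path risk rises by more than
#'     `threshold` relatively: `(P_new - P_old)/P_old > threshold` (a zero
#'     `P_old` counts as significant when `P_new > 0`). Note that because the
#'     path risk is a monotone union, this criterion accepts essentially every
#'     frequent extension whose prepended edge carries risk; it is provided
#'     for completeness, not as a usable default.}
#'   \item{`"absolute"`}{as `"relative"` but on `P_new - P_old > threshold`.}
#' }
#'
#' @param trajectories `sf_trajectories` or list of port-id vectors.
#' @param edge_risk named risk vector from [edge_risks()].
#' @param max_order maximum context length (default 5).
#' @param min_support minimum number of traversals for a context or rule
#'   (default 5).
#' @param criterion significance criterion, see above.
#' @param threshold relative/absolute path-risk change threshold (`>= 0`,
#'   default 0.1; used by `"relative"`/`"absolute"` only).
#' @param alpha significance level of the `"lrt"` test (default 0.001).
#' @return an object of class `sf_rules`: data.frame with `context`
#'   (`|`-joined ports, oldest to most recent; the last port is the current
#'   one), `next_port`, `order`, `support`, `probability`.
#' @export
extract_rules <- function(trajectories, edge_risk, max_order = 5,
                          min_support = 5,
                          criterion = c("lrt", "kld", "relative", "absolute"),
                          threshold = 0.1, alpha = 0.001) {
  criterion <- match.arg(criterion)
  stopifnot(max_order >= 1, min_support >= 1)
  if (threshold < 0) stop("threshold must be >= 0")
  stopifnot(alpha > 0, alpha < 1)
  seqs <- as_port_sequences(trajectories)
  counts <- lapply(seq_len(max_order), function(k) window_counts(seqs, k))

  if (criterion %in% c("lrt", "kld")) {
    rules <- extract_rules_dist(counts, edge_risk, max_order, min_support,
                                criterion, alpha)
  } else {
    rules <- extract_rules_risk(counts, edge_risk, max_order, min_support,
                                criterion, threshold)
  }
  rules <- rules[order(rules$order, rules$context, rules$next_port), , drop = FALSE]
  rownames(rules) <- NULL
  class(rules) <- c("sf_rules", "data.frame")
  rules
}

# distribution-based extraction: valid contexts (whole next-step distribution
# test vs the parent context), then rule emission per (ctx, next).
#
# Under "lrt", a higher-order rule is emitted only when its own next-port
# share also differs from the parent's share (1-df G test at the same alpha),
# so a genuinely dependent context does not drag its unremarkable next ports
# in as rules. Under "kld" (the cited HON framework's convention) every next
# of a valid context with enough support becomes a rule.
extract_rules_dist <- function(counts, edge_risk, max_order, min_support,
                               criterion, alpha) {
  c1 <- counts[[1L]]
  valid <- list(unique(c1$ctx))
  emitted <- vector("list", max_order)
  emitted[[1L]] <- {
    keep <- c1[c1$N >= min_support, ]
    if (nrow(keep)) data.frame(ctx = keep$ctx, nxt = keep$nxt, order = 1L,
                               support = keep$N, stringsAsFactors = FALSE)
  }
  if (max_order >= 2L) {
    for (k in 2:max_order) {
      ck <- counts[[k]]
      if (nrow(ck) == 0L) { valid[[k]] <- character(); next }
      tot <- ck[, list(Ntot = sum(N)), by = "ctx"]
      cand <- tot$ctx[tot$Ntot >= min_support]
      cand <- cand[drop_oldest(cand) %in% valid[[k - 1L]]]
      if (!length(cand)) { valid[[k]] <- character(); next }
      parent <- counts[[k - 1L]]
      ptot <- parent[, list(Nptot = sum(N), Kp = .N), by = "ctx"]
      ext <- ck[ck$ctx %in% cand, ]
      ext$pctx <- drop_oldest(ext$ctx)
      ext <- merge(ext, parent, by.x = c("pctx", "nxt"), by.y = c("ctx", "nxt"),
                   suffixes = c("", "_p"))
      ext <- merge(ext, ptot, by.x = "pctx", by.y = "ctx")
      etot <- ext[, list(Ne = sum(N)), by = "ctx"]
      ext <- merge(ext, etot, by = "ctx")
      if (criterion == "lrt") {
        # context test: G = 2 * sum n * ln((n/Ne)/(Np/Nptot)), df = Kp - 1
        stat <- ext[, list(
          G = 2 * sum(N * log((N / Ne) / (N_p / Nptot))),
          df = Kp[1L] - 1L
        ), by = "ctx"]
        ok <- stat$df >= 1L &
          stats::pchisq(stat$G, stat$df, lower.tail = FALSE) < alpha
      } else {
        stat <- ext[, list(
          kld = sum((N / Ne) * log2((N / Ne) / (N_p / Nptot))),
          Ne = Ne[1L]
        ), by = "ctx"]
        ok <- stat$kld > k / log2(1 + stat$Ne)
      }
      valid[[k]] <- stat$ctx[ok]
      em <- ext[ext$ctx %in% valid[[k]] & ext$N >= min_support, ]
      if (nrow(em) && criterion == "lrt") {
        p0 <- em$N_p / em$Nptot
        n1 <- em$N; n0 <- em$Ne - em$N
        g1 <- 2 * (n1 * log(n1 / (em$Ne * p0)) +
                     ifelse(n0 > 0, n0 * log(n0 / (em$Ne * (1 - p0))), 0))
        g1[!is.finite(g1)] <- 0  # p0 == 1 with full agreement
        em <- em[stats::pchisq(g1, 1, lower.tail = FALSE) < alpha, ]
      }
      if (nrow(em))
        emitted[[k]] <- data.frame(ctx = em$ctx, nxt = em$nxt, order = k,
                                   support = em$N, stringsAsFactors = FALSE)
    }
  }
  parts <- emitted[!vapply(emitted, is.null, logical(1L))]
  if (!length(parts))
    return(data.frame(context = character(), next_port = character(),
                      order = integer(), support = integer(),
                      probability = numeric()))
  rules <- do.call(rbind, parts)
  data.frame(context = gsub(SEP, "|", rules$ctx, fixed = TRUE),
             next_port = rules$nxt, order = rules$order, support = rules$support,
             probability = rule_path_risk(rules$ctx, rules$nxt, edge_risk),
             stringsAsFactors = FALSE)
}

# path-risk-change extraction: per-rule recursion, as the spec words it
extract_rules_risk <- function(counts, edge_risk, max_order, min_support,
                               criterion, threshold) {
  c1 <- counts[[1L]][counts[[1L]]$N >= min_support, ]
  rules <- data.frame(ctx = c1$ctx, nxt = c1$nxt, order = 1L, support = c1$N,
                      probability = edge_risk_of(edge_risk, c1$ctx, c1$nxt),
                      stringsAsFactors = FALSE)
  frontier <- rules
  k <- 1L
  while (k < max_order && nrow(frontier)) {
    ck <- counts[[k + 1L]]
    ck <- ck[ck$N >= min_support, ]
    if (nrow(ck) == 0L) break
    pctx <- drop_oldest(ck$ctx)
    idx <- match(paste(pctx, ck$nxt, sep = SEP),
                 paste(frontier$ctx, frontier$nxt, sep = SEP))
    cand <- ck[!is.na(idx), ]
    pprob <- frontier$probability[idx[!is.na(idx)]]
    if (nrow(cand) == 0L) break
    first_two <- vapply(strsplit(cand$ctx, SEP, fixed = TRUE),
                        function(p) edge_risk_of(edge_risk, p[1L], p[2L]),
                        numeric(1L))
    nprob <- 1 - (1 - pprob) * (1 - first_two)
    sig <- if (criterion == "relative") {
      # relative increase is +Inf when a zero-risk path gains any risk
      inc <- ifelse(pprob > 0, (nprob - pprob) / pprob,
                    ifelse(nprob > 0, Inf, 0))
      inc > threshold
    } else {
      (nprob - pprob) > threshold
    }
    frontier <- data.frame(ctx = cand$ctx[sig], nxt = cand$nxt[sig],
                           order = rep(k + 1L, sum(sig)), support = cand$N[sig],
                           probability = nprob[sig], stringsAsFactors = FALSE)
    rules <- rbind(rules, frontier)
    k <- k + 1L
  }
  data.frame(context = gsub(SEP, "|", rules$ctx, fixed = TRUE),
             next_port = rules$nxt, order = rules$order,
             support = rules$support, probability = rules$probability,
             stringsAsFactors = FALSE)
}

#' @export
print.sf_rules <- function(x, ...) {
  cat(sprintf("<sf_rules> %d rules; order counts: %s\n", nrow(x),
              paste(names(table(x$order)), table(x$order), sep = ":",
                    collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' @rdname extract_rules
#' @param rules an `sf_rules` object.
#' @param path CSV file path.
#' @export
write_rules <- function(rules, path) {
  utils::write.csv(data.frame(context = rules$context, next_port = rules$next_port,
                              order = rules$order, support = rules$support,
                              probability = formatC(rules$probability, digits = 12,
                                                    format = "g")),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- network wiring -------------------------------------------------------

split_context <- function(context) strsplit(context, "|", fixed = TRUE)

# node label: first-order = port; higher = "current|oldest,...,previous"
node_label <- function(context_ports) {
  k <- length(context_ports)
  if (k == 1L) return(context_ports)
  paste0(context_ports[k], "|",
         paste(context_ports[-k], collapse = ","))
}

#' Wire the species-flow higher-order network
#'
#' Converts extracted rules into HON nodes and edges. Each rule
#' `context -> next` (context oldest to most recent, last element the current
#' port) creates the source node labelled `current|older,...` and a directed
#' edge of weight equal to the rule probability. The edge target is the
#' highest-order existing node representing `next` whose context is a suffix
#' of the rule's history plus `next`, falling back to the first-order node, so
#' walks through the network stay history-consistent. First-order nodes exist
#' for every port appearing in any rule. A rule
#' `P({p0, p1, p2 -> p3}) = 0.5` yields the edge `p2|p0,p1 -> p3` with weight
#' 0.5.
#'
#' @param rules an `sf_rules` object.
#' @return an object of class `sf_hon`: list with `nodes` (data.frame `node`,
#'   `port`, `order`), `edges` (data.frame `source_node`, `target_node`,
#'   `source_port`, `target_port`, `order`, `weight`), and `port_of` (named
#'   character vector node -> physical port).
#' @export
wire_hon <- function(rules) {
  stopifnot(nrow(rules) >= 1L)
  rules <- rules[order(rules$order, rules$context, rules$next_port), , drop = FALSE]
  ctx_list <- split_context(rules$context)
  all_ports <- unique(c(unlist(ctx_list, use.names = FALSE), rules$next_port))
  if (any(!nzchar(all_ports))) stop("rule references an empty port id")

  ctx_keys <- vapply(ctx_list, paste, character(1L), collapse = "|")
  known_ctx <- unique(c(all_ports, ctx_keys))  # first-order + rule contexts

  node_of_ctx <- function(ports) node_label(ports)
  labels <- vapply(ctx_list, node_of_ctx, character(1L))

  # resolve target: longest suffix of (context, next) that is a known context
  targets <- character(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    hist <- c(ctx_list[[i]], rules$next_port[i])
    h <- length(hist)
    for (L in (h:1)) {
      tail_ctx <- hist[(h - L + 1L):h]
      if (paste(tail_ctx, collapse = "|") %in% known_ctx) {
        targets[i] <- node_of_ctx(tail_ctx)
        break
      }
    }
  }

  node_port <- function(lbl) sub("\\|.*$", "", lbl)
  nodes <- unique(data.frame(
    node = c(all_ports, labels, targets),
    stringsAsFactors = FALSE))
  nodes$port <- node_port(nodes$node)
  # order = number of context ports = commas + 2 when there is any history
  has_hist <- grepl("|", nodes$node, fixed = TRUE)
  n_commas <- ifelse(has_hist,
                     vapply(gregexpr(",", nodes$node, fixed = TRUE),
                            function(m) sum(m > 0L), integer(1L)), 0L)
  nodes$order <- ifelse(has_hist, n_commas + 2L, 1L)
  nodes <- nodes[order(nodes$order, nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- data.frame(
    source_node = labels, target_node = targets,
    source_port = node_port(labels), target_port = node_port(targets),
    order = rules$order, weight = rules$probability,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source_node, edges$target_node), , drop = FALSE]
  rownames(edges) <- NULL
  if (anyDuplicated(paste(edges$source_node, edges$target_node, sep = SEP)))
    stop("internal error: duplicate HON edges")

  structure(list(nodes = nodes,
                 edges = edges,
                 port_of = stats::setNames(nodes$port, nodes$node)),
            class = "sf_hon")
}

#' @export
print.sf_hon <- function(x, ...) {
  cat(sprintf("<sf_hon> %d nodes (%d higher-order) over %d ports; %d edges\n",
              nrow(x$nodes), sum(x$nodes$order >= 2L),
              length(unique(x$nodes$port)), nrow(x$edges)))
  invisible(x)
}

#' @export
as_igraph.sf_hon <- function(graph) {
  e <- graph$edges[, c("source_node", "target_node", "weight")]
  names(e) <- c("source", "target", "weight")
  igraph::graph_from_data_frame(e, directed = TRUE,
                                vertices = data.frame(name = graph$nodes$node))
}

#' Collapse a higher-order network to physical ports
#'
#' Combines all HON edges whose endpoints map to the same ordered physical
#' port pair (default: probabilistic union `1 - prod(1 - w)`), and the in-risk
#' of each port as the same combination of all edges incoming to any of its
#' nodes. Zero-weight edges are excluded from risk outputs.
#'
#' @param hon an `sf_hon` (or an `sf_digraph`, treated as one node per port).
#' @param mode `"union"`, `"sum"` or `"mean"`.
#' @return list with `pairs` (data.frame `source`, `target`, `weight`,
#'   `n_edges`) and `port_in` (named numeric vector of per-port incoming
#'   risk).
#' @export
collapse_to_ports <- function(hon, mode = c("union", "sum", "mean")) {
  mode <- match.arg(mode)
  if (inherits(hon, "sf_digraph")) {
    e <- data.frame(source_port = hon$edges$source,
                    target_port = hon$edges$target,
                    weight = hon$edges$weight, stringsAsFactors = FALSE)
    ports <- hon$nodes
  } else {
    e <- hon$edges[, c("source_port", "target_port", "weight")]
    ports <- unique(hon$nodes$port)
  }
  e <- e[e$weight > 0, , drop = FALSE]
  comb <- switch(mode,
                 union = function(w) -expm1(sum(log1p(-pmin(w, 1)))) + 0,
                 sum = sum,
                 mean = mean)
  dt <- data.table::as.data.table(e)
  pairs <- dt[, list(weight = comb(weight), n_edges = .N),
              by = c("source_port", "target_port")]
  pairs <- as.data.frame(pairs[order(pairs$source_port, pairs$target_port), ])
  names(pairs) <- c("source", "target", "weight", "n_edges")
  pin <- dt[, list(w = comb(weight)), by = "target_port"]
  port_in <- stats::setNames(rep(0, length(ports)), sort(ports))
  port_in[pin$target_port] <- pin$w
  list(pairs = pairs, port_in = port_in)
}

#' Per-port incoming risk over a full port table
#'
#' Collapses a network to physical ports and returns the per-port incoming
#' risk for *every* port in `ports`, zero-filling ports that the network does
#' not reach. Use this (rather than raw [collapse_to_ports()]) when comparing
#' models over a common region set.
#'
#' @param graph `sf_hon` or `sf_digraph`.
#' @param ports port table.
#' @param mode combination mode, see [collapse_to_ports()].
#' @return named numeric vector over `ports$port_id`.
#' @export
port_in_risk <- function(graph, ports, mode = "union") {
  v <- collapse_to_ports(graph, mode)$port_in
  out <- stats::setNames(numeric(nrow(ports)), ports$port_id)
  known <- intersect(names(v), ports$port_id)
  out[known] <- v[known]
  out
}
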