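test_that("path risk is the union of consecutive edge risks", {
  r <- c("C -> A" = 0.1, "A -> E" = 0.2)
  expect_equal(path_risk(c("C", "A"), r), 0.1)
  expect_equal(path_risk(c("C", "A", "E"), r), 0.28, tolerance = 1e-12)
  expect_error(path_risk("C", r), "at least 2")
  # absorbing edge of risk 1
  rr <- c("C -> A" = 0.1, "A -> E" = 0.2, "E -> F" = 1)
  expect_equal(path_risk(c("C", "A", "E", "F"), rr), 1)
  # missing edges contribute zero risk
  expect_equal(path_risk(c("X", "Y"), r), 0)
})

test_that("extended-path risk never falls below its suffix-path risk", {
  set.seed(41)
  ports <- paste0("p", 1:8)
  for (i in 1:100) {
    risks <- runif(20, 0, 0.9)
    names(risks) <- replicate(20, paste(sample(ports, 2), collapse = " -> "))
    path <- sample(ports, sample(3:6, 1))
    ext <- c(sample(ports, 1), path)
    expect_gte(path_risk(ext, risks) + 1e-15, path_risk(path, risks))
  }
})

test_that("no higher-order rules emerge from a memoryless chain", {
  cfg <- synth_config(n_ports = 20, n_ecoregions = 4, n_realms = 2,
                      n_regions = 4, n_ships = 20, n_voyages = 10000, seed = 314)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk)
  expect_lt(sum(rules$order >= 2) / nrow(rules), 0.01)
})

test_that("planted dependencies are recovered; patterns below support are not", {
  cfg <- hub_scenario_config(seed = 99)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk)
  got <- paste(rules$context, rules$next_port)
  for (pr in cfg$planted_rules) {
    expect_true(paste(paste(pr$context, collapse = "|"), pr$next_port) %in% got)
  }
  expect_true(all(rules$support >= 5))
  # a hand-built corpus: context seen min_support - 1 times stays absent
  seqs <- c(replicate(4, c("C", "A", "E"), simplify = FALSE),
            replicate(50, c("X", "A", sample(c("E", "F", "G", "H"), 1)),
                      simplify = FALSE))
  r2 <- extract_rules(seqs, c("C -> A" = .2, "A -> E" = .2), min_support = 5)
  expect_false(any(r2$order >= 2 & grepl("C", r2$context)))
})

test_that("rule probabilities are suffix-monotone and support-gated", {
  cfg <- hub_scenario_config(seed = 3)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk)
  hi <- rules[rules$order > 1, ]
  if (nrow(hi)) {
    key <- paste(rules$context, rules$next_port)
    for (i in seq_len(nrow(hi))) {
      suffix <- sub("^[^|]*\\|?", "", hi$context[i])
      j <- which(key == paste(suffix, hi$next_port[i]))
      if (length(j)) expect_gte(hi$probability[i] + 1e-15, rules$probability[j])
    }
  }
})

test_that("relative-change criterion with huge threshold degenerates to first order", {
  cfg <- hub_scenario_config(seed = 5)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk,
                         criterion = "relative", threshold = Inf)
  expect_true(all(rules$order == 1L))
  fon <- build_fon(truth$pair_risks)
  hon <- wire_hon(rules)
  # first-order-only rule set wires a graph whose collapsed pairs sit inside FON
  cp <- collapse_to_ports(hon)$pairs
  fkey <- paste(fon$edges$source, fon$edges$target)
  hkey <- paste(cp$source, cp$target)
  expect_true(all(hkey %in% fkey))
  m <- match(hkey, fkey)
  expect_equal(cp$weight, fon$edges$weight[m], tolerance = 1e-12)
})

test_that("wiring follows the worked example and stays history-consistent", {
  rules <- data.frame(
    context = c("p0", "p1", "p2", "p0|p1|p2", "p3"),
    next_port = c("p1", "p2", "p3", "p3", "p0"),
    order = c(1, 1, 1, 3, 1), support = 10,
    probability = c(0.1, 0.2, 0.3, 0.5, 0.05))
  class(rules) <- c("sf_rules", "data.frame")
  hon <- wire_hon(rules)
  e <- hon$edges
  worked <- e[e$source_node == "p2|p0,p1", ]
  expect_equal(worked$target_node, "p3")
  expect_equal(worked$weight, 0.5)
  expect_equal(unname(hon$port_of["p2|p0,p1"]), "p2")
  expect_equal(hon$nodes$order[hon$nodes$node == "p2|p0,p1"], 3L)
})

test_that("the wired edge targets the highest-order context-consistent node", {
  # rule (a,b -> c) must point at c|b when the context (b, c) exists as a rule
  rules <- data.frame(
    context = c("a", "b", "c", "a|b", "b|c"),
    next_port = c("b", "c", "d", "c", "d"),
    order = c(1, 1, 1, 2, 2), support = 10,
    probability = c(.1, .2, .3, .25, .35))
  class(rules) <- c("sf_rules", "data.frame")
  hon <- wire_hon(rules)
  e <- hon$edges
  expect_equal(e$target_node[e$source_node == "b|a"], "c|b")
  expect_equal(e$target_node[e$source_node == "c|b"], "d")
})

test_that("wiring is deterministic under rule-order permutation", {
  cfg <- hub_scenario_config(seed = 8)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk)
  h1 <- wire_hon(rules)
  set.seed(1)
  h2 <- wire_hon(rules[sample(nrow(rules)), ])
  expect_identical(h1$edges, h2$edges)
  expect_identical(h1$nodes, h2$nodes)
})

test_that("collapse to ports matches exhaustive union over parallel edges", {
  rules <- data.frame(
    context = c("a", "b", "a|b", "c"),
    next_port = c("b", "c", "c", "a"),
    order = c(1, 1, 2, 1), support = 5,
    probability = c(.2, .3, .45, .1))
  class(rules) <- c("sf_rules", "data.frame")
  hon <- wire_hon(rules)
  cp <- collapse_to_ports(hon)
  bc <- cp$pairs$weight[cp$pairs$source == "b" & cp$pairs$target == "c"]
  expect_equal(bc, oracle_union(c(0.3, 0.45)), tolerance = 1e-12)
  expect_equal(unname(cp$port_in["c"]), oracle_union(c(0.3, 0.45)), tolerance = 1e-12)
  # sum and mean modes
  expect_equal(collapse_to_ports(hon, "sum")$pairs$weight[
    cp$pairs$source == "b" & cp$pairs$target == "c"], 0.75)
  expect_equal(collapse_to_ports(hon, "mean")$pairs$weight[
    cp$pairs$source == "b" & cp$pairs$target == "c"], 0.375)
  expect_error(collapse_to_ports(hon, "median"))
  # brute-force union over random small HONs (<= 6 parallel edges)
  set.seed(51)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    w <- runif(k)
    expect_equal(1 - exp(sum(log1p(-w))), oracle_union(w), tolerance = 1e-12)
  }
})

test_that("rules serialize to csv and reload consistently", {
  cfg <- hub_scenario_config(seed = 2)
  sc <- gen_scenario(cfg)
  truth <- true_port_risk(sc, "ballast")
  rules <- extract_rules(sc$trajectories, truth$edge_risk)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, f)
  r2 <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(r2), nrow(rules))
  expect_equal(r2$support, rules$support)
  expect_equal(r2$probability, rules$probability, tolerance = 1e-10)
})
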