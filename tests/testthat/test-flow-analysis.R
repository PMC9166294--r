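# Current-flow solver: closed forms, conservation, oracle equivalence,
# interactor flow and cross-condition comparison

test_that("potentials obey Ohm's law and series resistance", {
  # single edge of conductance 2: potential difference 1/2
  g <- graph_from_weights(matrix(c(0, 2, 2, 0), 2, 2,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  v <- solve_potentials(flow_network(g, "A", "B"))
  expect_equal(unname(v["A"] - v["B"]), 0.5, tolerance = 1e-12)
  # chain of two unit edges: end-to-end difference 2
  gs <- make_toy_graph("series", n = 3)
  fs <- information_flow(gs, "N01", "N03")
  expect_equal(fs$effective_resistance, 2, tolerance = 1e-10)
  expect_equal(unname(fs$throughflow["N02"]), 1, tolerance = 1e-10)
})

test_that("current divider splits by conductance ratio", {
  g <- make_toy_graph("parallel", conductances = c(1, 3))
  fl <- information_flow(g, "S", "T")
  expect_equal(unname(fl$throughflow["M1"]), 0.25, tolerance = 1e-10)
  expect_equal(unname(fl$throughflow["M2"]), 0.75, tolerance = 1e-10)
  # harmonic combination of the branch resistances: R = 1/(1/2 + 3/2)
  expect_equal(fl$effective_resistance, 0.5, tolerance = 1e-10)
})

test_that("a balanced Wheatstone bridge carries no bridge current", {
  g <- make_toy_graph("wheatstone")
  fl <- information_flow(g, "S", "T")
  expect_lt(abs(fl$currents["A", "B"]), 1e-10)
  # unbalancing one arm sends current through the bridge
  g2 <- make_toy_graph("wheatstone", arm = 1)
  g2$weights["S", "A"] <- g2$weights["A", "S"] <- 2
  fl2 <- information_flow(g2, "S", "T")
  expect_gt(abs(fl2$currents["A", "B"]), 1e-3)
})

test_that("conservation holds: unit current in, unit current out, KCL inside", {
  fixtures <- list(
    make_toy_graph("series", n = 5),
    make_toy_graph("parallel", conductances = c(1, 3)),
    make_toy_graph("wheatstone"),
    make_toy_graph("random", seed = 7)
  )
  for (g in fixtures) {
    n <- length(g$labels)
    src <- g$labels[1]; snk <- g$labels[n]
    fl <- information_flow(g, src, snk)
    net <- rowSums(fl$currents)
    expect_equal(unname(net[src]), 1, tolerance = 1e-9)
    expect_equal(unname(net[snk]), -1, tolerance = 1e-9)
    interior <- setdiff(g$labels, c(src, snk))
    expect_true(all(abs(net[interior]) < 1e-9))
    expect_true(all(fl$throughflow >= 0))
    expect_true(all(fl$throughflow[interior] <= 1 + 1e-9))
  }
})

test_that("multi-source injection splits equally and balances", {
  g <- make_toy_graph("random", seed = 13)
  labs <- g$labels
  src <- labs[1:3]; snk <- labs[(length(labs) - 1):length(labs)]
  fl <- information_flow(g, src, snk)
  net <- rowSums(fl$currents)
  expect_equal(unname(net[src]), rep(1 / 3, 3), tolerance = 1e-9)
  expect_equal(sum(net[snk]), -1, tolerance = 1e-9)
  expect_equal(unname(fl$throughflow[src]), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("grounded solve matches the dense pseudoinverse oracle on random graphs", {
  for (seed in 1:60) {
    g <- make_toy_graph("random", seed = seed)
    labs <- g$labels
    src <- labs[1]; snk <- labs[length(labs)]
    fl <- information_flow(g, src, snk)
    or <- oracle_flow(g$weights, src, snk)
    expect_lt(max(abs(fl$throughflow - or$throughflow)), 1e-8)
    expect_lt(abs(fl$effective_resistance - or$effective_resistance), 1e-8)
    # gauge invariance: potentials agree up to an additive constant
    shift <- fl$potentials - or$potentials
    expect_lt(diff(range(shift)), 1e-8)
  }
})

test_that("Rayleigh monotonicity: raising any conductance never raises resistance", {
  g <- make_toy_graph("random", seed = 21)
  labs <- g$labels
  base <- information_flow(g, labs[1], labs[length(labs)])$effective_resistance
  edges <- which(upper.tri(g$weights) & g$weights > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    g2 <- g
    i <- edges[e, 1]; j <- edges[e, 2]
    g2$weights[i, j] <- g2$weights[j, i] <- g2$weights[i, j] * 2
    r2 <- information_flow(g2, labs[1],
                           labs[length(labs)])$effective_resistance
    expect_lte(r2, base + 1e-12)
  }
})

test_that("adding a bypass route reduces flow through the original path", {
  W <- matrix(0, 5, 5,
              dimnames = list(c("S", "B", "T", "P1", "P2"),
                              c("S", "B", "T", "P1", "P2")))
  W["S", "B"] <- W["B", "S"] <- 1; W["B", "T"] <- W["T", "B"] <- 1
  g_path <- graph_from_weights(W)
  f1 <- information_flow(g_path, "S", "T")
  expect_equal(unname(f1$throughflow["B"]), 1, tolerance = 1e-10)
  W["S", "P1"] <- W["P1", "S"] <- 1; W["P1", "P2"] <- W["P2", "P1"] <- 1
  W["P2", "T"] <- W["T", "P2"] <- 1
  f2 <- information_flow(graph_from_weights(W), "S", "T")
  expect_lt(unname(f2$throughflow["B"]), 1)
})

test_that("interactor flow covers bridges, dead ends and symmetric splits", {
  mk <- function(W, inter) graph_from_weights(
    W, kinds = ifelse(rownames(W) %in% inter, "interactor", "residue"))
  # sole bridge: all current passes
  W <- matrix(0, 3, 3, dimnames = rep(list(c("S", "X", "T")), 2))
  W["S", "X"] <- W["X", "S"] <- 1; W["X", "T"] <- W["T", "X"] <- 1
  fl <- information_flow(mk(W, "X"), "S", "T")
  expect_equal(interactor_flow(fl, "X"), 1, tolerance = 1e-10)
  # dangling interactor off the path carries nothing
  W2 <- matrix(0, 4, 4, dimnames = rep(list(c("S", "M", "T", "X")), 2))
  W2["S", "M"] <- W2["M", "S"] <- 1; W2["M", "T"] <- W2["T", "M"] <- 1
  W2["M", "X"] <- W2["X", "M"] <- 1
  fl2 <- information_flow(mk(W2, "X"), "S", "T")
  expect_lt(interactor_flow(fl2, "X"), 1e-12)
  # two symmetric parallel interactor bridges: 0.5 each
  W3 <- matrix(0, 4, 4, dimnames = rep(list(c("S", "X1", "X2", "T")), 2))
  for (x in c("X1", "X2")) {
    W3["S", x] <- W3[x, "S"] <- 1; W3[x, "T"] <- W3["T", x] <- 1
  }
  fl3 <- information_flow(mk(W3, c("X1", "X2")), "S", "T")
  expect_equal(interactor_flow(fl3, "X1"), 0.5, tolerance = 1e-10)
  expect_equal(interactor_flow(fl3, "X2"), 0.5, tolerance = 1e-10)
  expect_error(interactor_flow(fl3, "NOPE"), class = "pathflow_lookup_error")
  expect_error(interactor_flow(fl3, "S"), class = "pathflow_usage_error")
})

test_that("disconnected source/sink pairs raise a connectivity error", {
  W <- matrix(0, 4, 4, dimnames = rep(list(c("A", "B", "C", "D")), 2))
  W["A", "B"] <- W["B", "A"] <- 1
  W["C", "D"] <- W["D", "C"] <- 1
  g <- graph_from_weights(W)
  expect_error(information_flow(g, "A", "C"),
               class = "pathflow_connectivity_error")
  expect_error(flow_network(g, "A", "A"), class = "pathflow_usage_error")
  expect_error(flow_network(g, "A", "ZZ"), class = "pathflow_lookup_error")
})

test_that("condition comparison reports mean, SEM and deltas; absences stay NA", {
  fake_result <- function(vals, kinds = NULL) {
    structure(list(labels = names(vals),
                   kinds = kinds %||% rep("residue", length(vals)),
                   throughflow = vals),
              class = "flow_result")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  reps <- lapply(c(0.4, 0.5, 0.6), function(v)
    fake_result(c(N1 = v, N2 = 0.2)))
  same <- lapply(1:3, function(i) fake_result(c(N1 = 0.3, N2 = 0.2)))
  cmp <- compare_states(list(apo = same, holo = reps))
  expect_identical(attr(cmp, "reference"), "apo")
  apo_rows <- cmp[cmp$condition == "apo", ]
  expect_equal(apo_rows$sem, c(0, 0))
  holo_n1 <- cmp[cmp$condition == "holo" & cmp$node_label == "N1", ]
  expect_equal(holo_n1$mean, 0.5)
  expect_equal(holo_n1$sem, 0.1 / sqrt(3), tolerance = 1e-10)
  expect_equal(holo_n1$sem, 0.0577, tolerance = 1e-3)
  expect_equal(holo_n1$delta, 0.2)
  # an interactor absent from one condition is NA there, not 0
  with_x <- list(fake_result(c(N1 = 0.3, X = 0.9),
                             kinds = c("residue", "interactor")))
  cmp2 <- compare_states(list(apo = same, bound = with_x))
  expect_true(is.na(cmp2[cmp2$condition == "apo" &
                           cmp2$node_label == "X", "mean"]))
  # single replicate: SEM is NA, not 0
  expect_true(is.na(cmp2[cmp2$condition == "bound" &
                           cmp2$node_label == "X", "sem"]))
  expect_error(compare_states(list(a = reps), reference = "zzz"),
               class = "pathflow_usage_error")
  expect_error(compare_states(list(a = list())),
               class = "pathflow_usage_error")
})

test_that("flow_result behaves like a fitted-model object", {
  g <- make_toy_graph("parallel", conductances = c(1, 3))
  fl <- information_flow(g, "S", "T")
  expect_s3_class(fl, "flow_result")
  expect_named(coef(fl), g$labels)
  df <- as.data.frame(fl)
  expect_setequal(df$role, c("source", "sink", "interior"))
  expect_output(print(fl), "effective resistance")
  expect_output(print(summary(fl)), "Current-flow")
  path <- tempfile(fileext = ".csv")
  write_flow_result(fl, path, graph = g)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".manifest.json")))
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(man$total_injected, 1)
})
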