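test_that("intervening on a node never changes its own causes", {
  set.seed(21)
  X <- cbind(X = rnorm(100), Y = rnorm(100))
  d <- dag(c("X", "Y"), rbind(c("Y", "X")))
  expect_identical(causal_effect_in_dag(as_expr(X), d, "X", "Y"), 0)
})

test_that("the direct effect is recovered from data of a two-node model", {
  edges <- data.frame(from = "X", to = "Y", weight = 0.7)
  X <- sem_data(c("X", "Y"), edges, n = 5000, seed = 31)
  d <- dag(c("X", "Y"), rbind(c("X", "Y")))
  est <- causal_effect_in_dag(as_expr(X), d, "X", "Y")
  expect_lt(abs(est - 0.7), 0.05)
})

test_that("parent adjustment removes confounding that the marginal keeps", {
  edges <- data.frame(from = c("Z", "Z", "X"), to = c("X", "Y", "Y"),
                      weight = c(1, 1, 0.5))
  X <- sem_data(c("Z", "X", "Y"), edges, n = 10000, seed = 32)
  d <- dag(c("Z", "X", "Y"), rbind(c("Z", "X"), c("Z", "Y"), c("X", "Y")))
  adjusted <- causal_effect_in_dag(as_expr(X), d, "X", "Y")
  expect_lt(abs(adjusted - 0.5), 0.05)
  # path analysis of the linear model: marginal slope = 0.5 + 1*1/(1+1) = 1
  marginal <- unname(stats::coef(stats::lm(X[, "Y"] ~ X[, "X"]))[2L])
  expect_lt(abs(marginal - 1), 0.05)
})

test_that("collinear designs raise an informative error", {
  set.seed(33)
  z <- rnorm(50)
  X <- cbind(Z1 = z, Z2 = z, X = rnorm(50), Y = rnorm(50))
  d <- dag(colnames(X), rbind(c("Z1", "X"), c("Z2", "X"), c("X", "Y")))
  expect_error(causal_effect_in_dag(as_expr(X), d, "X", "Y"),
               "rank-deficient")
})

test_that("local parent sets are the knowledge-compatible neighbour cliques", {
  # cause X: directed parent P; siblings a (adjacent to P), b (adjacent
  # to P), a and b non-adjacent; sibling c not adjacent to P.
  g <- pdag(c("P", "X", "a", "b", "c"),
            directed = rbind(c("P", "X"), c("P", "a"), c("P", "b")),
            undirected = rbind(c("a", "X"), c("b", "X"), c("c", "X")))
  sets <- valid_parent_sets(g, "X")
  keys <- vapply(sets, paste, character(1), collapse = ",")
  expect_setequal(keys, c("P", "P,a", "P,b"))
})

test_that("a fully directed graph needs no enumeration", {
  edges <- data.frame(from = "X", to = "Y", weight = 0.7)
  X <- sem_data(c("X", "Y"), edges, n = 1000, seed = 34)
  g <- pdag(c("X", "Y"), directed = rbind(c("X", "Y")))
  d <- dag(c("X", "Y"), rbind(c("X", "Y")))
  expect_equal(causal_effect_bound(as_expr(X), g, "X", "Y"),
               causal_effect_in_dag(as_expr(X), d, "X", "Y"))
})

test_that("an undirected direct edge forces a zero lower bound", {
  edges <- data.frame(from = "A", to = "B", weight = 0.9)
  X <- sem_data(c("A", "B"), edges, n = 1000, seed = 35)
  g <- pdag(c("A", "B"), undirected = rbind(c("A", "B")))
  expect_identical(causal_effect_bound(as_expr(X), g, "A", "B"), 0)
})

test_that("local bounds equal the global enumeration oracle on small graphs", {
  for (s in 1:10) {
    fix <- rand_cpdag(6, 0.4, seed = 300 + s, max_und = 5L)
    g <- fix$cpdag
    set.seed(400 + s)
    X <- matrix(rnorm(60 * length(g$nodes)), 60,
                dimnames = list(NULL, g$nodes))
    e <- as_expr(X)
    dags <- enumerate_consistent_dags(g)
    for (cause in g$nodes) {
      for (effect in setdiff(g$nodes, cause)) {
        oracle_vals <- vapply(dags, function(d)
          causal_effect_in_dag(e, d, cause, effect), numeric(1))
        oracle <- oracle_vals[which.min(abs(oracle_vals))]
        expect_lt(abs(abs(causal_effect_bound(e, g, cause, effect)) -
                        abs(oracle)), 1e-8)
      }
    }
  }
})

test_that("effects scale with the units of cause and effect columns", {
  fix <- rand_cpdag(5, 0.5, seed = 501, max_und = 4L)
  g <- fix$cpdag
  set.seed(502)
  X <- matrix(rnorm(80 * length(g$nodes)), 80,
              dimnames = list(NULL, g$nodes))
  cause <- g$nodes[1L]; effect <- g$nodes[3L]
  base <- causal_effect_bound(as_expr(X), g, cause, effect)
  X_eff <- X; X_eff[, effect] <- 3 * X_eff[, effect]
  expect_equal(causal_effect_bound(as_expr(X_eff), g, cause, effect),
               3 * base, tolerance = 1e-10)
  X_cau <- X; X_cau[, cause] <- 2 * X_cau[, cause]
  expect_equal(causal_effect_bound(as_expr(X_cau), g, cause, effect),
               base / 2, tolerance = 1e-10)
})

test_that("the effect matrix covers every miRNA-mRNA pair", {
  set.seed(51)
  X <- matrix(rnorm(200 * 3), 200,
              dimnames = list(NULL, c("g1", "g2", "m1")))
  e <- as_expr(X, mirnas = "m1")
  g <- pdag(colnames(X)) # empty graph
  C <- effects_matrix(e, g)
  expect_equal(dim(C), c(1L, 2L))
  # no parents to adjust for: each entry is the simple regression slope
  slope <- unname(stats::coef(stats::lm(X[, "g1"] ~ X[, "m1"]))[2L])
  expect_equal(unname(C["m1", "g1"]), slope, tolerance = 1e-12)
  expect_lt(max(abs(C)), 0.2)
})

test_that("true targets receive systematically larger effect bounds", {
  seps <- vapply(1:6, function(s) {
    sim <- simulate_study_instance(20, 400, seed = 600 + 31 * s)
    g <- suppressMessages(learn_structure(sim$data))
    C <- effects_matrix(sim$data, g)
    keys <- outer(rownames(C), colnames(C), paste, sep = "\r")
    is_true <- keys %in% paste(sim$truth$regulator, sim$truth$target,
                               sep = "\r")
    mean(abs(C)[is_true]) - mean(abs(C)[!is_true])
  }, numeric(1))
  expect_gt(mean(seps), 0)
})
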