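chain_edges <- data.frame(from = c("A", "B"), to = c("B", "C"),
                          weight = c(0.8, 0.7))

test_that("the skeleton of a mediated chain is recovered with its sepset", {
  hits <- 0L
  for (s in 1:50) {
    X <- sem_data(c("A", "B", "C"), chain_edges, n = 5000, seed = 700 + s)
    g <- learn_skeleton(as_expr(X))
    e <- graph_edges(g)
    ok <- nrow(e) == 2L &&
      all(paste(e$source, e$target) %in% c("A B", "B C")) &&
      identical(get_sepset(g, "A", "C"), "B")
    hits <- hits + ok
  }
  expect_gte(hits, 45L)
})

test_that("constant edges survive any conditional-independence verdict", {
  set.seed(11)
  X <- cbind(A = rnorm(500), B = rnorm(500), C = rnorm(500)) # all independent
  kn <- knowledge_set("A", "C", "mirna_mrna")
  g <- learn_skeleton(as_expr(X), kn)
  expect_equal(unname(g$amat["A", "C"]), 1L)
  expect_equal(unname(g$amat["C", "A"]), 0L)
  expect_true(g$const["A", "C"])
  # and the non-knowledge pairs of independent data are mostly gone
  expect_lte(sum(g$amat) - 1L, 2L)
})

test_that("contradictory or out-of-universe knowledge is rejected", {
  set.seed(12)
  X <- cbind(A = rnorm(100), B = rnorm(100), C = rnorm(100))
  both <- knowledge_set(c("A", "B"), c("B", "A"), "mirna_mrna")
  expect_error(learn_skeleton(as_expr(X), both), "contradictory")
  outside <- knowledge_set("A", "Z", "mirna_mrna")
  expect_error(learn_skeleton(as_expr(X), outside), "restrict_to_universe")
})

test_that("v-structures are oriented by the sepset criterion", {
  # collider: A - C, B - C with sepset(A, B) empty
  g <- pdag(c("A", "B", "C"),
            undirected = rbind(c("A", "C"), c("B", "C")))
  g$sepsets[[sepset_key("A", "B")]] <- character(0)
  o <- orient_vstructures(g)
  expect_equal(unname(o$amat["A", "C"]), 1L)
  expect_equal(unname(o$amat["C", "A"]), 0L)
  expect_equal(unname(o$amat["B", "C"]), 1L)
  expect_equal(unname(o$amat["C", "B"]), 0L)
  # chain: middle node in the sepset, nothing oriented
  g2 <- pdag(c("A", "B", "C"),
             undirected = rbind(c("A", "B"), c("B", "C")))
  g2$sepsets[[sepset_key("A", "C")]] <- "B"
  o2 <- orient_vstructures(g2)
  expect_equal(unname(o2$amat["B", "A"]), 1L) # still undirected
  # constant edge keeps its direction; the other arm is still oriented
  g3 <- pdag(c("A", "B", "C"),
             constant = rbind(c("A", "C")),
             undirected = rbind(c("B", "C")))
  g3$sepsets[[sepset_key("A", "B")]] <- character(0)
  o3 <- orient_vstructures(g3)
  expect_equal(unname(o3$amat["B", "C"]), 1L)
  expect_equal(unname(o3$amat["C", "B"]), 0L)
  expect_true(o3$const["A", "C"])
})

test_that("a v-structure that contradicts knowledge loses, with a log", {
  # truth says C -> A but the sepsets scream A -> C <- B
  g <- pdag(c("A", "B", "C"),
            constant = rbind(c("C", "A")),
            undirected = rbind(c("B", "C")))
  g$sepsets[[sepset_key("A", "B")]] <- character(0)
  expect_message(o <- orient_vstructures(g), "kept")
  expect_equal(unname(o$amat["C", "A"]), 1L) # knowledge direction intact
  expect_equal(unname(o$amat["A", "C"]), 0L)
})

test_that("knowledge edges anchor the orientation of neighbouring regulators", {
  # miR-200 family / ZEB1 style scenario: two knowledge-backed repressors
  # of the transcription factor, a third regulator discovered from data.
  nodes <- c("miR200a", "miR200b", "miR429", "QKI", "ZEB1")
  edges <- data.frame(
    from = c("miR200a", "miR200b", "miR200b", "miR429"),
    to = c("ZEB1", "ZEB1", "QKI", "ZEB1"),
    weight = c(-0.8, -0.7, 0.6, -0.75))
  X <- sem_data(nodes, edges, n = 4000, seed = 42)
  dat <- expression_matrix(X, c(miR200a = "mirna", miR200b = "mirna",
                                miR429 = "mirna", QKI = "mrna",
                                ZEB1 = "tf_mrna"))
  kn <- knowledge_set(c("miR200a", "miR200b"), c("ZEB1", "ZEB1"),
                      "mirna_mrna")
  g <- suppressMessages(learn_structure(dat, kn))
  expect_true(g$const["miR200a", "ZEB1"] && g$const["miR200b", "ZEB1"])
  expect_equal(unname(g$amat["ZEB1", "miR200a"]), 0L)
  expect_equal(unname(g$amat["ZEB1", "miR200b"]), 0L)
  # the data-discovered regulator joins the collider at ZEB1
  expect_equal(unname(g$amat["miR429", "ZEB1"]), 1L)
  expect_equal(unname(g$amat["ZEB1", "miR429"]), 0L)
  expect_true(is_acyclic(g))
})

test_that("learning is invariant to the column order of the data", {
  sim <- simulate_study_instance(25, 300, seed = 77)
  g1 <- suppressMessages(learn_structure(sim$data))
  set.seed(123)
  perm <- sample(ncol(sim$data$values))
  shuffled <- expression_matrix(sim$data$values[, perm],
                                sim$data$roles[perm])
  g2 <- suppressMessages(learn_structure(shuffled))
  expect_identical(g1$amat, g2$amat)
})

test_that("every surviving knowledge record appears directed in the output", {
  for (s in 1:4) {
    sim <- simulate_study_instance(30, 250, seed = 900 + 13 * s)
    kn <- sample_knowledge(sim$network, 0.4, seed = s)
    g <- suppressMessages(learn_structure(sim$data, kn))
    if (nrow(kn) == 0L) next
    expect_true(all(g$amat[cbind(kn$regulator, kn$target)] == 1L))
    expect_true(all(g$amat[cbind(kn$target, kn$regulator)] == 0L))
    expect_true(all(g$const[cbind(kn$regulator, kn$target)]))
  }
})

test_that("independent data yield a near-empty structure", {
  set.seed(5)
  X <- matrix(rnorm(500 * 10), 500, 10,
              dimnames = list(NULL, sprintf("G%02d", 1:10)))
  g <- learn_structure(as_expr(X))
  expect_lte(nrow(graph_edges(g)), 3L) # ~alpha of 45 pairs
})
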