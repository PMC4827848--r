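test_that("acyclicity looks only at directed edges", {
  expect_true(is_acyclic(pdag(character(0))))
  cyc <- pdag(c("A", "B", "C"))
  cyc$amat["A", "B"] <- cyc$amat["B", "C"] <- cyc$amat["C", "A"] <- 1L
  expect_false(is_acyclic(cyc))
  mixed <- pdag(c("A", "B", "C"),
                directed = rbind(c("A", "B"), c("B", "C")),
                undirected = rbind(c("A", "C")))
  expect_true(is_acyclic(mixed))
})

test_that("graph constructors reject malformed edges", {
  expect_error(pdag("A", directed = rbind(c("A", "A"))), "self-loop")
  expect_error(pdag(c("A", "B"), directed = rbind(c("A", "B")),
                    undirected = rbind(c("A", "B"))), "duplicate")
  expect_error(pdag(c("A", "B"), directed = rbind(c("A", "C"))), "unknown")
  expect_error(dag(c("A", "B", "C"),
                   rbind(c("A", "B"), c("B", "C"), c("C", "A"))), "cycle")
  # knowledge edges that close a directed cycle surface as an error
  expect_error(pdag(c("A", "B", "C"),
                    constant = rbind(c("A", "B"), c("B", "C"), c("C", "A"))),
               "cycle")
})

test_that("orientation closure forces exactly the implied directions", {
  # no new v-structure at B: A -> B, B - C with A, C non-adjacent
  g1 <- orientation_closure(pdag(c("A", "B", "C"),
                                 directed = rbind(c("A", "B")),
                                 undirected = rbind(c("B", "C"))))
  expect_equal(unname(g1$amat["B", "C"]), 1L)
  expect_equal(unname(g1$amat["C", "B"]), 0L)
  # no cycle: A -> B -> C with A - C
  g2 <- orientation_closure(pdag(c("A", "B", "C"),
                                 directed = rbind(c("A", "B"), c("B", "C")),
                                 undirected = rbind(c("A", "C"))))
  expect_equal(unname(g2$amat["A", "C"]), 1L)
  expect_equal(unname(g2$amat["C", "A"]), 0L)
  # nothing forced for a lone undirected edge
  g3 <- orientation_closure(pdag(c("A", "B"),
                                 undirected = rbind(c("A", "B"))))
  expect_equal(unname(g3$amat["A", "B"]), 1L)
  expect_equal(unname(g3$amat["B", "A"]), 1L)
})

test_that("orientation closure preserves edges and is idempotent", {
  for (s in 1:5) {
    fix <- rand_cpdag(6, 0.4, seed = 100 + s, max_und = 15L)
    g <- fix$cpdag
    g2 <- orientation_closure(g)
    # same skeleton, no directed edge lost or reversed
    expect_equal(((g2$amat + t(g2$amat)) > 0), ((g$amat + t(g$amat)) > 0))
    dir1 <- g$amat == 1L & t(g$amat) == 0L
    expect_true(all(g2$amat[dir1] == 1L & t(g2$amat)[dir1] == 0L))
    expect_identical(orientation_closure(g2)$amat, g2$amat)
  }
})

test_that("contradictory forced orientations are reported, not silently resolved", {
  # D -> A forces A -> B (no new v-structure at A), E -> B forces B -> A
  g <- pdag(c("A", "B", "D", "E"),
            directed = rbind(c("D", "A"), c("E", "B")),
            undirected = rbind(c("A", "B")))
  expect_error(orientation_closure(g), "both directions")
})

test_that("consistent-extension enumeration matches the brute-force expectation", {
  chain <- pdag(c("A", "B", "C"),
                undirected = rbind(c("A", "B"), c("B", "C")))
  dags <- enumerate_consistent_dags(chain)
  expect_length(dags, 3L) # all but the collider A -> B <- C
  keys <- sort(vapply(dags, function(d) {
    e <- which(d$amat == 1L, arr.ind = TRUE)
    paste(sort(paste(d$nodes[e[, 1L]], d$nodes[e[, 2L]], sep = ">")),
          collapse = ";")
  }, character(1)))
  expect_equal(keys, sort(c("A>B;B>C", "B>A;C>B", "B>A;B>C")))

  full <- pdag(c("A", "B"), directed = rbind(c("A", "B")))
  ext <- enumerate_consistent_dags(full)
  expect_length(ext, 1L)
  expect_identical(ext[[1L]]$amat, full$amat)

  star <- pdag(c("H", paste0("L", 1:13)),
               undirected = cbind("H", paste0("L", 1:13)))
  expect_error(enumerate_consistent_dags(star), "budget")
})

test_that("every consistent extension keeps skeleton, v-structures and acyclicity", {
  for (s in 1:10) {
    fix <- rand_cpdag(6, 0.4, seed = 200 + s, max_und = 8L)
    g <- fix$cpdag
    dags <- enumerate_consistent_dags(g, max_undirected = 8L)
    expect_gt(length(dags), 0L)
    gv <- vstructures(g)
    for (d in dags) {
      expect_true(is_acyclic(d))
      expect_equal(((d$amat + t(d$amat)) > 0), ((g$amat + t(g$amat)) > 0))
      expect_identical(vstructures(d), gv)
    }
    # the generating DAG itself belongs to the enumerated class
    dag_keys <- vapply(dags, function(d) paste(d$amat, collapse = ""),
                       character(1))
    expect_true(paste(fix$dag$amat, collapse = "") %in% dag_keys)
  }
})

test_that("structural Hamming distance counts per-pair disagreements", {
  a <- pdag(c("A", "B", "C"), directed = rbind(c("A", "B")),
            undirected = rbind(c("B", "C")))
  expect_equal(structural_hamming_distance(a, a), 0L)
  b <- pdag(c("A", "B", "C"), directed = rbind(c("B", "A")),
            undirected = rbind(c("B", "C")))
  expect_equal(structural_hamming_distance(a, b), 1L)
  c_ <- pdag(c("A", "B", "C"), directed = rbind(c("A", "B")))
  expect_equal(structural_hamming_distance(a, c_), 1L)
})

test_that("graph serialization round-trips through the edge-list format", {
  g <- pdag(c("A", "B", "C", "D"),
            directed = rbind(c("A", "B")),
            undirected = rbind(c("B", "C")),
            constant = rbind(c("A", "D")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  g2 <- read_graph_tsv(path)
  expect_identical(g2$amat, g$amat)
  expect_identical(g2$const, g$const)
})
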