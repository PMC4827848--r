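# Independent linear-SEM sampler used as an oracle for effect-estimation
# and learning tests. Deliberately separate from the package's own
# generator: plain topological loop over a data frame of weighted edges.
sem_data <- function(nodes, edges, n, seed,
                     noise = function(n) stats::runif(n, -1, 1),
                     intercepts = 0) {
  set.seed(seed)
  X <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  b <- stats::setNames(rep_len(intercepts, length(nodes)), nodes)
  done <- character(0)
  while (length(done) < length(nodes)) {
    progressed <- FALSE
    for (v in setdiff(nodes, done)) {
      idx <- which(edges$to == v)
      if (!all(edges$from[idx] %in% done)) next
      x <- b[[v]] + noise(n)
      for (k in idx) x <- x + edges$weight[k] * X[, edges$from[k]]
      X[, v] <- x
      done <- c(done, v)
      progressed <- TRUE
    }
    if (!progressed) stop("sem_data: edges are cyclic")
  }
  X
}

# Wrap a plain matrix as an expression object; genes default to mRNA,
# with the given miRNA/TF identifiers overriding.
as_expr <- function(X, mirnas = character(0), tfs = character(0)) {
  roles <- stats::setNames(rep("mrna", ncol(X)), colnames(X))
  roles[mirnas] <- "mirna"
  roles[tfs] <- "tf_mrna"
  expression_matrix(X, roles)
}

# Random DAG over n nodes: random topological order, forward edges with
# probability p.
rand_dag <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  ord <- sample(nodes)
  pairs <- t(utils::combn(seq_len(n), 2L))
  keep <- stats::runif(nrow(pairs)) < p
  dag(nodes, cbind(ord[pairs[keep, 1L]], ord[pairs[keep, 2L]]))
}

# Random CPDAG (pattern of a random DAG) with at most max_und undirected
# edges; returns both the pattern and a DAG in its class.
rand_cpdag <- function(n, p, seed, max_und = 5L) {
  for (k in 0:200) {
    d <- rand_dag(n, p, seed + 1000L * k)
    g <- dag_to_cpdag(d)
    U <- g$amat == 1L & t(g$amat) == 1L
    if (sum(U) / 2L <= max_und) return(list(cpdag = g, dag = d))
  }
  stop("could not draw a CPDAG within the undirected-edge budget")
}

edge_key_df <- function(g) {
  e <- graph_edges(g)
  paste(e$source, e$target, e$mark, e$constant)
}
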