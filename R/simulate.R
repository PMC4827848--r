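# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so package functions never perturb global
# randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Draw regulatory-strength weights
#'
#' Weights are uniform on the two-sided support [-1, -0.1] U [0.1, 1]:
#' each sign with probability 1/2 and the magnitude uniform on [0.1, 1],
#' so no regulatory effect is ever negligibly small or larger than one.
#'
#' @param n number of draws (uses the current RNG stream).
#' @return Numeric vector of length `n`.
#' @export
sample_weight <- function(n = 1L) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 0.1, 1)
}

default_noise <- function(noise) {
  if (is.character(noise)) {
    noise <- switch(noise,
                    uniform = list(dist = "uniform", min = -1, max = 1),
                    laplace = list(dist = "laplace", scale = 1),
                    student_t = list(dist = "student_t", df = 5),
                    stop("unknown noise distribution: ", noise, call. = FALSE))
  }
  stopifnot(is.list(noise), !is.null(noise$dist))
  noise
}

draw_noise <- function(noise, n) {
  switch(noise$dist,
         uniform = stats::runif(n, noise$min, noise$max),
         laplace = sample(c(-1, 1), n, replace = TRUE) *
           stats::rexp(n, rate = 1 / noise$scale),
         student_t = stats::rt(n, df = noise$df),
         stop("unknown noise distribution: ", noise$dist, call. = FALSE))
}

noise_variance <- function(noise) {
  switch(noise$dist,
         uniform = (noise$max - noise$min)^2 / 12,
         laplace = 2 * noise$scale^2,
         student_t = noise$df / (noise$df - 2))
}

#' Generate a random ground-truth regulatory network
#'
#' Draws a random topological order over the genes, adds each forward
#' pair independently with probability `edge_prob`, and keeps only the
#' role-admissible edges: TF-coding mRNAs may regulate any gene (miRNAs
#' and mRNAs, transcriptionally), miRNAs may regulate mRNAs including
#' TF-coding ones (post-transcriptionally), and plain mRNAs regulate
#' nothing. Each surviving edge gets a weight from [sample_weight()] and
#' each node an intercept drawn from N(0, 1).
#'
#' @param n_nodes number of genes (at least 2).
#' @param role_fractions named numeric vector with entries `mirna`,
#'   `tf_mrna`, `mrna` summing to 1.
#' @param edge_prob probability of each admissible forward pair; when
#'   `NULL` it is chosen so that regulated genes (mRNAs and TF-mRNAs)
#'   have mean in-degree `mean_in_degree`.
#' @param mean_in_degree target mean regulator count per mRNA used when
#'   `edge_prob` is `NULL` (default 2).
#' @param noise error-term specification: `"uniform"` (default,
#'   Uniform(-1, 1)), `"laplace"`, `"student_t"`, or a list with a `dist`
#'   field and parameters.
#' @param seed integer seed; identical seeds give identical networks.
#' @return An object of class `cider_network` with fields `dag`
#'   (`cider_dag`), `roles`, `edges` (data frame `from`, `to`, `weight`),
#'   `intercepts`, `noise`.
#' @export
generate_network <- function(n_nodes, role_fractions = c(mirna = 0.1,
                                                         tf_mrna = 0.1,
                                                         mrna = 0.8),
                             edge_prob = NULL, mean_in_degree = 2,
                             noise = "uniform", seed = 1L) {
  if (n_nodes < 2L) stop("n_nodes must be at least 2", call. = FALSE)
  if (abs(sum(role_fractions) - 1) > 1e-8 || any(role_fractions < 0)) {
    stop("role fractions must be non-negative and sum to 1", call. = FALSE)
  }
  need <- c("mirna", "tf_mrna", "mrna")
  if (!all(need %in% names(role_fractions))) {
    stop("role_fractions needs entries: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  noise <- default_noise(noise)

  counts <- floor(role_fractions[need] * n_nodes)
  counts["mrna"] <- counts["mrna"] + (n_nodes - sum(counts))
  wd <- nchar(as.character(n_nodes))
  nodes <- c(sprintf(paste0("miR_%0", wd, "d"), seq_len(counts["mirna"])),
             sprintf(paste0("TF_%0", wd, "d"), seq_len(counts["tf_mrna"])),
             sprintf(paste0("gene_%0", wd, "d"), seq_len(counts["mrna"])))
  roles <- stats::setNames(rep(need, counts), nodes)

  if (is.null(edge_prob)) {
    q <- role_fractions["tf_mrna"] +
      role_fractions["mirna"] * (1 - role_fractions["mirna"])
    target_edges <- mean_in_degree *
      n_nodes * (role_fractions["mrna"] + role_fractions["tf_mrna"])
    edge_prob <- min(1, unname(target_edges /
                                 (n_nodes * (n_nodes - 1) / 2 * q)))
  }
  if (edge_prob < 0 || edge_prob > 1) {
    stop("edge_prob must be in [0, 1]", call. = FALSE)
  }

  with_seed(seed, {
    topo <- sample(nodes)
    idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    from <- topo[idx[, 1L]]
    to <- topo[idx[, 2L]]
    present <- stats::runif(nrow(idx)) < edge_prob
    admissible <- (roles[from] == "tf_mrna") |
      (roles[from] == "mirna" & roles[to] %in% c("mrna", "tf_mrna"))
    keep <- present & admissible
    edges <- data.frame(from = from[keep], to = to[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    edges$weight <- sample_weight(nrow(edges))
    rownames(edges) <- NULL
    intercepts <- stats::setNames(stats::rnorm(n_nodes), nodes)
    structure(list(dag = dag(nodes, edges[, c("from", "to")]),
                   roles = roles[sort(nodes)],
                   edges = edges,
                   intercepts = intercepts[sort(nodes)],
                   noise = noise),
              class = "cider_network")
  })
}

#' @export
print.cider_network <- function(x, ...) {
  tab <- table(x$roles)
  cat("<cider_network> ", length(x$dag$nodes), " nodes (",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "),
      "), ", nrow(x$edges), " weighted edges, ", x$noise$dist,
      " noise\n", sep = "")
  invisible(x)
}

topological_order <- function(d) {
  D <- d$amat
  n <- nrow(D)
  indeg <- colSums(D)
  out <- integer(0)
  alive <- rep(TRUE, n)
  while (length(out) < n) {
    src <- which(alive & indeg == 0L)
    if (length(src) == 0L) stop("graph is cyclic", call. = FALSE)
    v <- src[1L]
    out <- c(out, v)
    alive[v] <- FALSE
    indeg <- indeg - D[v, ]
    indeg[!alive] <- 1L
  }
  d$nodes[out]
}

#' Generate expression data from a simulated network
#'
#' Traverses the network in topological order and sets each gene to the
#' linear structural-equation value x_i = b_i + sum over parents j of
#' w_j * x_j + e_i, with the error term e_i drawn from the network's
#' noise specification.
#'
#' @param network a `cider_network`.
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @return A `cider_expr` (samples by genes) carrying the network roles.
#' @export
generate_expression <- function(network, n_samples, seed = 1L) {
  nodes <- network$dag$nodes
  topo <- topological_order(network$dag)
  X <- matrix(0, n_samples, length(nodes),
              dimnames = list(sprintf("S%04d", seq_len(n_samples)), nodes))
  with_seed(seed, {
    for (v in topo) {
      e <- network$edges[network$edges$to == v, , drop = FALSE]
      x <- network$intercepts[[v]] + draw_noise(network$noise, n_samples)
      if (nrow(e) > 0L) {
        x <- x + X[, e$from, drop = FALSE] %*% e$weight
      }
      X[, v] <- x
    }
  })
  expression_matrix(X, network$roles)
}

#' Covariance matrix implied by the structural-equation model
#'
#' With B the weighted adjacency (B[i, j] = weight of edge j -> i) and
#' S the diagonal error-variance matrix, the model implies
#' Cov(x) = (I - B)^-1 S (I - B)^-T. Useful for checking simulated data
#' against its population distribution.
#'
#' @param network a `cider_network`.
#' @return Covariance matrix over the network's genes.
#' @export
sem_implied_covariance <- function(network) {
  nodes <- network$dag$nodes
  n <- length(nodes)
  B <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges) > 0L) {
    B[cbind(network$edges$to, network$edges$from)] <- network$edges$weight
  }
  inv <- solve(diag(n) - B)
  v <- noise_variance(network$noise)
  inv %*% (diag(n) * v) %*% t(inv)
}

#' True regulatory edges of a network, typed as knowledge records
#'
#' Classifies every ground-truth edge by interaction type: `tf_mirna` for
#' TF-mRNA -> miRNA edges and `mirna_mrna` for miRNA -> mRNA (including
#' TF-coding mRNA) edges. TF -> mRNA edges carry neither knowledge type
#' and are excluded.
#'
#' @param network a `cider_network`.
#' @return A `cider_knowledge` set with `source = "simulated-truth"`.
#' @export
true_knowledge <- function(network) {
  e <- network$edges
  r <- network$roles
  type <- ifelse(r[e$from] == "tf_mrna" & r[e$to] == "mirna", "tf_mirna",
                 ifelse(r[e$from] == "mirna", "mirna_mrna", NA))
  keep <- !is.na(type)
  knowledge_set(e$from[keep], e$to[keep], type[keep], "simulated-truth")
}

#' Sample a graded subset of true edges as prior knowledge
#'
#' For each requested interaction type, uniformly samples
#' floor(fraction * n_type) true edges without replacement. For a fixed
#' seed the subsets are nested across fractions (the permutation is drawn
#' once and truncated), so a knowledge sweep is monotone by construction.
#'
#' @param network a `cider_network`.
#' @param fraction fraction of each type's true edges to reveal, in
#'   [0, 1].
#' @param types interaction types to sample from.
#' @param seed integer seed (must leave `seed + 2` below 2^31).
#' @return A `cider_knowledge` set.
#' @export
sample_knowledge <- function(network, fraction,
                             types = c("tf_mirna", "mirna_mrna"),
                             seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  truth <- true_knowledge(network)
  canonical <- c("tf_mirna", "mirna_mrna")
  picks <- list()
  for (ty in intersect(canonical, types)) {
    rows <- truth[truth$type == ty, , drop = FALSE]
    n_take <- floor(fraction * nrow(rows))
    if (n_take == 0L) next
    perm <- with_seed(seed + match(ty, canonical), sample(nrow(rows)))
    picks[[ty]] <- rows[perm[seq_len(n_take)], , drop = FALSE]
  }
  if (length(picks) == 0L) return(knowledge_set())
  all <- do.call(rbind, picks)
  knowledge_set(all$regulator, all$target, all$type, "simulated-truth")
}
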