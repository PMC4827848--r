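#' Knowledge-constrained skeleton learning (PC-stable deletion phase)
#'
#' Starts from the complete undirected graph on the genes of `data`,
#' marks every knowledge record as a constant edge, and removes
#' non-constant edges by Fisher-z conditional-independence tests with
#' conditioning sets of growing size drawn from the current
#' neighbourhoods (order-independent, PC-stable variant: neighbourhoods
#' are frozen per size level). Constant edges are never tested for
#' removal but remain available as members of conditioning sets, which is
#' how a knowledge edge can expose a spurious dependence elsewhere. The
#' separating set of every removed edge is recorded for v-structure
#' detection.
#'
#' @param data a `cider_expr`; every column must have nonzero variance.
#' @param knowledge a `cider_knowledge` set already restricted to the
#'   genes of `data` (see [restrict_to_universe()]); `NULL` for none.
#' @param alpha significance level of the CI tests (default 0.01).
#' @param max_cond_size largest conditioning-set size (default 3).
#' @return A `cider_pdag` whose constant edges are directed
#'   regulator-to-target and whose remaining edges are undirected, with
#'   the sepset registry populated.
#' @export
learn_skeleton <- function(data, knowledge = NULL, alpha = 0.01,
                           max_cond_size = 3L) {
  genes <- sort(colnames(data$values))
  X <- data$values[, genes, drop = FALSE]
  n <- nrow(X)
  p <- length(genes)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(utils::head(genes[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (n <= 3L) stop("need more than 3 samples for marginal CI tests",
                    call. = FALSE)

  if (is.null(knowledge)) knowledge <- knowledge_set()
  in_univ <- knowledge$regulator %in% genes & knowledge$target %in% genes
  if (any(!in_univ)) {
    stop("knowledge references genes absent from the data; apply ",
         "restrict_to_universe() first", call. = FALSE)
  }
  ukey <- paste(pmin(knowledge$regulator, knowledge$target),
                pmax(knowledge$regulator, knowledge$target))
  if (anyDuplicated(ukey)) {
    stop("contradictory knowledge: both directions supplied for pair ",
         ukey[duplicated(ukey)][1L], call. = FALSE)
  }

  C <- stats::cor(X)
  A <- matrix(TRUE, p, p, dimnames = list(genes, genes))
  diag(A) <- FALSE
  protected <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  if (nrow(knowledge) > 0L) {
    protected[cbind(knowledge$regulator, knowledge$target)] <- TRUE
    protected <- protected | t(protected)
  }
  # hashed registry: O(1) insertion matters when level 0 removes most of
  # the p^2/2 pairs of a large panel
  sepsets <- new.env(parent = emptyenv())

  # level 0: all marginal tests at once
  stat0 <- sqrt(n - 3) * abs(atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12)))
  p0 <- 2 * stats::pnorm(-stat0)
  drop0 <- which(p0 > alpha & upper.tri(p0) & !protected, arr.ind = TRUE)
  for (r in seq_len(nrow(drop0))) {
    i <- drop0[r, 1L]; j <- drop0[r, 2L]
    A[i, j] <- A[j, i] <- FALSE
    assign(sepset_key(genes[i], genes[j]), character(0), envir = sepsets)
  }

  for (ell in seq_len(max_cond_size)) {
    if (n <= ell + 3L) break
    Asnap <- A
    edges <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(edges) == 0L) break
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    any_testable <- FALSE
    sqn <- sqrt(n - ell - 3)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      if (protected[i, j]) next
      if (!A[i, j]) next
      tested <- character(0)
      removed <- FALSE
      for (side in 1:2) {
        anchor <- if (side == 1L) i else j
        other <- if (side == 1L) j else i
        nb <- setdiff(which(Asnap[, anchor]), other)
        if (length(nb) < ell) next
        any_testable <- TRUE
        subs <- combn_sets(nb, ell)
        for (s in seq_len(ncol(subs))) {
          S <- subs[, s]
          skey <- paste(S, collapse = ",")
          if (skey %in% tested) next
          tested <- c(tested, skey)
          rho <- partial_cor(C, i, j, S, genes = genes)
          stat <- sqn * abs(atanh(clamp_cor(rho)))
          if (2 * stats::pnorm(-stat) > alpha) {
            A[i, j] <- A[j, i] <- FALSE
            assign(sepset_key(genes[i], genes[j]), genes[S], envir = sepsets)
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    if (!any_testable) break
  }

  und <- which(A & upper.tri(A) & !protected, arr.ind = TRUE)
  g <- pdag(genes,
            undirected = cbind(genes[und[, 1L]], genes[und[, 2L]]),
            constant = knowledge[, c("regulator", "target")],
            sepsets = sepsets)
  g
}

combn_sets <- function(x, m) {
  if (length(x) == m) return(matrix(x, ncol = 1L))
  utils::combn(x, m)
}

#' Orient v-structures from the sepset registry
#'
#' For every unshielded triple i - j - k (i and k non-adjacent), the
#' triple is a v-structure exactly when j does not belong to the
#' separating set recorded for (i, k) -- the operational form of "i and k
#' remain dependent given j" -- and the two edges are oriented
#' i -> j <- k. Constant-edge directions are never overridden; a
#' v-structure that would reverse one is reported with a message and the
#' knowledge direction wins.
#'
#' @param g a `cider_pdag` with sepsets populated by [learn_skeleton()].
#' @return The `cider_pdag` with v-structure edges directed.
#' @export
orient_vstructures <- function(g) {
  nodes <- g$nodes
  A <- adjacency_amat(g)
  conflicts <- character(0)
  for (j in seq_along(nodes)) {
    nbrs <- which(A[, j] == 1L)
    if (length(nbrs) < 2L) next
    for (a in seq_along(nbrs)) {
      for (b in seq_len(a - 1L)) {
        i <- nbrs[b]; k <- nbrs[a]
        if (A[i, k] == 1L) next
        sep <- get_sepset(g, nodes[i], nodes[k])
        if (is.null(sep)) next
        if (nodes[j] %in% sep) next
        for (tail in c(nodes[i], nodes[k])) {
          res <- orient_into(g, tail, nodes[j])
          g <- res$g
          conflicts <- c(conflicts, res$conflict)
        }
      }
    }
  }
  conflicts <- unique(conflicts)
  if (length(conflicts) > 0L) {
    message("kept ", length(conflicts), " existing orientation(s) against ",
            "conflicting v-structure(s): ",
            paste(utils::head(conflicts, 3L), collapse = "; "),
            if (length(conflicts) > 3L) "; ...")
  }
  attr(g, "orientation_conflicts") <- conflicts
  g
}

# Direct the edge from -> to if it is currently undirected; keep (and
# report) any existing opposite orientation, which can only come from
# knowledge or an earlier v-structure.
orient_into <- function(g, from, to) {
  conflict <- character(0)
  if (g$amat[from, to] == 1L && g$amat[to, from] == 1L) {
    g$amat[to, from] <- 0L
  } else if (g$amat[to, from] == 1L && g$amat[from, to] == 0L) {
    kind <- if (g$const[to, from]) "constant" else "v-structure"
    conflict <- paste0(from, " -> ", to, " vs ", kind, " ", to, " -> ", from)
  }
  list(g = g, conflict = conflict)
}

#' Learn the causal structure from expression data and knowledge
#'
#' Full structure-construction sequence: PC-stable skeleton learning with
#' constant edges ([learn_skeleton()]), constant-edge orientation from the
#' knowledge records, v-structure orientation ([orient_vstructures()]),
#' and orientation propagation ([orientation_closure()]). Every knowledge
#' record that survives restriction to the gene universe is guaranteed to
#' appear in the output as a directed edge regulator-to-target.
#'
#' @inheritParams learn_skeleton
#' @return A `cider_pdag`.
#' @export
learn_structure <- function(data, knowledge = NULL, alpha = 0.01,
                            max_cond_size = 3L) {
  if (!is.null(knowledge)) {
    knowledge <- restrict_to_universe(knowledge, data)
  }
  g <- learn_skeleton(data, knowledge, alpha = alpha,
                      max_cond_size = max_cond_size)
  g <- orient_vstructures(g)
  # sampling noise can make rule applications clash or v-structures close
  # directed cycles; resolve such edges conservatively (leave or make
  # them undirected) instead of aborting the run
  g <- relax_directed_cycles(g)
  g <- orientation_closure(g, on_conflict = "keep_undirected")
  validate_pdag(g)
  g
}

# V-structure orientations inferred from noisy sepsets can close directed
# cycles. Revert cycle-region directed edges (never constant ones) to
# undirected, lexicographically first, until the directed part is acyclic.
relax_directed_cycles <- function(g) {
  reverted <- character(0)
  while (!is_acyclic(g)) {
    D <- directed_amat(g)
    n <- nrow(D)
    indeg <- colSums(D)
    alive <- rep(TRUE, n)
    repeat {
      src <- which(alive & indeg == 0L)
      if (length(src) == 0L) break
      alive[src] <- FALSE
      indeg <- indeg - if (length(src) == 1L) D[src, ] else
        colSums(D[src, , drop = FALSE])
    }
    cyc <- which(alive)
    sub <- D[cyc, cyc, drop = FALSE] == 1L & !g$const[cyc, cyc, drop = FALSE]
    cand <- which(sub, arr.ind = TRUE)
    if (nrow(cand) == 0L) {
      stop("directed cycle formed entirely by constant edges: ",
           "contradictory knowledge", call. = FALSE)
    }
    ord <- order(g$nodes[cyc[cand[, 1L]]], g$nodes[cyc[cand[, 2L]]])
    i <- cyc[cand[ord[1L], 1L]]
    j <- cyc[cand[ord[1L], 2L]]
    g$amat[j, i] <- 1L
    reverted <- c(reverted, paste(g$nodes[i], g$nodes[j], sep = ">"))
  }
  if (length(reverted) > 0L) {
    message("reverted ", length(reverted),
            " cycle-closing orientation(s) to undirected")
  }
  attr(g, "cycle_reverts") <- reverted
  g
}
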