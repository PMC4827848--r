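#' Partially directed graphs for causal structure learning
#'
#' A `cider_pdag` holds the mixed graph produced by constraint-based
#' structure learning: a skeleton whose edges are either directed or
#' undirected, a `constant` flag on edges fixed by regulatory knowledge,
#' and the registry of separating sets recorded when edges were removed
#' by conditional-independence tests.
#'
#' Nodes are gene identifiers and are kept in lexicographic order so that
#' every iteration over nodes or edges is deterministic.
#'
#' @param nodes character vector of node (gene) identifiers.
#' @param directed two-column matrix or data frame of directed edges
#'   (from, to).
#' @param undirected two-column matrix or data frame of undirected edges.
#' @param constant two-column matrix or data frame of knowledge-fixed
#'   edges (regulator, target); these are stored directed and flagged.
#' @param sepsets named list mapping a pair key (see [sepset_key()]) to a
#'   character vector of separating nodes.
#' @return An object of class `cider_pdag`.
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL,
                 constant = NULL, sepsets = list()) {
  nodes <- sort(unique(as.character(nodes)))
  n <- length(nodes)
  amat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  const <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, amat = amat, const = const,
                      sepsets = sepsets),
                 class = "cider_pdag")
  add <- function(g, pairs, mark, is_const) {
    pairs <- as_edge_pairs(pairs)
    for (r in seq_len(nrow(pairs))) {
      g <- add_edge(g, pairs[r, 1L], pairs[r, 2L], mark, is_const)
    }
    g
  }
  g <- add(g, directed, "directed", FALSE)
  g <- add(g, undirected, "undirected", FALSE)
  g <- add(g, constant, "directed", TRUE)
  validate_pdag(g)
  g
}

as_edge_pairs <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(matrix(character(0), 0L, 2L))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.character(x) && is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "character"
  x[, 1:2, drop = FALSE]
}

add_edge <- function(g, from, to, mark = c("directed", "undirected"),
                     constant = FALSE) {
  mark <- match.arg(mark)
  if (!all(c(from, to) %in% g$nodes)) {
    stop("edge (", from, ", ", to, ") references unknown node", call. = FALSE)
  }
  if (from == to) stop("self-loop on node '", from, "'", call. = FALSE)
  if (g$amat[from, to] + g$amat[to, from] > 0L) {
    stop("duplicate edge between '", from, "' and '", to, "'", call. = FALSE)
  }
  g$amat[from, to] <- 1L
  if (mark == "undirected") g$amat[to, from] <- 1L
  if (constant) {
    if (mark == "undirected") {
      stop("constant edges must be directed", call. = FALSE)
    }
    g$const[from, to] <- TRUE
  }
  g
}

validate_pdag <- function(g) {
  stopifnot(is.matrix(g$amat), all(g$amat %in% c(0L, 1L)))
  if (any(diag(g$amat) != 0L)) stop("self-loops are not allowed", call. = FALSE)
  if (!is_acyclic(g)) {
    stop("directed edges form a cycle", call. = FALSE)
  }
  bad <- g$const & !(g$amat == 1L & t(g$amat) == 0L)
  if (any(bad)) {
    stop("constant edges must be present and directed", call. = FALSE)
  }
  invisible(g)
}

#' Directed acyclic graph
#'
#' @param nodes character vector of node identifiers.
#' @param edges two-column matrix or data frame of directed edges (from, to).
#' @return An object of class `cider_dag`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  n <- length(nodes)
  amat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  edges <- as_edge_pairs(edges)
  for (r in seq_len(nrow(edges))) {
    from <- edges[r, 1L]; to <- edges[r, 2L]
    if (!all(c(from, to) %in% nodes)) {
      stop("edge (", from, ", ", to, ") references unknown node", call. = FALSE)
    }
    if (from == to) stop("self-loop on node '", from, "'", call. = FALSE)
    amat[from, to] <- 1L
  }
  d <- structure(list(nodes = nodes, amat = amat), class = "cider_dag")
  if (!is_acyclic(d)) stop("edges form a directed cycle", call. = FALSE)
  d
}

# Directed-only adjacency (i -> j), dropping undirected marks.
directed_amat <- function(g) {
  if (inherits(g, "cider_dag")) return(g$amat)
  (g$amat == 1L & t(g$amat) == 0L) * 1L
}

undirected_amat <- function(g) {
  if (inherits(g, "cider_dag")) return(matrix(0L, length(g$nodes), length(g$nodes),
                                              dimnames = list(g$nodes, g$nodes)))
  (g$amat == 1L & t(g$amat) == 1L) * 1L
}

adjacency_amat <- function(g) {
  ((g$amat + t(g$amat)) > 0L) * 1L
}

#' Parents, siblings and adjacency of a node
#'
#' `pdag_parents()` returns the nodes with a directed edge into `node`;
#' `pdag_siblings()` the nodes joined to `node` by an undirected edge;
#' `pdag_adjacent()` all neighbours regardless of mark.
#'
#' @param g a `cider_pdag` or `cider_dag`.
#' @param node node identifier.
#' @return Character vector of node identifiers.
#' @export
pdag_parents <- function(g, node) {
  D <- directed_amat(g)
  g$nodes[D[, node] == 1L]
}

#' @rdname pdag_parents
#' @export
pdag_siblings <- function(g, node) {
  U <- undirected_amat(g)
  g$nodes[U[, node] == 1L]
}

#' @rdname pdag_parents
#' @export
pdag_adjacent <- function(g, node) {
  A <- adjacency_amat(g)
  g$nodes[A[, node] == 1L]
}

#' Test acyclicity of the directed part of a graph
#'
#' Undirected edges are ignored: the graph is acyclic if and only if its
#' directed edges contain no directed cycle.
#'
#' @param g a `cider_pdag` or `cider_dag`.
#' @return Logical scalar.
#' @export
is_acyclic <- function(g) {
  D <- directed_amat(g)
  n <- nrow(D)
  if (n == 0L) return(TRUE)
  indeg <- colSums(D)
  alive <- rep(TRUE, n)
  repeat {
    src <- which(alive & indeg == 0L)
    if (length(src) == 0L) break
    alive[src] <- FALSE
    if (length(src) == 1L) {
      indeg <- indeg - D[src, ]
    } else {
      indeg <- indeg - colSums(D[src, , drop = FALSE])
    }
  }
  !any(alive)
}

#' V-structures of a graph
#'
#' Returns a canonical string key `"i|j|k"` for every collider
#' i -> j <- k with i and k non-adjacent (i before k lexicographically),
#' sorted. Useful for comparing orientation invariants across graphs.
#'
#' @param g a `cider_pdag` or `cider_dag`.
#' @return Sorted character vector of triple keys.
#' @export
vstructures <- function(g) {
  D <- directed_amat(g)
  A <- adjacency_amat(g)
  nodes <- g$nodes
  out <- character(0)
  for (j in seq_along(nodes)) {
    pa <- which(D[, j] == 1L)
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) {
      for (b in seq_len(a - 1L)) {
        i <- pa[b]; k <- pa[a]
        if (A[i, k] == 0L) {
          out <- c(out, paste(nodes[i], nodes[j], nodes[k], sep = "|"))
        }
      }
    }
  }
  sort(out)
}

#' Complete orientation propagation (Meek's rules)
#'
#' Directs every undirected edge whose orientation is forced by the two
#' constraints "create no new v-structure" and "create no directed cycle",
#' using the four standard pattern-completion rules. Edges whose direction
#' is not forced stay undirected. The operation is idempotent and never
#' removes or reverses an existing directed edge.
#'
#' @param g a `cider_pdag` with v-structures and constant edges already
#'   oriented.
#' @param on_conflict `"error"` (default) signals an error when
#'   propagation forces both directions on one edge or an orientation
#'   would close a directed cycle -- the sign of contradictory knowledge
#'   or CI results. `"keep_undirected"` instead leaves such edges
#'   undirected (the conservative resolution for sampling noise); the
#'   conflicted orientations are reported once and recorded in the
#'   `"propagation_conflicts"` attribute.
#' @return The closed `cider_pdag`.
#' @export
orientation_closure <- function(g, on_conflict = c("error",
                                                   "keep_undirected")) {
  on_conflict <- match.arg(on_conflict)
  blocked <- character(0)
  conflicts <- character(0)
  repeat {
    forced <- meek_forced(g)
    keys <- character(0)
    if (nrow(forced) > 0L) {
      keys <- paste(forced[, 1L], forced[, 2L], sep = ">")
      live <- !(keys %in% blocked)
      forced <- forced[live, , drop = FALSE]
      keys <- keys[live]
    }
    if (nrow(forced) == 0L) break
    clash <- keys %in% paste(forced[, 2L], forced[, 1L], sep = ">")
    if (any(clash)) {
      if (on_conflict == "error") {
        stop("orientation rules force both directions on edge ",
             forced[which(clash)[1L], 1L], " - ", forced[which(clash)[1L], 2L],
             ": contradictory knowledge or CI results", call. = FALSE)
      }
      blocked <- c(blocked, keys[clash])
      conflicts <- c(conflicts, keys[clash])
      forced <- forced[!clash, , drop = FALSE]
    }
    applied <- FALSE
    for (r in seq_len(nrow(forced))) {
      from <- forced[r, 1L]; to <- forced[r, 2L]
      if (!(g$amat[from, to] == 1L && g$amat[to, from] == 1L)) next
      g$amat[to, from] <- 0L
      if (is_acyclic(g)) {
        applied <- TRUE
      } else {
        if (on_conflict == "error") {
          stop("orienting ", from, " -> ", to, " closes a directed cycle: ",
               "contradictory knowledge or CI results", call. = FALSE)
        }
        g$amat[to, from] <- 1L
        blocked <- c(blocked, paste(from, to, sep = ">"))
        conflicts <- c(conflicts, paste(from, to, sep = ">"))
      }
    }
    if (!applied && !any(clash)) break
  }
  conflicts <- unique(conflicts)
  if (length(conflicts) > 0L) {
    message("left ", length(conflicts), " conflicted orientation(s) ",
            "undirected during propagation")
  }
  attr(g, "propagation_conflicts") <- conflicts
  g
}

# All orientations a -> b of currently-undirected edges forced by Meek's
# rules R1-R4 against the current graph. Returned as a 2-column matrix;
# both directions may appear (detected as inconsistency by the caller).
meek_forced <- function(g) {
  D <- directed_amat(g)
  U <- undirected_amat(g)
  A <- adjacency_amat(g)
  nodes <- g$nodes
  n <- length(nodes)
  out <- matrix(character(0), 0L, 2L)
  if (sum(U) == 0L) return(out)
  nonadj <- (A == 0L); diag(nonadj) <- FALSE
  # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
  r1 <- (t(D) %*% nonadj > 0L) & (U == 1L)
  # R2: a -> c -> b with a - b  =>  a -> b
  r2 <- (D %*% D > 0L) & (U == 1L)
  und <- which(U == 1L & upper.tri(U), arr.ind = TRUE)
  for (r in seq_len(nrow(und))) {
    for (swap in c(FALSE, TRUE)) {
      a <- if (swap) und[r, 2L] else und[r, 1L]
      b <- if (swap) und[r, 1L] else und[r, 2L]
      if (r1[a, b] || r2[a, b]) {
        out <- rbind(out, c(nodes[a], nodes[b]))
        next
      }
      # R3: a - c -> b, a - d -> b, c and d non-adjacent  =>  a -> b
      cand <- which(U[a, ] == 1L & D[, b] == 1L)
      hit <- FALSE
      if (length(cand) >= 2L) {
        for (i in seq_along(cand)) {
          for (j in seq_len(i - 1L)) {
            if (nonadj[cand[i], cand[j]]) { hit <- TRUE; break }
          }
          if (hit) break
        }
      }
      # R4: a adj c, a adj d, c -> d -> b, c and b non-adjacent  =>  a -> b
      if (!hit) {
        ds <- which(D[, b] == 1L & A[a, ] == 1L)
        for (d in ds) {
          cs <- which(D[, d] == 1L & A[a, ] == 1L & nonadj[, b])
          if (length(cs) > 0L) { hit <- TRUE; break }
        }
      }
      if (hit) out <- rbind(out, c(nodes[a], nodes[b]))
    }
  }
  unique(out)
}

#' Enumerate every DAG consistent with a partially directed graph
#'
#' Assigns a direction to each undirected edge in all ways that keep the
#' graph acyclic and create no v-structure absent from the input; directed
#' (including constant) edges are kept verbatim. Used as the exactness
#' oracle for the local effect-bound enumeration and on small components.
#'
#' @param g a `cider_pdag`.
#' @param max_undirected enumeration guard; an error is signalled if the
#'   graph has more undirected edges than this (default 12).
#' @return List of `cider_dag` objects.
#' @export
enumerate_consistent_dags <- function(g, max_undirected = 12L) {
  U <- undirected_amat(g)
  und <- which(U == 1L & upper.tri(U), arr.ind = TRUE)
  k <- nrow(und)
  if (k > max_undirected) {
    stop("enumeration budget exceeded: ", k, " undirected edges (guard ",
         max_undirected, ")", call. = FALSE)
  }
  base_vs <- vstructures(g)
  D0 <- directed_amat(g)
  nodes <- g$nodes
  out <- list()
  for (mask in 0:(2^k - 1L)) {
    Dm <- D0
    bits <- bitwAnd(bitwShiftR(mask, seq_len(max(k, 1L)) - 1L), 1L)
    for (e in seq_len(k)) {
      i <- und[e, 1L]; j <- und[e, 2L]
      if (bits[e] == 1L) Dm[j, i] <- 1L else Dm[i, j] <- 1L
    }
    cand <- structure(list(nodes = nodes, amat = Dm), class = "cider_dag")
    if (!is_acyclic(cand)) next
    if (!all(vstructures(cand) %in% base_vs)) next
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Pattern (CPDAG) of a DAG
#'
#' Undirects every edge, restores the directions that take part in a
#' v-structure, and completes with [orientation_closure()]. The result
#' represents the Markov-equivalence class of the input DAG.
#'
#' @param d a `cider_dag`.
#' @return A `cider_pdag`.
#' @export
dag_to_cpdag <- function(d) {
  A <- d$amat
  g <- structure(list(nodes = d$nodes,
                      amat = ((A + t(A)) > 0L) * 1L,
                      const = matrix(FALSE, length(d$nodes), length(d$nodes),
                                     dimnames = dimnames(A)),
                      sepsets = list()),
                 class = "cider_pdag")
  for (key in vstructures(d)) {
    trip <- strsplit(key, "|", fixed = TRUE)[[1L]]
    g$amat[trip[2L], trip[1L]] <- 0L
    g$amat[trip[2L], trip[3L]] <- 0L
  }
  orientation_closure(g)
}

#' Structural Hamming distance between two graphs over the same nodes
#'
#' Each unordered node pair contributes 1 when the two graphs disagree on
#' its edge (absent vs present, undirected vs directed, or opposite
#' directions).
#'
#' @param g1,g2 `cider_pdag` or `cider_dag` objects on identical node sets.
#' @return Non-negative integer.
#' @export
structural_hamming_distance <- function(g1, g2) {
  stopifnot(identical(g1$nodes, g2$nodes))
  code <- function(g) {
    a <- if (inherits(g, "cider_dag")) g$amat else g$amat
    # 0 none, 1 i->j, 2 j->i, 3 undirected (upper triangle orientation)
    up <- upper.tri(a)
    a[up] + 2L * t(a)[up]
  }
  sum(code(g1) != code(g2))
}

#' Separating-set registry helpers
#'
#' Sepsets are stored under an order-free key for each non-adjacent pair.
#'
#' @param i,j node identifiers.
#' @return `sepset_key()` returns the canonical key string.
#' @export
sepset_key <- function(i, j) {
  paste(sort(c(i, j)), collapse = "\r")
}

#' @rdname sepset_key
#' @param g a `cider_pdag`.
#' @return `get_sepset()` returns the recorded separating set (character
#'   vector) or `NULL` when none was recorded.
#' @export
get_sepset <- function(g, i, j) {
  key <- sepset_key(i, j)
  s <- g$sepsets
  if (is.environment(s)) {
    if (!exists(key, envir = s, inherits = FALSE)) return(NULL)
    get(key, envir = s)
  } else {
    s[[key]]
  }
}

#' Edge list of a graph
#'
#' @param g a `cider_pdag` or `cider_dag`.
#' @return Data frame with columns `source`, `target`, `mark`
#'   (`"directed"`/`"undirected"`), `constant` (0/1). Undirected edges
#'   appear once, with `source` lexicographically first.
#' @export
graph_edges <- function(g) {
  nodes <- g$nodes
  D <- directed_amat(g)
  U <- undirected_amat(g)
  di <- which(D == 1L, arr.ind = TRUE)
  un <- which(U == 1L & upper.tri(U), arr.ind = TRUE)
  const <- if (inherits(g, "cider_dag")) {
    rep(0L, nrow(di))
  } else {
    as.integer(g$const[di])
  }
  out <- rbind(
    data.frame(source = nodes[di[, 1L]], target = nodes[di[, 2L]],
               mark = rep("directed", nrow(di)), constant = const,
               stringsAsFactors = FALSE),
    data.frame(source = nodes[un[, 1L]], target = nodes[un[, 2L]],
               mark = rep("undirected", nrow(un)), constant = rep(0L, nrow(un)),
               stringsAsFactors = FALSE)
  )
  out[order(out$source, out$target), , drop = FALSE]
}

#' Read and write graphs as tab-separated edge lists
#'
#' The format has columns `source`, `target`, `mark`
#' (`directed`/`undirected`) and `constant` (0/1) and round-trips through
#' [read_graph_tsv()]. Separating sets are not serialized.
#'
#' @param g a `cider_pdag`.
#' @param path file path.
#' @export
write_graph_tsv <- function(g, path) {
  utils::write.table(graph_edges(g), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param nodes optional full node set (isolated nodes are not recoverable
#'   from the edge list alone).
#' @return `read_graph_tsv()` returns a `cider_pdag`.
#' @export
read_graph_tsv <- function(path, nodes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "mark", "constant")
  if (!all(need %in% names(tab))) {
    stop("graph file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  all_nodes <- unique(c(tab$source, tab$target, nodes))
  dirs <- tab$mark == "directed" & tab$constant == 0L
  und <- tab$mark == "undirected"
  cons <- tab$mark == "directed" & tab$constant == 1L
  pdag(all_nodes,
       directed = tab[dirs, c("source", "target")],
       undirected = tab[und, c("source", "target")],
       constant = tab[cons, c("source", "target")])
}

#' @export
print.cider_pdag <- function(x, ...) {
  e <- graph_edges(x)
  cat("<cider_pdag> ", length(x$nodes), " nodes, ",
      sum(e$mark == "directed"), " directed (", sum(e$constant), " constant), ",
      sum(e$mark == "undirected"), " undirected edges\n", sep = "")
  invisible(x)
}

#' @export
print.cider_dag <- function(x, ...) {
  cat("<cider_dag> ", length(x$nodes), " nodes, ", sum(x$amat),
      " directed edges\n", sep = "")
  invisible(x)
}
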