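#' Causal effect of one gene on another in a fixed DAG
#'
#' Under the joint-Gaussian linear model, the total causal effect of
#' `cause` on `effect` is the coefficient of `cause` in the ordinary
#' least-squares regression of `effect` on `cause` and the parents of
#' `cause` (adjusting for the cause's parent set blocks every back-door
#' path while leaving all directed paths open). When `effect` is itself a
#' parent of `cause` the effect is 0 by definition: intervening on a node
#' cannot change its causes.
#'
#' @param data a `cider_expr`.
#' @param dag a `cider_dag` over (a superset of) the genes involved.
#' @param cause,effect gene identifiers, distinct.
#' @return The estimated causal effect (expression change of `effect` per
#'   unit change of `cause`).
#' @export
causal_effect_in_dag <- function(data, dag, cause, effect) {
  if (cause == effect) stop("cause and effect must differ", call. = FALSE)
  pa <- pdag_parents(dag, cause)
  if (effect %in% pa) return(0)
  drop(ols_cause_coef(data$values, cause, pa, effect))
}

# Coefficient of `cause` in the multi-response OLS regression of each
# column in `effects` on (intercept, cause, parents). Data are used on
# their native expression scale.
ols_cause_coef <- function(X, cause, parents, effects) {
  Z <- cbind(1, X[, c(cause, parents), drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("rank-deficient regression design for cause '", cause,
         "' with parents {", paste(parents, collapse = ", "),
         "}; collinear genes", call. = FALSE)
  }
  B <- qr.coef(qz, X[, effects, drop = FALSE])
  B[2L, ]
}

#' Admissible local parent sets of a cause in a partially directed graph
#'
#' IDA-style local enumeration: in the Markov-equivalence class
#' represented by the graph, the possible parent sets of `cause` are its
#' directed parents plus any subset S of its undirected neighbours whose
#' orientation towards `cause` creates no new v-structure at `cause` --
#' i.e. every member of S is adjacent to every other member of S and to
#' every existing parent. Enumerated deterministically by subset size and
#' then lexicographically.
#'
#' Admissible subsets are exactly the cliques among the eligible
#' neighbours, so enumeration walks the clique tree instead of all
#' 2^k subsets and stays cheap even for hub genes.
#'
#' @param g a `cider_pdag`.
#' @param cause gene identifier.
#' @param max_parent_sets enumeration guard on the number of admissible
#'   parent sets (default 10000).
#' @return List of character vectors, each a candidate parent set
#'   (directed parents first), ordered by the number of added neighbours
#'   and then lexicographically.
#' @export
valid_parent_sets <- function(g, cause, max_parent_sets = 10000L) {
  pa <- pdag_parents(g, cause)
  sib <- pdag_siblings(g, cause)
  A <- adjacency_amat(g)
  cand <- sib[vapply(sib, function(s) all(A[s, pa] == 1L), logical(1))]
  cliques <- list(character(0))
  extend <- function(cur, rest) {
    for (i in seq_along(rest)) {
      s <- rest[i]
      new <- c(cur, s)
      cliques[[length(cliques) + 1L]] <<- new
      if (length(cliques) > max_parent_sets) {
        stop("enumeration budget exceeded for '", cause, "': more than ",
             max_parent_sets, " admissible parent sets", call. = FALSE)
      }
      later <- rest[-seq_len(i)]
      extend(new, later[A[s, later] == 1L])
    }
  }
  extend(character(0), cand)
  keys <- vapply(cliques, function(s) paste(s, collapse = ","), character(1))
  ord <- order(lengths(cliques), keys)
  lapply(cliques[ord], function(s) c(pa, s))
}

#' Lower bound on the causal effect over admissible orientations
#'
#' Because the learned graph identifies the causal structure only up to
#' its equivalence class, the effect of `cause` on `effect` is a set of
#' values, one per admissible orientation. Following the
#' intervention-calculus bound, the value of smallest absolute magnitude
#' is returned (sign preserved; ties broken by the deterministic
#' enumeration order of [valid_parent_sets()]).
#'
#' @inheritParams causal_effect_in_dag
#' @param graph a `cider_pdag`, typically from [learn_structure()].
#' @param max_parent_sets guard passed to [valid_parent_sets()].
#' @return The minimum-|effect| estimate.
#' @export
causal_effect_bound <- function(data, graph, cause, effect,
                                max_parent_sets = 10000L) {
  if (cause == effect) stop("cause and effect must differ", call. = FALSE)
  sets <- valid_parent_sets(graph, cause, max_parent_sets)
  best <- NULL
  for (pa in sets) {
    v <- if (effect %in% pa) 0 else
      drop(ols_cause_coef(data$values, cause, pa, effect))
    if (is.null(best) || abs(v) < abs(best)) best <- v
  }
  best
}

#' miRNA-by-mRNA matrix of causal-effect lower bounds
#'
#' Fills entry (i, j) with [causal_effect_bound()] for miRNA i on mRNA j
#' (TF-coding mRNAs included as effect candidates), sharing the local
#' parent-set enumeration and one multi-response regression per parent
#' set, so large gene panels stay tractable.
#'
#' @param data a `cider_expr` whose roles identify at least one miRNA and
#'   one mRNA.
#' @param graph a `cider_pdag` from [learn_structure()].
#' @param max_parent_sets guard passed to [valid_parent_sets()].
#' @return A numeric matrix with miRNAs in rows and mRNAs in columns.
#' @export
effects_matrix <- function(data, graph, max_parent_sets = 10000L) {
  mirnas <- sort(genes_by_role(data, "mirna"))
  mrnas <- sort(genes_by_role(data, c("mrna", "tf_mrna")))
  if (length(mirnas) == 0L || length(mrnas) == 0L) {
    stop("roles must identify at least one miRNA and one mRNA",
         call. = FALSE)
  }
  C <- matrix(0, length(mirnas), length(mrnas),
              dimnames = list(mirnas, mrnas))
  X <- data$values
  for (mi in mirnas) {
    sets <- valid_parent_sets(graph, mi, max_parent_sets)
    best <- rep(NA_real_, length(mrnas))
    for (pa in sets) {
      coefs <- ols_cause_coef(X, mi, pa, mrnas)
      coefs[mrnas %in% pa] <- 0
      take <- is.na(best) | abs(coefs) < abs(best)
      best[take] <- coefs[take]
    }
    C[mi, ] <- best
  }
  C
}

#' Ranked miRNA-target predictions from an effect or score matrix
#'
#' @param C numeric matrix, miRNAs in rows and mRNAs in columns.
#' @return Data frame with columns `mirna`, `mrna`, `effect`,
#'   `abs_effect`, `rank`, ordered by decreasing absolute effect with
#'   lexicographic (mirna, mrna) tie-breaking.
#' @export
ranked_targets <- function(C) {
  out <- data.frame(mirna = rep(rownames(C), times = ncol(C)),
                    mrna = rep(colnames(C), each = nrow(C)),
                    effect = as.vector(C),
                    stringsAsFactors = FALSE)
  out$abs_effect <- abs(out$effect)
  out <- out[order(-out$abs_effect, out$mirna, out$mrna), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
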