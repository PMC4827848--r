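#' Per-miRNA top-k target predictions
#'
#' For each miRNA (row) returns the k mRNAs with largest absolute score;
#' ties are broken by lexicographic mRNA identifier.
#'
#' @param scores numeric matrix, miRNAs in rows and mRNAs in columns.
#' @param k number of targets per miRNA (at least 1).
#' @return Data frame with columns `mirna`, `mrna`.
#' @export
top_k_targets <- function(scores, k) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  k <- min(k, ncol(scores))
  mrnas <- colnames(scores)
  rows <- lapply(rownames(scores), function(mi) {
    ord <- order(-abs(scores[mi, ]), mrnas)
    data.frame(mirna = mi, mrna = mrnas[ord[seq_len(k)]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global top-n pair predictions
#'
#' Takes the n (miRNA, mRNA) pairs with largest absolute score across the
#' whole matrix; ties are broken by lexicographic (mirna, mrna). With n
#' equal to the number of true edges, precision and recall (and hence the
#' F-score) coincide, which removes the arbitrary per-miRNA cutoff from
#' simulation benchmarks.
#'
#' @param scores numeric matrix, miRNAs in rows and mRNAs in columns.
#' @param n number of pairs to predict.
#' @return Data frame with columns `mirna`, `mrna`.
#' @export
top_n_global <- function(scores, n) {
  ranked <- ranked_targets(scores)
  ranked[seq_len(min(n, nrow(ranked))), c("mirna", "mrna"), drop = FALSE]
}

edge_pair_keys <- function(x) {
  if (inherits(x, "cider_knowledge")) return(pair_keys(x))
  if (is.data.frame(x)) return(paste(x[[1L]], x[[2L]], sep = "\r"))
  stop("expected a data frame of pairs", call. = FALSE)
}

#' Precision, recall and F-score of edge predictions
#'
#' Precision is the fraction of predicted pairs that are true, recall the
#' fraction of true pairs predicted, and F their harmonic mean
#' F = 2 * precision * recall / (precision + recall) (0 when both are 0).
#' An empty prediction set has precision 0 by convention.
#'
#' @param predicted data frame of predicted (mirna, mrna) pairs (first
#'   two columns used).
#' @param truth data frame of true pairs; must be non-empty (recall is
#'   undefined otherwise).
#' @return A list of class `cider_eval` with fields `precision`,
#'   `recall`, `f_score`, `n_predicted`, `n_true`, `n_hits`.
#' @export
f_score <- function(predicted, truth) {
  truth_keys <- unique(edge_pair_keys(truth))
  if (length(truth_keys) == 0L) {
    stop("ground truth is empty: recall is undefined", call. = FALSE)
  }
  pred_keys <- unique(edge_pair_keys(predicted))
  hits <- sum(pred_keys %in% truth_keys)
  precision <- if (length(pred_keys) == 0L) 0 else hits / length(pred_keys)
  recall <- hits / length(truth_keys)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f_score = f,
                 n_predicted = length(pred_keys),
                 n_true = length(truth_keys), n_hits = hits),
            class = "cider_eval")
}

#' @export
print.cider_eval <- function(x, ...) {
  cat(sprintf(
    "<cider_eval> precision %.3f, recall %.3f, F %.3f (%d predicted, %d true, %d hits)\n",
    x$precision, x$recall, x$f_score, x$n_predicted, x$n_true, x$n_hits))
  invisible(x)
}

#' Count predictions validated by a knowledge database
#'
#' The real-data summary metric: how many predicted (miRNA, mRNA) pairs
#' appear in a database of experimentally validated interactions.
#'
#' @param predicted data frame of predicted pairs.
#' @param database a `cider_knowledge` set (or pair data frame).
#' @return Integer count.
#' @export
count_validated <- function(predicted, database) {
  sum(unique(edge_pair_keys(predicted)) %in% edge_pair_keys(database))
}

#' Knowledge-sweep experiment on simulated networks
#'
#' For each replicate network: simulate expression data, then for every
#' knowledge fraction and knowledge type reveal that share of the true
#' regulatory edges as constant-edge knowledge, learn the structure,
#' estimate the causal-effect matrix, predict the top-N pairs globally
#' (N = number of true miRNA-to-mRNA edges, making precision = recall =
#' F), and score against the true miRNA-to-mRNA edge set. Knowledge
#' subsets are nested across fractions, so each curve is monotone in the
#' amount of information by construction.
#'
#' @param n_networks number of replicate networks (the full study design
#'   uses 50; reduced profiles are appropriate for quick runs).
#' @param n_nodes,n_samples network size and sample count per replicate.
#' @param fractions knowledge fractions to sweep (default 0 to 0.5 by
#'   0.05).
#' @param types knowledge types: any of `"tf_mirna"`, `"mirna_mrna"`,
#'   `"combined"`.
#' @param alpha,max_cond_size structure-learning parameters.
#' @param role_fractions,edge_prob,mean_in_degree,noise passed to
#'   [generate_network()].
#' @param max_parent_sets passed to [effects_matrix()].
#' @param seed master seed; every network, dataset and knowledge draw is
#'   derived from it.
#' @param verbose print one line per replicate.
#' @return Data frame with columns `fraction`, `type`, `replicate`,
#'   `precision`, `recall`, `f_score`.
#' @export
knowledge_sweep <- function(n_networks = 50L, n_nodes = 1000L,
                            n_samples = 250L,
                            fractions = seq(0, 0.5, by = 0.05),
                            types = c("tf_mirna", "mirna_mrna", "combined"),
                            alpha = 0.01, max_cond_size = 3L,
                            role_fractions = c(mirna = 0.1, tf_mrna = 0.1,
                                               mrna = 0.8),
                            edge_prob = NULL, mean_in_degree = 2,
                            noise = "uniform", max_parent_sets = 10000L,
                            seed = 1L, verbose = FALSE) {
  rows <- list()
  for (rep_i in seq_len(n_networks)) {
    sim <- simulate_study_instance(n_nodes, n_samples,
                                   seed = seed + 101L * rep_i,
                                   role_fractions = role_fractions,
                                   edge_prob = edge_prob,
                                   mean_in_degree = mean_in_degree,
                                   noise = noise)
    cache <- new.env(parent = emptyenv())
    for (frac in fractions) {
      for (ty in types) {
        kn <- sweep_knowledge(sim$network, frac, ty, seed + 3L * rep_i)
        key <- paste0("k", paste(sort(pair_keys(kn)), collapse = ";"))
        if (!is.null(cache[[key]])) {
          res <- cache[[key]]
        } else {
          g <- suppressMessages(
            learn_structure(sim$data, kn, alpha = alpha,
                            max_cond_size = max_cond_size))
          C <- effects_matrix(sim$data, g, max_parent_sets = max_parent_sets)
          pred <- top_n_global(C, nrow(sim$truth))
          res <- f_score(pred, sim$truth)
          cache[[key]] <- res
        }
        rows[[length(rows) + 1L]] <-
          data.frame(fraction = frac, type = ty, replicate = rep_i,
                     precision = res$precision, recall = res$recall,
                     f_score = res$f_score, stringsAsFactors = FALSE)
      }
    }
    if (verbose) {
      message("replicate ", rep_i, "/", n_networks, " done")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate one benchmark instance: network, data and ground truth
#'
#' Convenience wrapper used by [knowledge_sweep()] and by method
#' comparisons that need the identical replicate inputs: generates a
#' network and expression data, and extracts the true miRNA-to-mRNA edge
#' set used as evaluation ground truth. In the rare event that a network
#' has no miRNA-to-mRNA edge (F would be undefined) the network seed is
#' re-drawn deterministically.
#'
#' @inheritParams knowledge_sweep
#' @param seed instance seed.
#' @return List with elements `network` (`cider_network`), `data`
#'   (`cider_expr`) and `truth` (`cider_knowledge`, type `mirna_mrna`).
#' @export
simulate_study_instance <- function(n_nodes, n_samples, seed,
                                    role_fractions = c(mirna = 0.1,
                                                       tf_mrna = 0.1,
                                                       mrna = 0.8),
                                    edge_prob = NULL, mean_in_degree = 2,
                                    noise = "uniform") {
  for (try_i in 0:20) {
    net_seed <- seed + 100003L * try_i
    network <- generate_network(n_nodes, role_fractions = role_fractions,
                                edge_prob = edge_prob,
                                mean_in_degree = mean_in_degree,
                                noise = noise, seed = net_seed)
    truth_all <- true_knowledge(network)
    truth <- truth_all[truth_all$type == "mirna_mrna", , drop = FALSE]
    if (nrow(truth) > 0L) {
      data <- generate_expression(network, n_samples, seed = net_seed + 1L)
      return(list(network = network, data = data, truth = truth))
    }
  }
  stop("could not simulate a network with miRNA->mRNA edges", call. = FALSE)
}

sweep_knowledge <- function(network, fraction, type, seed) {
  types <- switch(type,
                  combined = c("tf_mirna", "mirna_mrna"),
                  tf_mirna = "tf_mirna",
                  mirna_mrna = "mirna_mrna",
                  stop("unknown knowledge type: ", type, call. = FALSE))
  sample_knowledge(network, fraction, types = types, seed = seed)
}

#' Summarize a knowledge-sweep table
#'
#' @param sweep_table output of [knowledge_sweep()].
#' @return Data frame with one row per (fraction, type): mean, sd and
#'   Monte-Carlo standard error of the F-score, and replicate count.
#' @export
summarize_sweep <- function(sweep_table) {
  agg <- stats::aggregate(f_score ~ fraction + type, data = sweep_table,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(fraction = agg$fraction, type = agg$type,
                    mean_f = agg$f_score[, "mean"],
                    sd_f = agg$f_score[, "sd"],
                    n = agg$f_score[, "n"])
  out$se_f <- out$sd_f / sqrt(out$n)
  out[order(out$type, out$fraction), , drop = FALSE]
}
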