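#' End-to-end miRNA target prediction pipeline
#'
#' Orchestrates knowledge input, structure learning, causal-effect
#' estimation and (when ground truth is supplied) evaluation, writing all
#' artifacts to an output directory: `graph.tsv` (learned structure),
#' `effects.tsv` (miRNA-by-mRNA effect matrix), `predictions.tsv` (ranked
#' pair list), `evaluation.tsv` and `manifest.tsv` (configuration echo,
#' seed, versions). Identical configurations produce byte-identical
#' numeric outputs.
#'
#' @param config named list:
#'   \describe{
#'     \item{expression, roles}{paths of the expression matrix and role
#'       table (required).}
#'     \item{knowledge}{optional path of a knowledge TSV.}
#'     \item{knowledge_type}{default interaction type for knowledge rows
#'       without a `type` column (default `"mirna_mrna"`).}
#'     \item{ground_truth}{optional path of a true-edge TSV used for
#'       evaluation; overlapping pairs are removed from the knowledge.}
#'     \item{alpha, max_cond_size}{learner parameters (defaults 0.01, 3).}
#'     \item{k}{per-miRNA prediction cutoff for evaluation (optional; the
#'       default evaluates top-N global pairs with N = number of true
#'       pairs).}
#'     \item{seed}{non-negative integer seed (default 1).}
#'     \item{out_dir}{output directory (required; created if absent).}
#'   }
#' @return Invisibly, a list with the learned graph, effect matrix,
#'   predictions and evaluation result (or `NULL`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  data <- stage("read_expression",
                read_expression_tsv(cfg$expression, cfg$roles))
  knowledge <- stage("read_knowledge", {
    if (is.null(cfg$knowledge)) NULL else {
      kn <- read_interactions(cfg$knowledge,
                              interaction_type = cfg$knowledge_type)
      restrict_to_universe(kn, data)
    }
  })
  truth <- stage("read_ground_truth", {
    if (is.null(cfg$ground_truth)) NULL else
      read_interactions(cfg$ground_truth,
                        interaction_type = cfg$knowledge_type)
  })
  if (!is.null(knowledge) && !is.null(truth)) {
    knowledge <- separate_knowledge_from_ground_truth(knowledge, truth)
  }
  graph <- stage("learn_structure",
                 learn_structure(data, knowledge, alpha = cfg$alpha,
                                 max_cond_size = cfg$max_cond_size))
  C <- stage("effects_matrix", effects_matrix(data, graph))
  preds <- stage("rank_targets", ranked_targets(C))
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- stage("evaluate", {
      pred_pairs <- if (is.null(cfg$k)) {
        top_n_global(C, nrow(truth))
      } else {
        top_k_targets(C, cfg$k)
      }
      f_score(pred_pairs, truth)
    })
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_graph_tsv(graph, out("graph.tsv"))
  utils::write.table(data.frame(mirna = rownames(C), C, check.names = FALSE),
                     out("effects.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(preds, out("predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  eval_df <- if (is.null(evaluation)) {
    data.frame(metric = character(0), value = numeric(0))
  } else {
    data.frame(metric = c("precision", "recall", "f_score", "n_predicted",
                          "n_true", "n_hits"),
               value = unlist(evaluation, use.names = FALSE))
  }
  utils::write.table(eval_df, out("evaluation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    key = c("package_version", "r_version", "seed", "alpha",
            "max_cond_size", "expression", "roles", "knowledge",
            "ground_truth", "k"),
    value = c(as.character(utils::packageVersion("cider")),
              paste(R.version$major, R.version$minor, sep = "."),
              cfg$seed, cfg$alpha, cfg$max_cond_size, cfg$expression,
              cfg$roles, cfg$knowledge %||% "", cfg$ground_truth %||% "",
              cfg$k %||% ""))
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(graph = graph, effects = C, predictions = preds,
                 evaluation = evaluation))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  stopifnot(is.list(config))
  # exact [[-indexing: $ would let "k" partially match "knowledge"
  cfg <- list(
    expression = config[["expression"]], roles = config[["roles"]],
    knowledge = config[["knowledge"]],
    knowledge_type = config[["knowledge_type"]] %||% "mirna_mrna",
    ground_truth = config[["ground_truth"]],
    alpha = config[["alpha"]] %||% 0.01,
    max_cond_size = config[["max_cond_size"]] %||% 3L,
    k = config[["k"]], seed = config[["seed"]] %||% 1L,
    out_dir = config[["out_dir"]])
  if (is.null(cfg$expression) || is.null(cfg$roles) || is.null(cfg$out_dir)) {
    stop("config needs 'expression', 'roles' and 'out_dir'", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || cfg$seed < 0) {
    stop("seed must be a non-negative integer", call. = FALSE)
  }
  for (f in c("expression", "roles", "knowledge", "ground_truth")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config file for '", f, "' not found: ", cfg[[f]], call. = FALSE)
    }
  }
  cfg
}
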