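#' Pearson-correlation baseline
#'
#' Scores each miRNA-mRNA pair by the absolute Pearson correlation of
#' their expression columns.
#'
#' @param data a `cider_expr`.
#' @return Numeric score matrix, miRNAs in rows and mRNAs (including
#'   TF-coding mRNAs) in columns; entries in [0, 1].
#' @export
pearson_scores <- function(data) {
  mirnas <- sort(genes_by_role(data, "mirna"))
  mrnas <- sort(genes_by_role(data, c("mrna", "tf_mrna")))
  X <- data$values
  check_nonzero_variance(X, c(mirnas, mrnas))
  abs(stats::cor(X[, mirnas, drop = FALSE], X[, mrnas, drop = FALSE]))
}

#' Lasso-regression baseline
#'
#' For every mRNA, fits an L1-penalized linear regression of its
#' expression on all miRNA columns and scores each miRNA by the absolute
#' value of its coefficient. The penalty is chosen by seeded k-fold
#' cross-validation.
#'
#' @param data a `cider_expr` with at least two miRNAs.
#' @param penalty_selection `"lambda.min"` (default) or `"lambda.1se"`,
#'   the cross-validated penalty handed to [glmnet::cv.glmnet()].
#' @param nfolds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return Numeric score matrix, miRNAs in rows and mRNAs in columns.
#' @export
lasso_scores <- function(data, penalty_selection = c("lambda.min",
                                                     "lambda.1se"),
                         nfolds = 5L, seed = 1L) {
  penalty_selection <- match.arg(penalty_selection)
  mirnas <- sort(genes_by_role(data, "mirna"))
  mrnas <- sort(genes_by_role(data, c("mrna", "tf_mrna")))
  if (length(mirnas) < 2L) stop("lasso baseline needs at least 2 miRNAs",
                                call. = FALSE)
  X <- data$values
  check_nonzero_variance(X, c(mirnas, mrnas))
  Xmi <- X[, mirnas, drop = FALSE]
  foldid <- with_seed(seed,
                      sample(rep(seq_len(nfolds), length.out = nrow(X))))
  out <- matrix(0, length(mirnas), length(mrnas),
                dimnames = list(mirnas, mrnas))
  for (j in mrnas) {
    fit <- glmnet::cv.glmnet(Xmi, X[, j], foldid = foldid)
    beta <- as.numeric(stats::coef(fit, s = penalty_selection))[-1L]
    out[, j] <- abs(beta)
  }
  out
}

#' Z-score pseudo-knock-out baseline
#'
#' Treats the sample where a miRNA attains its minimum expression as a
#' knock-out of that miRNA and scores each mRNA by how far its expression
#' in that sample deviates from its mean, in standard-deviation units:
#' score(i, j) = |x_j(s*) - mean(x_j)| / sd(x_j) with s* =
#' argmin_s x_i(s).
#'
#' @param data a `cider_expr` with at least two samples.
#' @return Numeric score matrix, miRNAs in rows and mRNAs in columns.
#' @export
zscore_scores <- function(data) {
  mirnas <- sort(genes_by_role(data, "mirna"))
  mrnas <- sort(genes_by_role(data, c("mrna", "tf_mrna")))
  X <- data$values
  if (nrow(X) < 2L) stop("z-score baseline needs at least 2 samples",
                         call. = FALSE)
  check_nonzero_variance(X, mrnas)
  mu <- colMeans(X[, mrnas, drop = FALSE])
  sd_ <- apply(X[, mrnas, drop = FALSE], 2L, stats::sd)
  out <- matrix(0, length(mirnas), length(mrnas),
                dimnames = list(mirnas, mrnas))
  for (i in mirnas) {
    s_star <- which.min(X[, i])
    out[i, ] <- abs(X[s_star, mrnas] - mu) / sd_
  }
  out
}

check_nonzero_variance <- function(X, genes) {
  sds <- apply(X[, genes, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(utils::head(genes[sds == 0], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run one baseline by name
#'
#' @param data a `cider_expr`.
#' @param method `"pearson"`, `"lasso"` or `"zscore"`.
#' @param ... passed to the method.
#' @return Numeric score matrix, miRNAs in rows and mRNAs in columns.
#' @export
baseline_scores <- function(data, method = c("pearson", "lasso", "zscore"),
                            ...) {
  method <- match.arg(method)
  switch(method,
         pearson = pearson_scores(data),
         lasso = lasso_scores(data, ...),
         zscore = zscore_scores(data))
}
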