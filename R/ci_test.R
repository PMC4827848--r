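#' Fisher-z conditional-independence test
#'
#' Tests whether genes `i` and `j` are conditionally independent given the
#' set `S`, under the joint-Gaussian assumption: the partial correlation
#' r(i, j | S) is computed by inverting the correlation submatrix of
#' `{i, j} U S`, transformed with Fisher's z = atanh(r), and the statistic
#' sqrt(n - |S| - 3) * |z| is referred to the standard normal.
#'
#' @param data a `cider_expr`.
#' @param i,j gene identifiers, distinct and not in `S`.
#' @param S character vector of conditioning genes (may be empty).
#' @param alpha significance level; the pair is declared independent when
#'   the two-sided p-value exceeds `alpha`.
#' @return A list of class `cider_ci` with fields `pair`,
#'   `conditioning_set`, `statistic`, `p_value`, `independent`.
#' @export
fisher_z_ci_test <- function(data, i, j, S = character(0), alpha = 0.01) {
  S <- setdiff(as.character(S), character(0))
  if (i == j) stop("i and j must differ", call. = FALSE)
  if (i %in% S || j %in% S) {
    stop("conditioning set must not contain i or j", call. = FALSE)
  }
  X <- data$values
  miss <- setdiff(c(i, j, S), colnames(X))
  if (length(miss) > 0L) stop("unknown gene(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(X)
  if (n <= length(S) + 3L) {
    stop("need more than |S| + 3 = ", length(S) + 3L,
         " samples for the Fisher-z test, have ", n, call. = FALSE)
  }
  C <- stats::cor(X[, c(i, j, S), drop = FALSE])
  r <- partial_cor(C, 1L, 2L, seq_along(S) + 2L,
                   genes = c(i, j, S))
  stat <- sqrt(n - length(S) - 3) * abs(atanh(clamp_cor(r)))
  p <- 2 * stats::pnorm(-stat)
  structure(list(pair = c(i, j), conditioning_set = S,
                 statistic = stat, p_value = p,
                 independent = p > alpha),
            class = "cider_ci")
}

#' @export
print.cider_ci <- function(x, ...) {
  cat("<cider_ci> ", x$pair[1L], " _||_ ", x$pair[2L], " | {",
      paste(x$conditioning_set, collapse = ", "), "}: z-stat = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      if (x$independent) " (independent)" else " (dependent)", "\n", sep = "")
  invisible(x)
}

# Partial correlation of columns i, j of a correlation matrix given the
# columns in S (all integer indices into C). |S| is small (<= the PC
# conditioning bound), so direct inversion of the (|S|+2) submatrix is
# cheapest.
partial_cor <- function(C, i, j, S, genes = colnames(C)) {
  if (length(S) == 0L) return(C[i, j])
  idx <- c(i, j, S)
  P <- tryCatch(solve(C[idx, idx]),
                error = function(e) {
                  stop("singular correlation submatrix for genes {",
                       paste(genes[idx], collapse = ", "),
                       "}; remove collinear columns", call. = FALSE)
                })
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

clamp_cor <- function(r) {
  max(min(r, 1 - 1e-12), -1 + 1e-12)
}
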