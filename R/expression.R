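#' Expression matrix with gene roles
#'
#' Container for matched miRNA/mRNA expression profiles: a numeric matrix
#' with samples in rows and genes in columns (normalized, log-scale
#' expression assumed upstream), plus a role for every gene
#' (`"mirna"`, `"mrna"` or `"tf_mrna"` for transcription-factor-coding
#' mRNAs). All structure learning and effect estimation consumes this
#' object.
#'
#' @param values numeric matrix, rows = samples, columns = genes; must
#'   have column names (gene identifiers) and contain no missing values.
#' @param roles named character vector mapping every gene to its role.
#' @return An object of class `cider_expr`.
#' @export
expression_matrix <- function(values, roles) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have gene column names",
                                      call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (anyNA(values)) stop("expression matrix contains missing values",
                          call. = FALSE)
  if (nrow(values) < 3L) stop("at least 3 samples are required", call. = FALSE)
  roles <- vapply(roles, as.character, character(1))
  bad_role <- setdiff(unique(roles), c("mirna", "mrna", "tf_mrna"))
  if (length(bad_role) > 0L) {
    stop("unknown roles: ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  missing_roles <- setdiff(colnames(values), names(roles))
  if (length(missing_roles) > 0L) {
    stop("no role for genes: ",
         paste(utils::head(missing_roles, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(values = values,
                 roles = roles[colnames(values)]),
            class = "cider_expr")
}

#' @export
print.cider_expr <- function(x, ...) {
  tab <- table(x$roles)
  cat("<cider_expr> ", nrow(x$values), " samples x ", ncol(x$values),
      " genes (", paste(names(tab), as.integer(tab), sep = ": ",
                        collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Genes of a given role
#'
#' @param data a `cider_expr`.
#' @param roles character vector of roles to keep.
#' @return Character vector of gene identifiers, in column order.
#' @export
genes_by_role <- function(data, roles) {
  names(data$roles)[data$roles %in% roles]
}

#' Read and write expression matrices and role tables
#'
#' The expression format is tab-separated with gene identifiers in the
#' first row and sample identifiers in the first column; the role table
#' has columns `gene_id` and `role`.
#'
#' @param path file path.
#' @param roles_path path of the role table.
#' @return `read_expression_tsv()` returns a `cider_expr`.
#' @export
read_expression_tsv <- function(path, roles_path) {
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  roles <- read_roles_tsv(roles_path)
  expression_matrix(as.matrix(tab), roles)
}

#' @rdname read_expression_tsv
#' @return `read_roles_tsv()` returns a named character vector of roles.
#' @export
read_roles_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "role") %in% names(tab))) {
    stop("role file must have columns gene_id and role", call. = FALSE)
  }
  stats::setNames(trimws(tab$role), trimws(tab$gene_id))
}

#' @rdname read_expression_tsv
#' @param data a `cider_expr`.
#' @export
write_expression_tsv <- function(data, path, roles_path = NULL) {
  out <- data.frame(sample_id = rownames(data$values),
                    data$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roles_path)) {
    utils::write.table(
      data.frame(gene_id = names(data$roles), role = unname(data$roles)),
      roles_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
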