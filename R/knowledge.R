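#' Regulatory-knowledge interaction sets
#'
#' A knowledge set holds experimentally validated (or database-predicted)
#' regulator-to-target interactions of two kinds: transcriptional
#' TF-to-miRNA regulation (`"tf_mirna"`) and post-transcriptional
#' miRNA-to-mRNA regulation (`"mirna_mrna"`). During structure learning
#' each record becomes a constant edge, fixed in existence and direction.
#'
#' Records are deduplicated on the (regulator, target) pair; identifiers
#' are whitespace-trimmed with case preserved.
#'
#' @param regulator,target character vectors of gene identifiers.
#' @param type interaction type, `"tf_mirna"` or `"mirna_mrna"`
#'   (recycled).
#' @param source free-text provenance tag (recycled).
#' @return A data frame of class `cider_knowledge` with columns
#'   `regulator`, `target`, `type`, `source`.
#' @export
knowledge_set <- function(regulator = character(0), target = character(0),
                          type = character(0), source = "user") {
  regulator <- trimws(as.character(regulator))
  target <- trimws(as.character(target))
  if (length(regulator) != length(target)) {
    stop("regulator and target must have equal length", call. = FALSE)
  }
  n <- length(regulator)
  type <- rep_len(as.character(type), if (n > 0L) n else length(type))
  bad_type <- setdiff(unique(type), c("tf_mirna", "mirna_mrna"))
  if (length(bad_type) > 0L) {
    stop("unknown interaction type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (any(regulator == target)) {
    stop("self-regulation records are not allowed: ",
         regulator[which(regulator == target)[1L]], call. = FALSE)
  }
  out <- data.frame(regulator = regulator, target = target,
                    type = rep_len(type, n), source = rep_len(source, n),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("regulator", "target")]), , drop = FALSE]
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cider_knowledge", "data.frame")
  out
}

pair_keys <- function(k) paste(k$regulator, k$target, sep = "\r")

#' Read a regulatory-knowledge table
#'
#' Expects a tab-separated file with a header containing at least
#' `regulator` and `target` columns; an optional `type` column carries the
#' interaction type per row (otherwise `interaction_type` applies to all
#' rows). Extra columns are ignored.
#'
#' @param path file path.
#' @param interaction_type default interaction type for rows without a
#'   `type` column.
#' @param source provenance tag stored with each record (default: the file
#'   name).
#' @return A `cider_knowledge` set, deduplicated.
#' @export
read_interactions <- function(path, interaction_type = "mirna_mrna",
                              source = basename(path)) {
  if (!file.exists(path)) stop("knowledge file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("knowledge file is empty: ", path,
                                call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  reg_col <- match("regulator", header)
  tgt_col <- match("target", header)
  typ_col <- match("type", header)
  if (is.na(reg_col) || is.na(tgt_col)) {
    stop("knowledge file must have 'regulator' and 'target' columns: ",
         path, call. = FALSE)
  }
  body <- fields[-1L]
  if (length(body) == 0L) return(knowledge_set())
  short <- which(vapply(body, length, integer(1)) < max(reg_col, tgt_col))
  if (length(short) > 0L) {
    stop("malformed row (fewer than 2 columns) at line ", short[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  regulator <- vapply(body, `[[`, character(1), reg_col)
  target <- vapply(body, `[[`, character(1), tgt_col)
  type <- if (!is.na(typ_col)) {
    vapply(body, function(f) {
      if (length(f) >= typ_col && nzchar(trimws(f[[typ_col]]))) {
        trimws(f[[typ_col]])
      } else interaction_type
    }, character(1))
  } else {
    rep(interaction_type, length(body))
  }
  knowledge_set(regulator, target, type, source)
}

#' Restrict knowledge to the gene universe of an expression matrix
#'
#' Keeps only records whose regulator and target are both present in
#' `genes`; records referencing genes absent from the expression data are
#' dropped with a message (they cannot constrain a graph that does not
#' contain them).
#'
#' @param knowledge a `cider_knowledge` set.
#' @param genes character vector of gene identifiers, or a `cider_expr`.
#' @return The filtered `cider_knowledge` set, with attribute `n_dropped`
#'   holding the number of records removed.
#' @export
restrict_to_universe <- function(knowledge, genes) {
  if (inherits(genes, "cider_expr")) genes <- colnames(genes$values)
  keep <- knowledge$regulator %in% genes & knowledge$target %in% genes
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message("dropped ", dropped,
            " knowledge record(s) outside the expression gene universe")
  }
  out <- knowledge[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Separate prior knowledge from evaluation ground truth
#'
#' Any (regulator, target) pair present in both the prior knowledge and
#' the ground-truth set is removed from the knowledge and kept only for
#' evaluation, so that an interaction can never be both an input
#' constraint and a scored hit.
#'
#' @param knowledge a `cider_knowledge` set used as prior knowledge.
#' @param ground_truth a `cider_knowledge` set reserved for evaluation.
#' @return The knowledge set minus every pair present in `ground_truth`.
#' @export
separate_knowledge_from_ground_truth <- function(knowledge, ground_truth) {
  keep <- !(pair_keys(knowledge) %in% pair_keys(ground_truth))
  out <- knowledge[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cider_knowledge <- function(x, ...) {
  cat("<cider_knowledge> ", nrow(x), " record(s)",
      if (nrow(x) > 0L) paste0(" (", paste(names(table(x$type)),
                                           as.integer(table(x$type)),
                                           sep = ": ", collapse = ", "), ")"),
      "\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}
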