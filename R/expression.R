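#' Expression matrix with sample and class metadata
#'
#' Lightweight container for a transcripts-by-samples abundance matrix on a
#' TPM-like linear scale, together with the group label of every sample, the
#' species, and the RNA class of the rows. All downstream statistics
#' (fold changes, Welch tests, correlations) operate on this container.
#'
#' @param values numeric matrix, transcripts in rows, samples in columns.
#'   Row and column names are required and must be unique; values must be
#'   finite and non-negative.
#' @param group_of named character vector mapping every sample id (column
#'   name) to its group label, e.g. `c("LAC:1" = "LAC", ...)`. If `NULL`,
#'   groups are parsed from column names of the form `group:replicate`.
#' @param species species label, e.g. `"cattle"` or `"yak"`.
#' @param rna_class one of `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"circRNA"`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `group_of`, `species`, `rna_class`.
#' @examples
#' m <- matrix(runif(12, 1, 100), 4, 3,
#'             dimnames = list(paste0("t", 1:4), paste0("A:", 1:3)))
#' em <- expression_matrix(m, species = "cattle", rna_class = "mRNA")
#' em$rna_class
#' @export
expression_matrix <- function(values, group_of = NULL, species = "cattle",
                              rna_class = c("mRNA", "lncRNA", "miRNA", "circRNA")) {
  rna_class <- match.arg(rna_class)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) > 0)
      stop("'values' must have row names (transcript ids)")
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values)))
    stop("'values' must have column names (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  if (is.null(group_of)) {
    group_of <- sub(":.*$", "", colnames(values))
    names(group_of) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(group_of))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  group_of <- group_of[colnames(values)]
  structure(
    list(values = values, group_of = group_of,
         species = species, rna_class = rna_class),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s %s: %d transcripts x %d samples (groups: %s)\n",
              x$species, x$rna_class, nrow(x$values), ncol(x$values),
              paste(unique(x$group_of), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Samples belonging to a group
#'
#' @param x an `expression_matrix`.
#' @param group a group label.
#' @return character vector of sample ids in that group.
#' @keywords internal
group_samples <- function(x, group) {
  ids <- names(x$group_of)[x$group_of == group]
  if (!length(ids))
    stop("unknown group label: '", group, "' (available: ",
         paste(unique(x$group_of), collapse = ", "), ")")
  ids
}

#' Write / read an expression matrix as TSV
#'
#' The on-disk dialect is a plain TSV with a `transcript_id` first column and
#' one column per sample, sample ids of the form `group:replicate` so that
#' group membership round-trips through the header alone.
#'
#' @param x an `expression_matrix`.
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(transcript_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("failed to write expression TSV at '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param species,rna_class metadata restored on read (not stored in the TSV).
#' @export
read_expression_tsv <- function(path, species = "cattle", rna_class = "mRNA") {
  if (!file.exists(path)) stop("expression TSV not found: '", path, "'")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, species = species, rna_class = rna_class)
}

#' Log2-transformed expression values
#'
#' @param x an `expression_matrix`.
#' @param pseudocount added before taking log2 (default 1).
#' @return numeric matrix of `log2(TPM + pseudocount)`.
#' @export
log2_values <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"), pseudocount > 0)
  log2(x$values + pseudocount)
}
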