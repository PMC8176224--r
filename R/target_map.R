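#' miRNA-target interaction map
#'
#' Predicted miRNA to target relations, target classes included so that
#' mRNA, lncRNA and circRNA targets can be distinguished downstream.
#'
#' @param edges data.frame with columns `mirna_id, target_id, target_class`
#'   (`target_class` one of `"mRNA"`, `"lncRNA"`, `"circRNA"`).
#' @return the validated data.frame, classed `target_map`.
#' @export
target_map <- function(edges) {
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(edges)))
    stop("target map needs columns: ", paste(need, collapse = ", "))
  if (!all(edges$target_class %in% c("mRNA", "lncRNA", "circRNA")))
    stop("target_class must be mRNA, lncRNA or circRNA")
  if (any(edges$mirna_id == edges$target_id))
    stop("self-targeting edges are not allowed")
  edges <- unique(edges[, need])
  rownames(edges) <- NULL
  class(edges) <- c("target_map", "data.frame")
  edges
}

#' @rdname target_map
#' @param path TSV `mirna_id<TAB>target_id<TAB>target_class` with header.
#' @export
read_target_tsv <- function(path) {
  if (!file.exists(path)) stop("target map not found: '", path, "'")
  target_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname target_map
#' @param map a `target_map`.
#' @export
write_target_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Regulator miRNA sets per target
#'
#' @param map a [target_map].
#' @return named list: target id -> character vector of regulator miRNA ids.
#' @keywords internal
regulators_of <- function(map) {
  split(map$mirna_id, map$target_id)
}
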