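#' Read / write GMT term maps
#'
#' GMT: one term per line, `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' On read, descriptions are kept in the `descriptions` attribute; on
#' write, the term name doubles as the description unless a named
#' character vector is supplied.
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors (term ->
#'   gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stop("malformed GMT lines (need term, description, >=1 gene): ",
         paste(which(bad), collapse = ", "))
  terms <- stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                           vapply(parts, `[`, "", 1))
  attr(terms, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2), names(terms))
  terms
}

#' @rdname read_gmt
#' @param terms named list of character vectors.
#' @param descriptions optional named character vector of descriptions.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(terms), names(terms))
  lines <- vapply(names(terms), function(t)
    paste(c(t, descriptions[[t]], terms[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Fisher over-representation analysis
#'
#' One-sided (enrichment) Fisher exact test of a study gene set against
#' each term of a term map, on the 2x2 table (k, n - k; K - k,
#' B - n - K + k) where k is the study-term overlap, K the term size, n the
#' study size and B the background size. Term gene sets are intersected
#' with the background before testing. The one-sided Fisher p-value is the
#' hypergeometric upper tail, computed by the same kernel as the miRNA
#' sponge test ([hyper_upper_tail()]). Selection is at raw p < `p_max`,
#' with BH-adjusted values reported alongside.
#'
#' @param study character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background character vector of background gene ids.
#' @param terms named list of character vectors (term -> gene ids), e.g.
#'   from [read_gmt()].
#' @param p_max significance threshold on the raw p-value (default 0.05).
#' @return data.frame `term_id, description, k, K, n, B, p, fdr,
#'   significant`, sorted by p then term id.
#' @export
fisher_enrichment <- function(study, background, terms, p_max = 0.05) {
  study <- unique(study)
  background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders))
    stop("study genes missing from the background: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) sprintf(" (and %d more)",
                                            length(offenders) - 5))
  descriptions <- attr(terms, "descriptions")
  B <- length(background)
  n <- length(study)
  rows <- lapply(names(terms), function(t) {
    genes <- intersect(terms[[t]], background)
    K <- length(genes)
    k <- length(intersect(study, genes))
    p <- if (K == 0) 1 else hyper_upper_tail(k, U = B, M = K, N = n)
    data.frame(term_id = t,
               description = if (!is.null(descriptions)) descriptions[[t]]
                             else t,
               k = k, K = K, n = n, B = B, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out$significant <- out$p < p_max
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname fisher_enrichment
#' @param enrichment a [fisher_enrichment()] result.
#' @param path output TSV path.
#' @export
write_enrichment_tsv <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
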