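#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.005 -> 0.01), matching how
#' percentages are conventionally printed in transcript-detection tables,
#' rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Transcript detection summary
#'
#' Summarises how many reference isoforms were detected in a group:
#' `known_pct` is `100 * known / reference`, rounded half-up to two
#' decimals, and `all_count = known + novel` is enforced.
#'
#' @param known number of known (reference-matching) isoforms detected.
#' @param novel number of novel isoforms detected.
#' @param reference total reference isoforms; must be >= known and > 0.
#' @param group optional group label carried into the result.
#' @return a list of class `detection_summary` with fields `group`,
#'   `known_count`, `novel_count`, `all_count`, `reference_count`,
#'   `known_pct`.
#' @examples
#' detection_summary(18891, 8331, 28881)$known_pct  # 65.41
#' @export
detection_summary <- function(known, novel, reference, group = NA_character_) {
  if (reference == 0) stop("reference isoform count must be > 0")
  stopifnot(known >= 0, novel >= 0, reference >= known)
  structure(
    list(group = group, known_count = known, novel_count = novel,
         all_count = known + novel, reference_count = reference,
         known_pct = round_half_up(100 * known / reference, 2)),
    class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf("%s: %d known (%.2f%% of %d reference) + %d novel = %d detected\n",
              if (is.na(x$group)) "group" else x$group, x$known_count,
              x$known_pct, x$reference_count, x$novel_count, x$all_count))
  invisible(x)
}

#' Novel-to-known expression ratio
#'
#' The mean expression of novel transcripts as a percentage of the mean
#' expression of known transcripts, rounded half-up to the nearest integer
#' percent.
#'
#' @param novel_mean mean expression of novel transcripts.
#' @param known_mean mean expression of known transcripts; must be > 0.
#' @return integer percentage.
#' @examples
#' expression_ratio(2.93, 10.37)  # 28
#' @export
expression_ratio <- function(novel_mean, known_mean) {
  if (known_mean <= 0) stop("known_mean must be > 0")
  as.integer(round_half_up(100 * novel_mean / known_mean))
}

#' Compact pipeline report
#'
#' Assembles a deterministic plain-text report from whichever stage
#' outputs are supplied: detection summaries, per-comparison direction
#' tallies, co-differential Venn counts, network node/edge counts by
#' class, and significant enrichment terms. With `dir` set, the report and
#' TSV companions are also written to disk.
#'
#' @param detection list of [detection_summary()] objects.
#' @param de_tables named list of `de_table`s (names label the comparison).
#' @param codesets named list of [co_differential()] results.
#' @param network a `cerna_network`.
#' @param enrichment a [fisher_enrichment()] table.
#' @param dir optional output directory for `report.txt` and TSVs.
#' @return character vector of report lines, invisibly; printed when
#'   interactive output is expected via `cat(report, sep = "\n")`.
#' @export
run_report <- function(detection = NULL, de_tables = NULL, codesets = NULL,
                       network = NULL, enrichment = NULL, dir = NULL) {
  if (is.null(detection) && is.null(de_tables) && is.null(codesets) &&
      is.null(network) && is.null(enrichment))
    stop("at least one stage output is required")
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("== pipeline report ==")
  if (!is.null(detection)) {
    add("-- detection --")
    for (d in detection)
      add("%s\tknown %d (%.2f%% of %d)\tnovel %d\tall %d",
          if (is.na(d$group)) "group" else d$group, d$known_count,
          d$known_pct, d$reference_count, d$novel_count, d$all_count)
  }
  if (!is.null(de_tables)) {
    add("-- differential expression --")
    for (nm in names(de_tables)) {
      t <- direction_tally(de_tables[[nm]])
      add("%s\ttotal %d\tup %d\tdown %d", nm, t[["n_total"]], t[["n_up"]],
          t[["n_down"]])
    }
  }
  if (!is.null(codesets)) {
    add("-- co-differential --")
    for (nm in names(codesets)) {
      cs <- codesets[[nm]]
      t <- direction_tally(cs)
      add("%s\tco-DE %d\tup %d\tdown %d\tconflicts %d\tvenn %d/%d/%d",
          nm, length(cs$ids), t[["n_up"]], t[["n_down"]],
          length(cs$conflicts), cs$venn[["only_1"]], cs$venn[["shared"]],
          cs$venn[["only_2"]])
    }
  }
  if (!is.null(network)) {
    add("-- ceRNA network --")
    add("nodes %d\tedges %d\tceRNA pairs %d\tmiRNA-target edges %d",
        nrow(network$nodes), nrow(network$edges),
        sum(network$edges$kind == "cerna_pair"),
        sum(network$edges$kind == "mirna_target"))
    if (nrow(network$nodes))
      for (cls in sort(unique(network$nodes$class)))
        add("nodes[%s] %d", cls, sum(network$nodes$class == cls))
  }
  if (!is.null(enrichment)) {
    add("-- enrichment --")
    sig <- enrichment[enrichment$significant, , drop = FALSE]
    add("significant terms %d of %d", nrow(sig), nrow(enrichment))
    for (i in seq_len(min(5, nrow(sig))))
      add("%s\tk=%d K=%d p=%.3g", sig$term_id[i], sig$k[i], sig$K[i],
          sig$p[i])
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeLines(lines, file.path(dir, "report.txt"))
    if (!is.null(de_tables))
      for (nm in names(de_tables))
        write_de_tsv(de_tables[[nm]], file.path(dir, sprintf("de_%s.tsv", nm)))
    if (!is.null(network)) {
      write_sif(network, file.path(dir, "network.sif"))
      write_node_attributes(network, file.path(dir, "network_nodes.tsv"))
      write_sponge_tsv(network, file.path(dir, "sponge_tests.tsv"))
    }
    if (!is.null(enrichment))
      write_enrichment_tsv(enrichment, file.path(dir, "enrichment.tsv"))
  }
  invisible(lines)
}
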