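#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage end to end: simulate a two-species bundle with
#' planted truth, call differential expression per RNA class in the two
#' comparisons (low-altitude reference vs. high-altitude cattle on the
#' cattle matrices; low-altitude reference vs. yak on the yak matrices,
#' projected onto cattle ids through the ortholog map), intersect into
#' co-differential sets, classify lncRNA-gene associations, retain
#' negatively co-expressed miRNA-target pairs, build the ceRNA network
#' with the sponge test, run enrichment of the co-differential mRNAs, and
#' assemble the report.
#'
#' The simulation seed fully determines the run: annotation uses
#' `config$seed` and expression `config$seed + 1`; all later stages are
#' deterministic functions of the generated data.
#'
#' @param config a [sim_config].
#' @param de_conf a [de_config].
#' @param lnc_conf a [lnc_assoc_config].
#' @param cerna_conf a [cerna_config].
#' @param outdir optional directory: the fixture, stage outputs, report
#'   and an echo of `config` (`config.R`, reloadable with [dget()]) are
#'   written there.
#' @return a list of class `pipeline_result` with elements `sim`,
#'   `de` (per class, per comparison), `codesets`, `lnc` (candidates and
#'   associations), `pairs` (retained miRNA-target pairs), `network`,
#'   `enrichment`, `report`, and `recovery` (triplet precision/recall and
#'   co-DE recall against the planted truth).
#' @export
run_pipeline <- function(config = sim_config(), de_conf = de_config(),
                         lnc_conf = lnc_assoc_config(),
                         cerna_conf = cerna_config(), outdir = NULL) {
  sim <- generate_expression(config)
  groups <- config$groups
  ref <- groups[1]

  de <- list(); codesets <- list()
  for (cls in names(sim$bundle$cattle)) {
    de_cattle <- call_de(sim$bundle$cattle[[cls]], ref, groups[2], de_conf)
    de_yak <- call_de(sim$bundle$yak[[cls]], ref, groups[3], de_conf)
    de_proj <- project_to_cattle(de_yak, sim$ortholog)
    de[[cls]] <- list(cattle = de_cattle, yak = de_yak, projected = de_proj)
    codesets[[cls]] <- co_differential(de_cattle, de_proj)
  }

  candidates <- filter_lncrna_candidates(sim$annotation, lnc_conf)
  assoc <- lnc_associations(sim$annotation, sim$bundle$cattle$lncRNA,
                            sim$bundle$cattle$mRNA, lnc_conf)

  de_ids <- lapply(codesets, function(cs) cs$ids)
  pairs <- negative_target_pairs(
    sim$targets, sim$bundle$cattle$miRNA,
    sim$bundle$cattle[c("mRNA", "lncRNA", "circRNA")],
    cerna_conf, de_ids = de_ids)
  network <- build_cerna_network(codesets, pairs, sim$bundle$cattle,
                                 sim$targets, cerna_conf)

  enrichment <- if (length(sim$terms)) fisher_enrichment(
    codesets$mRNA$ids, rownames(sim$bundle$cattle$mRNA$values), sim$terms)
    else NULL

  report <- run_report(
    de_tables = stats::setNames(
      lapply(names(de), function(cls) de[[cls]]$cattle),
      paste0(names(de), "_", ref, "-vs-", groups[2])),
    codesets = codesets, network = network, enrichment = enrichment,
    dir = if (is.null(outdir)) NULL else file.path(outdir, "report"))

  recovery <- c(
    score_triplet_recovery(network, sim$truth),
    codiff_recall = score_codiff_recall(codesets, sim$truth))

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_fixture(sim, file.path(outdir, "fixture"))
    dput(config, file.path(outdir, "config.R"))
  }
  structure(list(sim = sim, de = de, codesets = codesets,
                 lnc = list(candidates = candidates, associations = assoc),
                 pairs = pairs, network = network, enrichment = enrichment,
                 report = report, recovery = recovery),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(x$report, sep = "\n")
  cat(sprintf("triplet precision %.2f recall %.2f | co-DE recall %.2f\n",
              x$recovery[["precision"]], x$recovery[["recall"]],
              x$recovery[["codiff_recall"]]))
  invisible(x)
}

#' Score recovered ceRNA pairs against the planted truth
#'
#' Compares the network's accepted ceRNA pair edges with the planted
#' triplet partner pairs (unordered). When nothing was planted and nothing
#' recovered, both scores are 1.
#'
#' @param network a `cerna_network`.
#' @param truth a `truth_set`.
#' @return named numeric vector `c(precision, recall, n_recovered,
#'   n_planted)`.
#' @export
score_triplet_recovery <- function(network, truth) {
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ce <- network$edges[network$edges$kind == "cerna_pair", , drop = FALSE]
  recovered <- unique(pair_key(ce$source, ce$target))
  planted <- unique(pair_key(truth$triplets$a_id, truth$triplets$b_id))
  tp <- length(intersect(recovered, planted))
  c(precision = if (length(recovered)) tp / length(recovered)
      else as.numeric(length(planted) == 0),
    recall = if (length(planted)) tp / length(planted) else 1,
    n_recovered = length(recovered), n_planted = length(planted))
}

#' Recall of planted co-differential transcripts
#'
#' Fraction of planted differential transcripts (which are planted in both
#' comparisons) recovered in the co-differential sets of their class.
#'
#' @param codesets named list of [co_differential()] results per class.
#' @param truth a `truth_set`.
#' @return a single recall value (1 when nothing was planted).
#' @export
score_codiff_recall <- function(codesets, truth) {
  calls <- truth$de_calls
  if (!nrow(calls)) return(1)
  hit <- mapply(function(id, cls) id %in% codesets[[cls]]$ids,
                calls$transcript_id, calls$rna_class)
  mean(hit)
}
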