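#' Differential-expression configuration
#'
#' Encodes the class-specific significance criteria used throughout the
#' pipeline: mRNA and lncRNA are called significant at BH FDR < `fdr_max`
#' together with |log2FC| >= `log2fc_min`, while miRNA and circRNA use the
#' raw p-value (< `p_max`) with the same fold-change gate.
#'
#' @param log2fc_min minimum absolute log2 fold change (inclusive; default 1).
#' @param fdr_max FDR threshold for FDR-based classes (default 0.05).
#' @param p_max raw p-value threshold for raw-p classes (default 0.05).
#' @param pseudocount TPM pseudocount used for fold changes and the log2
#'   transform feeding the test (default 1).
#' @param variance_floor lower bound applied to each group's sample variance
#'   so that zero-variance groups still yield defined p-values (default 1e-8).
#' @param criterion_of_class named character vector mapping RNA class to
#'   `"fdr"` or `"p"`.
#' @return a list of class `de_config`.
#' @export
de_config <- function(log2fc_min = 1, fdr_max = 0.05, p_max = 0.05,
                      pseudocount = 1, variance_floor = 1e-8,
                      criterion_of_class = c(mRNA = "fdr", lncRNA = "fdr",
                                             miRNA = "p", circRNA = "p")) {
  stopifnot(log2fc_min > 0, fdr_max > 0, fdr_max <= 1, p_max > 0, p_max <= 1,
            pseudocount > 0, variance_floor > 0)
  if (!all(criterion_of_class %in% c("fdr", "p")))
    stop("criterion_of_class values must be 'fdr' or 'p'")
  structure(list(log2fc_min = log2fc_min, fdr_max = fdr_max, p_max = p_max,
                 pseudocount = pseudocount, variance_floor = variance_floor,
                 criterion_of_class = criterion_of_class),
            class = "de_config")
}

#' Per-transcript log2 fold change between two groups
#'
#' Computes `log2((mean_b + pseudocount) / (mean_a + pseudocount))` on the
#' TPM scale, group b relative to group a. The pseudocount keeps the ratio
#' finite for transcripts absent from one group.
#'
#' @param x an [expression_matrix].
#' @param group_a,group_b group labels; `group_a` is the reference.
#' @param pseudocount added to each group mean (default 1).
#' @return named numeric vector of log2 fold changes, one per transcript.
#' @examples
#' m <- matrix(c(0, 0, 0, 3, 3, 3), 1,
#'             dimnames = list("t1", c("A:1", "A:2", "A:3", "B:1", "B:2", "B:3")))
#' em <- expression_matrix(m, rna_class = "mRNA")
#' log2_fold_change(em, "A", "B")  # log2(4/1) = 2
#' @export
log2_fold_change <- function(x, group_a, group_b, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"), pseudocount > 0)
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  ma <- rowMeans(x$values[, sa, drop = FALSE])
  mb <- rowMeans(x$values[, sb, drop = FALSE])
  log2((mb + pseudocount) / (ma + pseudocount))
}

#' Welch two-sample test on log2 expression
#'
#' Row-wise two-sided Welch (unequal variance) t-test on
#' `log2(TPM + pseudocount)`. Each group's variance is floored at
#' `variance_floor`, so all-constant groups still produce a defined p-value;
#' identical samples in both groups give p = 1.
#'
#' This is the stand-in significance engine of the pipeline; it is isolated
#' here so that a count-based model can be swapped in without touching the
#' thresholding logic downstream.
#'
#' @inheritParams log2_fold_change
#' @param variance_floor lower bound on each group's variance.
#' @return named numeric vector of p-values in (0, 1].
#' @export
de_test <- function(x, group_a, group_b, pseudocount = 1,
                    variance_floor = 1e-8) {
  stopifnot(inherits(x, "expression_matrix"))
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  if (length(sa) < 2) stop("group '", group_a, "' has fewer than 2 samples")
  if (length(sb) < 2) stop("group '", group_b, "' has fewer than 2 samples")
  la <- log2(x$values[, sa, drop = FALSE] + pseudocount)
  lb <- log2(x$values[, sb, drop = FALSE] + pseudocount)
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- pmax(apply(la, 1, stats::var), variance_floor)
  vb <- pmax(apply(lb, 1, stats::var), variance_floor)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] with input validation. Adjusted values are the
#' step-up quantities `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1 and
#' returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed transcripts
#'
#' Computes per-transcript fold changes and Welch p-values between two
#' groups, BH-adjusts the p-values within the tested matrix, and applies the
#' class-appropriate significance criterion from `config`
#' (FDR for mRNA/lncRNA, raw p for miRNA/circRNA by default). The
#' fold-change gate `|log2FC| >= log2fc_min` is inclusive at the boundary.
#'
#' @inheritParams log2_fold_change
#' @param config a [de_config].
#' @return a `data.frame` of class `de_table`, sorted by transcript id, with
#'   columns `transcript_id, mean_a, mean_b, log2fc, p, fdr, direction,
#'   significant` and attributes `comparison` (c(group_a, group_b)) and
#'   `rna_class`. `direction` is `"up"` when significant with log2fc > 0,
#'   `"down"` when significant with log2fc < 0, else `"none"`.
#' @export
call_de <- function(x, group_a, group_b, config = de_config()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(config, "de_config"))
  crit <- config$criterion_of_class[x$rna_class]
  if (is.na(crit))
    stop("no significance criterion configured for RNA class '",
         x$rna_class, "'")
  sa <- group_samples(x, group_a)
  sb <- group_samples(x, group_b)
  lfc <- log2_fold_change(x, group_a, group_b, config$pseudocount)
  p <- de_test(x, group_a, group_b, config$pseudocount, config$variance_floor)
  fdr <- benjamini_hochberg(p)
  passes <- abs(lfc) >= config$log2fc_min &
    (if (crit == "fdr") fdr < config$fdr_max else p < config$p_max)
  direction <- ifelse(passes, ifelse(lfc > 0, "up", "down"), "none")
  out <- data.frame(
    transcript_id = rownames(x$values),
    mean_a = rowMeans(x$values[, sa, drop = FALSE]),
    mean_b = rowMeans(x$values[, sb, drop = FALSE]),
    log2fc = lfc, p = p, fdr = fdr,
    direction = direction, significant = passes,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparison") <- c(group_a, group_b)
  attr(out, "rna_class") <- x$rna_class
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write / read a DE table as TSV
#'
#' @param de a `de_table` from [call_de()] or [project_to_cattle()].
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  if (!file.exists(path)) stop("DE table not found: '", path, "'")
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(de) <- c("de_table", "data.frame")
  de
}
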