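#' Genomic annotation of genes and lncRNAs
#'
#' A flat table of features on 1-based inclusive coordinates (GTF
#' convention). `length` is the spliced transcript length (sum of exon
#' widths), which may be smaller than the genomic span.
#'
#' @param features data.frame with columns `id, chrom, start, end, strand,
#'   kind, exon_count, length`; `kind` is `"gene"` or `"lncRNA"`, strand
#'   `"+"` or `"-"`.
#' @return the validated data.frame, classed `genomic_annotation`.
#' @export
genomic_annotation <- function(features) {
  need <- c("id", "chrom", "start", "end", "strand", "kind",
            "exon_count", "length")
  if (!all(need %in% names(features)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(features$id)) stop("duplicate feature ids")
  if (any(features$start > features$end)) stop("start > end in annotation")
  if (any(features$exon_count < 1)) stop("exon_count must be >= 1")
  if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(features$kind %in% c("gene", "lncRNA")))
    stop("kind must be 'gene' or 'lncRNA'")
  span <- features$end - features$start + 1
  if (any(features$length > span))
    stop("spliced length exceeds genomic span for: ",
         paste(features$id[features$length > span], collapse = ", "))
  rownames(features) <- NULL
  class(features) <- c("genomic_annotation", "data.frame")
  features
}

as_granges <- function(annotation, ignore_strand = FALSE,
                       chrom_levels = sort(unique(annotation$chrom))) {
  GenomicRanges::GRanges(
    seqnames = factor(annotation$chrom, levels = chrom_levels),
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = if (ignore_strand) "*" else annotation$strand
  )
}

#' Write / read annotation as GTF
#'
#' Each feature is emitted as a `transcript` row plus `exon` rows whose
#' widths sum to the spliced length, with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes (`protein_coding` for genes, `lncRNA` for
#' lncRNAs). Reading reverses the process: the span and strand come from the
#' transcript row, the exon count and spliced length from the exon rows.
#'
#' @param annotation a [genomic_annotation].
#' @param path GTF file path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genomic_annotation"))
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    f <- annotation[i, ]
    k <- f$exon_count
    widths <- rep(f$length %/% k, k)
    widths[k] <- widths[k] + f$length %% k
    slack <- (f$end - f$start + 1) - f$length
    gaps <- if (k > 1) rep(slack %/% (k - 1), k - 1) else integer(0)
    starts <- f$start + c(0, cumsum(widths[-k] + gaps))
    data.frame(
      chrom = f$chrom,
      start = c(f$start, starts),
      end = c(f$end, starts + widths - 1),
      strand = f$strand,
      type = c("transcript", rep("exon", k)),
      gene_id = f$id, transcript_id = f$id,
      gene_biotype = if (f$kind == "gene") "protein_coding" else "lncRNA",
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = df$type, gene_id = df$gene_id,
    transcript_id = df$transcript_id, gene_biotype = df$gene_biotype
  )
  tryCatch(rtracklayer::export(gr, path, format = "gtf"),
           error = function(e) stop("failed to write GTF at '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: '", path, "'")
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  ex <- gr[gr$type == "exon"]
  exon_count <- table(ex$transcript_id)
  spliced <- tapply(GenomicRanges::width(ex), ex$transcript_id, sum)
  ids <- tx$transcript_id
  genomic_annotation(data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start = GenomicRanges::start(tx),
    end = GenomicRanges::end(tx),
    strand = as.character(GenomicRanges::strand(tx)),
    kind = ifelse(tx$gene_biotype == "protein_coding", "gene", "lncRNA"),
    exon_count = as.integer(exon_count[ids]),
    length = as.integer(spliced[ids]),
    stringsAsFactors = FALSE
  ))
}

#' lncRNA association configuration
#'
#' @param cis_window maximum gap, in bp, between a lncRNA and a gene for a
#'   cis call (default 10,000; inclusive at exactly the window).
#' @param min_length candidate filter: spliced length must exceed this
#'   (default 200 nt, strict).
#' @param min_exons candidate filter: exon count must exceed this
#'   (default 2, strict).
#' @param trans_pcc_min Pearson correlation a lncRNA-mRNA pair must exceed
#'   (strictly) to be called trans-associated (default 0.9).
#' @return a list of class `lnc_assoc_config`.
#' @export
lnc_assoc_config <- function(cis_window = 10000, min_length = 200,
                             min_exons = 2, trans_pcc_min = 0.9) {
  stopifnot(cis_window > 0, min_length >= 0, min_exons >= 0,
            trans_pcc_min > 0, trans_pcc_min <= 1)
  structure(list(cis_window = cis_window, min_length = min_length,
                 min_exons = min_exons, trans_pcc_min = trans_pcc_min),
            class = "lnc_assoc_config")
}

#' Filter lncRNA candidates by length and exon count
#'
#' Keeps lncRNA features longer than `min_length` nucleotides with more than
#' `min_exons` exons; both comparisons are strict.
#'
#' @param annotation a [genomic_annotation].
#' @param config a [lnc_assoc_config].
#' @return character vector of retained lncRNA ids.
#' @export
filter_lncrna_candidates <- function(annotation, config = lnc_assoc_config()) {
  keep <- annotation$kind == "lncRNA" &
    annotation$length > config$min_length &
    annotation$exon_count > config$min_exons
  annotation$id[keep]
}

#' Classify cis lncRNA-gene associations
#'
#' A lncRNA is cis-associated with a gene when the two intervals lie on the
#' same chromosome, do not overlap, and the gap between them (bases strictly
#' between the intervals) is at most `cis_window`; the rule is strand
#' agnostic and inclusive at exactly the window.
#'
#' @inheritParams filter_lncrna_candidates
#' @return data.frame `lncrna_id, gene_id, relation ("cis"), evidence`
#'   (gap distance in bp).
#' @export
classify_cis <- function(annotation, config = lnc_assoc_config()) {
  lnc <- annotation[annotation$kind == "lncRNA", , drop = FALSE]
  gene <- annotation[annotation$kind == "gene", , drop = FALSE]
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      relation = character(0), evidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(lnc) || !nrow(gene)) return(empty)
  lev <- sort(unique(annotation$chrom))
  grl <- as_granges(lnc, ignore_strand = TRUE, chrom_levels = lev)
  grg <- as_granges(gene, ignore_strand = TRUE, chrom_levels = lev)
  hits <- GenomicRanges::findOverlaps(grl, grg, maxgap = config$cis_window)
  if (!length(hits)) return(empty)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  # gap = bases strictly between the intervals; < 0 means they overlap
  gap <- pmax(lnc$start[i], gene$start[j]) - pmin(lnc$end[i], gene$end[j]) - 1
  keep <- gap >= 0 & gap <= config$cis_window
  out <- data.frame(lncrna_id = lnc$id[i][keep], gene_id = gene$id[j][keep],
                    relation = rep("cis", sum(keep)),
                    evidence = as.numeric(gap[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Classify antisense lncRNA-gene associations
#'
#' A lncRNA is an antisense candidate for a gene when the two features
#' overlap by at least one base on the same chromosome but opposite strands;
#' the evidence is the overlap length in bp (inclusive coordinates).
#' Same-strand overlaps are recorded in the `sense_overlaps` attribute of
#' the result and excluded from the associations.
#'
#' @param annotation a [genomic_annotation].
#' @return data.frame `lncrna_id, gene_id, relation ("antisense"), evidence`
#'   with attribute `sense_overlaps` (same-strand overlapping pairs).
#' @export
classify_antisense <- function(annotation) {
  lnc <- annotation[annotation$kind == "lncRNA", , drop = FALSE]
  gene <- annotation[annotation$kind == "gene", , drop = FALSE]
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      relation = character(0), evidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(lnc) || !nrow(gene)) {
    attr(empty, "sense_overlaps") <- empty[, 1:2]
    return(empty)
  }
  lev <- sort(unique(annotation$chrom))
  grl <- as_granges(lnc, ignore_strand = TRUE, chrom_levels = lev)
  grg <- as_granges(gene, ignore_strand = TRUE, chrom_levels = lev)
  hits <- GenomicRanges::findOverlaps(grl, grg)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  ov <- pmin(lnc$end[i], gene$end[j]) - pmax(lnc$start[i], gene$start[j]) + 1
  opposite <- lnc$strand[i] != gene$strand[j]
  out <- data.frame(lncrna_id = lnc$id[i][opposite],
                    gene_id = gene$id[j][opposite],
                    relation = rep("antisense", sum(opposite)),
                    evidence = as.numeric(ov[opposite]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  sense <- data.frame(lncrna_id = lnc$id[i][!opposite],
                      gene_id = gene$id[j][!opposite],
                      stringsAsFactors = FALSE)
  attr(out, "sense_overlaps") <- sense
  out
}

#' Classify trans lncRNA-mRNA associations by co-expression
#'
#' A positional rule cannot reach genes far from the lncRNA, so trans
#' relations are called from expression alone: pairs whose Pearson
#' correlation of log2(TPM + 1) across the shared samples strictly exceeds
#' `trans_pcc_min` are trans candidates, after removing pairs already
#' explained positionally (cis or antisense).
#'
#' @param lnc_expr,mrna_expr [expression_matrix] objects over the same
#'   samples.
#' @param config a [lnc_assoc_config].
#' @param exclude optional data.frame with columns `lncrna_id, gene_id` of
#'   pairs to skip (typically the cis and antisense calls).
#' @return data.frame `lncrna_id, gene_id, relation ("trans"), evidence`
#'   (the Pearson correlation).
#' @export
classify_trans <- function(lnc_expr, mrna_expr, config = lnc_assoc_config(),
                           exclude = NULL) {
  if (!identical(colnames(lnc_expr$values), colnames(mrna_expr$values)))
    stop("lncRNA and mRNA matrices must share the same samples in order")
  lm <- t(log2_values(lnc_expr))
  mm <- t(log2_values(mrna_expr))
  r <- suppressWarnings(stats::cor(lm, mm))
  hits <- which(r > config$trans_pcc_min & !is.na(r), arr.ind = TRUE)
  out <- data.frame(lncrna_id = rownames(r)[hits[, 1]],
                    gene_id = colnames(r)[hits[, 2]],
                    relation = rep("trans", nrow(hits)),
                    evidence = r[hits],
                    stringsAsFactors = FALSE)
  if (!is.null(exclude) && nrow(out) && nrow(exclude)) {
    key <- paste(out$lncrna_id, out$gene_id)
    out <- out[!key %in% paste(exclude$lncrna_id, exclude$gene_id), ,
               drop = FALSE]
  }
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' All lncRNA-gene associations with precedence
#'
#' Runs the antisense, cis and trans classifiers and combines them under
#' the precedence antisense > cis > trans, so no pair carries two relations.
#'
#' @inheritParams classify_trans
#' @param annotation a [genomic_annotation].
#' @return data.frame `lncrna_id, gene_id, relation, evidence`.
#' @export
lnc_associations <- function(annotation, lnc_expr = NULL, mrna_expr = NULL,
                             config = lnc_assoc_config()) {
  anti <- classify_antisense(annotation)
  cis <- classify_cis(annotation, config)
  key <- function(d) paste(d$lncrna_id, d$gene_id)
  cis <- cis[!key(cis) %in% key(anti), , drop = FALSE]
  positional <- rbind(as.data.frame(anti), cis)
  if (is.null(lnc_expr) || is.null(mrna_expr)) {
    rownames(positional) <- NULL
    return(positional)
  }
  trans <- classify_trans(lnc_expr, mrna_expr, config, exclude = positional)
  out <- rbind(positional, trans)
  rownames(out) <- NULL
  out
}
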