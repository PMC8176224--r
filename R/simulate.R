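#' Simulation configuration
#'
#' Parameters of the synthetic two-species, four-class expression study.
#' The defaults mirror the cross-species heart design the pipeline targets:
#' three groups (low-altitude cattle reference, high-altitude cattle,
#' high-altitude yak analog) of three replicates each, planted fold changes
#' of |log2FC| = `de_log2fc`, miRNA-mediated repression strong enough to
#' produce SCC < -0.7 miRNA-target anticorrelation and PCC > 0.9
#' partner-partner co-expression, and one-to-many cattle-to-yak ortholog
#' multiplicity.
#'
#' @param seed integer; fully determines all outputs.
#' @param replicates_per_group samples per group (default 3).
#' @param n_mrna,n_lncrna,n_mirna,n_circrna transcripts per RNA class.
#' @param frac_de fraction of each class planted differentially expressed.
#' @param de_log2fc planted |log2 fold change| (default 2).
#' @param repression_beta per-miRNA log2 repression coefficient applied to
#'   ceRNA partners (default 1.5).
#' @param noise_sd log2-scale residual standard deviation per sample
#'   (default 0.25); must be positive.
#' @param divergence_sd log2-scale yak-cattle divergence noise (default 0.1).
#' @param n_triplets planted ceRNA triplets (default 8).
#' @param min_shared_mirnas shared miRNAs per planted triplet (default 3).
#' @param extra_regulators additional (non-shared) regulator miRNAs per
#'   triplet partner in the target map (default 2).
#' @param background_targets_per_mirna random decoy targets per miRNA
#'   (default 5).
#' @param ortholog_multiplicity_max maximum yak ids per cattle id
#'   (default 3).
#' @param chrom_length chromosome length in bp (default 2e7).
#' @param cis_frac,antisense_frac fractions of lncRNAs planted cis to /
#'   antisense-overlapping a gene; the remainder are distal.
#' @param cis_distance gap in bp between planted cis lncRNAs and their gene
#'   (default 2000).
#' @param base_log2_mean,base_log2_sd baseline log2 abundance distribution.
#' @param groups group labels; the first is the low-altitude reference, all
#'   others receive the altitude effect.
#' @param n_random_terms decoy gene sets in the generated GMT (default 10).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, replicates_per_group = 3,
                       n_mrna = 300, n_lncrna = 60, n_mirna = 60,
                       n_circrna = 60, frac_de = 0.15, de_log2fc = 2,
                       repression_beta = 1.5, noise_sd = 0.25,
                       divergence_sd = 0.1, n_triplets = 8,
                       min_shared_mirnas = 3, extra_regulators = 2,
                       background_targets_per_mirna = 5,
                       ortholog_multiplicity_max = 3, chrom_length = 2e7,
                       cis_frac = 0.3, antisense_frac = 0.2,
                       cis_distance = 2000, base_log2_mean = 5,
                       base_log2_sd = 1.5,
                       groups = c("LAC", "HAC", "LWQY"),
                       n_random_terms = 10) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  stopifnot(replicates_per_group >= 2, n_mrna >= 0, n_lncrna >= 0,
            n_mirna >= 0, n_circrna >= 0, frac_de >= 0, frac_de <= 1,
            de_log2fc > 0, repression_beta > 0, divergence_sd >= 0,
            n_triplets >= 0, min_shared_mirnas >= 1,
            ortholog_multiplicity_max >= 1, chrom_length > 0,
            length(groups) >= 2)
  if (n_triplets > 0 && round(frac_de * n_mrna) < n_triplets)
    stop("frac_de * n_mrna must cover the ", n_triplets,
         " planted triplet mRNA participants")
  if (n_triplets * min_shared_mirnas > n_mirna)
    stop("not enough miRNAs for ", n_triplets, " disjoint shared sets of ",
         min_shared_mirnas)
  if (n_lncrna > n_mrna)
    stop("placement requires n_lncrna <= n_mrna (one host gene per lncRNA)")
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic annotation
#'
#' Places `n_mrna` genes sequentially along one chromosome with wide
#' inter-gene gaps, then plants lncRNAs in three positional classes: a
#' fraction exactly `cis_distance` bp downstream of a gene (cis-positive
#' for the 10-kb rule), a fraction overlapping a gene on the opposite
#' strand (antisense-positive), and the remainder distal (> 10 kb from any
#' gene). Distal lncRNAs always pass the candidate filter (length > 200 nt,
#' > 2 exons), emulating bona-fide intergenic lncRNAs; cis and antisense
#' lncRNAs have variable lengths and exon counts.
#'
#' @param config a [sim_config].
#' @return a [genomic_annotation] with attribute `lnc_truth`: data.frame
#'   `id, label ("cis"/"antisense"/"distal"), gene_id` of planted labels.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_g <- config$n_mrna
    n_l <- config$n_lncrna
    widths <- sample(2000:6000, n_g, replace = TRUE)
    gaps <- sample(25000:35000, n_g, replace = TRUE)
    starts <- 10000 + cumsum(c(0, (widths + gaps)[-n_g]))
    ends <- starts + widths - 1
    if (n_g > 0 && ends[n_g] + 15000 > config$chrom_length)
      stop("infeasible placement: ", n_g, " genes need ",
           ends[n_g] + 15000, " bp but chrom_length is ", config$chrom_length)
    gene_strand <- sample(c("+", "-"), n_g, replace = TRUE)
    gene_exons <- sample(5:9, n_g, replace = TRUE)
    gene_len <- pmax(200, round(widths * stats::runif(n_g, 0.3, 0.6)))
    genes <- data.frame(
      id = sprintf("cg%04d", seq_len(n_g)), chrom = "chr1",
      start = starts, end = ends, strand = gene_strand, kind = "gene",
      exon_count = gene_exons, length = gene_len, stringsAsFactors = FALSE)

    if (n_l == 0) {
      ann <- genomic_annotation(genes)
      attr(ann, "lnc_truth") <- data.frame(id = character(0),
                                           label = character(0),
                                           gene_id = character(0),
                                           stringsAsFactors = FALSE)
      return(ann)
    }
    n_cis <- round(config$cis_frac * n_l)
    n_anti <- round(config$antisense_frac * n_l)
    n_dist <- n_l - n_cis - n_anti
    hosts <- sample.int(n_g, n_l)
    label <- rep(c("cis", "antisense", "distal"), c(n_cis, n_anti, n_dist))
    lstart <- integer(n_l); lwidth <- integer(n_l); lstrand <- character(n_l)
    lexon <- integer(n_l); llen <- integer(n_l)
    for (i in seq_len(n_l)) {
      h <- hosts[i]
      if (label[i] == "cis") {
        lwidth[i] <- sample(400:2500, 1)
        lstart[i] <- ends[h] + config$cis_distance + 1
        lstrand[i] <- sample(c("+", "-"), 1)
        lexon[i] <- sample(1:5, 1)
        llen[i] <- max(lexon[i], round(lwidth[i] * stats::runif(1, 0.5, 0.9)))
      } else if (label[i] == "antisense") {
        lwidth[i] <- min(widths[h] - 200, sample(400:2500, 1))
        lstart[i] <- starts[h] + 100
        lstrand[i] <- if (gene_strand[h] == "+") "-" else "+"
        lexon[i] <- sample(1:5, 1)
        llen[i] <- max(lexon[i], round(lwidth[i] * stats::runif(1, 0.5, 0.9)))
      } else {
        lwidth[i] <- sample(700:2500, 1)
        lstart[i] <- ends[h] + 10501
        lstrand[i] <- sample(c("+", "-"), 1)
        lexon[i] <- sample(3:5, 1)
        llen[i] <- max(500, round(lwidth[i] * stats::runif(1, 0.72, 0.9)))
      }
    }
    lnc <- data.frame(
      id = sprintf("clnc%04d", seq_len(n_l)), chrom = "chr1",
      start = lstart, end = lstart + lwidth - 1, strand = lstrand,
      kind = "lncRNA", exon_count = lexon, length = llen,
      stringsAsFactors = FALSE)
    ann <- genomic_annotation(rbind(genes, lnc))
    attr(ann, "lnc_truth") <- data.frame(
      id = lnc$id, label = label, gene_id = genes$id[hosts],
      stringsAsFactors = FALSE)
    ann
  })
}

#' Generate expression with planted signal and ground truth
#'
#' Generative model (all on the log2 scale, exported as TPM = 2^log2):
#' each transcript draws a baseline ~ Normal(`base_log2_mean`,
#' `base_log2_sd`); planted differential transcripts add a ±`de_log2fc`
#' shift in every non-reference ("altitude") group; each planted ceRNA
#' triplet picks `min_shared_mirnas` miRNAs shifted together in one
#' direction, and both partner transcripts receive
#' `-repression_beta * sum(miRNA log2 deviation)` so that partners co-vary
#' positively with each other and negatively with their miRNAs; residual
#' Normal(0, `noise_sd`) noise is added per transcript and sample. Yak
#' matrices are ortholog copies of the cattle values (1 to
#' `ortholog_multiplicity_max` yak ids per cattle id) plus
#' Normal(0, `divergence_sd`) divergence noise.
#'
#' Triplet partner A is an mRNA; partner B alternates between circRNA and
#' distal lncRNA across triplets. The target map contains the shared-miRNA
#' edges, `extra_regulators` decoy regulators per partner, and
#' `background_targets_per_mirna` random decoy edges per miRNA (sparing the
#' planted partners). The GMT term map contains one term holding the
#' planted differential mRNAs plus `n_random_terms` random decoy sets.
#'
#' @param config a [sim_config].
#' @param annotation a [generate_annotation()] result (or `NULL` to
#'   generate it from `config`).
#' @return list with elements `bundle` (class `expression_bundle`: per
#'   species, per class [expression_matrix] objects), `truth` (class
#'   `truth_set`), `ortholog` ([ortholog_map]), `targets` ([target_map]),
#'   `terms` (named list of gene sets), and `annotation`.
#' @export
generate_expression <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$noise_sd <= 0) stop("noise_sd must be positive")
  if (is.null(annotation)) annotation <- generate_annotation(config)
  lnc_truth <- attr(annotation, "lnc_truth")
  withr::with_seed(config$seed + 1L, {
    groups <- config$groups
    reps <- config$replicates_per_group
    samples <- as.vector(t(outer(groups, seq_len(reps), paste, sep = ":")))
    alt <- as.numeric(sub(":.*", "", samples) != groups[1])
    n_s <- length(samples)

    pick <- function(x, n) x[sample.int(length(x), n)]  # sample() scalar-safe
    ids <- list(
      mRNA = annotation$id[annotation$kind == "gene"],
      lncRNA = annotation$id[annotation$kind == "lncRNA"],
      miRNA = sprintf("cmir%04d", seq_len(config$n_mirna)),
      circRNA = sprintf("ccirc%04d", seq_len(config$n_circrna))
    )

    # --- choose planted DE ids and triplet membership ------------------
    n_tri <- config$n_triplets
    s_m <- config$min_shared_mirnas
    tri_mirnas <- if (n_tri > 0)
      split(pick(ids$miRNA, n_tri * s_m), rep(seq_len(n_tri), each = s_m))
      else list()
    b_class <- if (n_tri > 0)
      rep_len(c("circRNA", "lncRNA"), n_tri) else character(0)
    distal_lnc <- lnc_truth$id[lnc_truth$label == "distal"]
    n_b_lnc <- sum(b_class == "lncRNA")
    if (n_b_lnc > length(distal_lnc))
      stop("not enough distal lncRNAs for the planted lncRNA triplet partners")
    tri_a <- pick(ids$mRNA, n_tri)
    tri_b <- character(n_tri)
    tri_b[b_class == "lncRNA"] <- pick(distal_lnc, n_b_lnc)
    tri_b[b_class == "circRNA"] <- pick(ids$circRNA,
                                        sum(b_class == "circRNA"))
    # shared miRNAs are planted down-regulated at altitude, so partners rise:
    # the dominant direction pattern in cross-altitude heart comparisons
    tri_dir <- rep("down", n_tri)

    pick_de <- function(pool, n, exclude = character(0)) {
      avail <- setdiff(pool, exclude)
      avail[sample.int(length(avail), max(0, min(length(avail), n)))]
    }
    de_extra <- list(
      mRNA = pick_de(ids$mRNA, round(config$frac_de * config$n_mrna) - n_tri,
                     tri_a),
      lncRNA = pick_de(ids$lncRNA, round(config$frac_de * config$n_lncrna),
                       tri_b[b_class == "lncRNA"]),
      miRNA = pick_de(ids$miRNA,
                      round(config$frac_de * config$n_mirna) - n_tri * s_m,
                      unlist(tri_mirnas)),
      circRNA = pick_de(ids$circRNA, round(config$frac_de * config$n_circrna),
                        tri_b[b_class == "circRNA"])
    )

    # --- latent cattle log2 matrices -----------------------------------
    shift <- numeric(0)  # planted altitude shift (log2) per transcript id
    de_rows <- list()
    record <- function(id, cls, dir) {
      de_rows[[length(de_rows) + 1]] <<- data.frame(
        transcript_id = id, rna_class = cls, direction = dir,
        stringsAsFactors = FALSE)
    }
    for (cls in names(de_extra)) for (id in de_extra[[cls]]) {
      d <- sample(c("up", "down"), 1)
      shift[id] <- if (d == "up") config$de_log2fc else -config$de_log2fc
      record(id, cls, d)
    }
    for (k in seq_len(n_tri)) {
      mdir <- tri_dir[k]
      for (m in tri_mirnas[[k]]) {
        shift[m] <- if (mdir == "up") config$de_log2fc else -config$de_log2fc
        record(m, "miRNA", mdir)
      }
      pdir <- if (mdir == "down") "up" else "down"
      record(tri_a[k], "mRNA", pdir)
      record(tri_b[k], b_class[k], pdir)
    }

    base <- lapply(ids, function(v)
      stats::setNames(stats::rnorm(length(v), config$base_log2_mean,
                                   config$base_log2_sd), v))
    log2m <- lapply(names(ids), function(cls) {
      v <- ids[[cls]]
      m <- matrix(stats::rnorm(length(v) * n_s, 0, config$noise_sd),
                  length(v), n_s, dimnames = list(v, samples))
      m <- m + base[[cls]]
      sh <- shift[v]
      sh[is.na(sh)] <- 0
      m + outer(sh, alt)
    })
    names(log2m) <- names(ids)
    # triplet partners: repression-driven expression replaces the
    # independent row (partner = base - beta * sum of miRNA deviations)
    for (k in seq_len(n_tri)) {
      dev <- log2m$miRNA[tri_mirnas[[k]], , drop = FALSE] -
        base$miRNA[tri_mirnas[[k]]]
      rep_term <- -config$repression_beta * colSums(dev)
      for (spec in list(c("mRNA", tri_a[k]), c(b_class[k], tri_b[k]))) {
        cls <- spec[1]; id <- spec[2]
        log2m[[cls]][id, ] <- base[[cls]][id] + rep_term +
          stats::rnorm(n_s, 0, config$noise_sd)
      }
    }

    # --- ortholog map and yak matrices ---------------------------------
    all_ids <- unlist(ids, use.names = FALSE)
    mult <- sample.int(config$ortholog_multiplicity_max, length(all_ids),
                       replace = TRUE)
    names(mult) <- all_ids
    omap <- ortholog_map(stats::setNames(lapply(all_ids, function(id)
      sprintf("%s_y%d", sub("^c", "y", id), seq_len(mult[[id]]))), all_ids))

    bundle <- list(cattle = list(), yak = list())
    for (cls in names(ids)) {
      bundle$cattle[[cls]] <- expression_matrix(
        2^log2m[[cls]], species = "cattle", rna_class = cls)
      yids <- unlist(omap[ids[[cls]]], use.names = FALSE)
      src <- rep(ids[[cls]], lengths(omap[ids[[cls]]]))
      ym <- log2m[[cls]][src, , drop = FALSE] +
        matrix(stats::rnorm(length(yids) * n_s, 0, config$divergence_sd),
               length(yids), n_s)
      rownames(ym) <- yids
      bundle$yak[[cls]] <- expression_matrix(2^ym, species = "yak",
                                             rna_class = cls)
    }
    class(bundle) <- "expression_bundle"

    # --- target map ----------------------------------------------------
    edges <- list()
    partner_ids <- c(tri_a, tri_b)
    for (k in seq_len(n_tri)) {
      for (spec in list(c("mRNA", tri_a[k]), c(b_class[k], tri_b[k]))) {
        cls <- spec[1]; id <- spec[2]
        extra <- pick(setdiff(ids$miRNA, unlist(tri_mirnas)),
                      config$extra_regulators)
        edges[[length(edges) + 1]] <- data.frame(
          mirna_id = c(tri_mirnas[[k]], extra), target_id = id,
          target_class = cls, stringsAsFactors = FALSE)
      }
    }
    bg_pool <- list(mRNA = setdiff(ids$mRNA, partner_ids),
                    lncRNA = setdiff(ids$lncRNA, partner_ids),
                    circRNA = setdiff(ids$circRNA, partner_ids))
    bg_ids <- unlist(bg_pool, use.names = FALSE)
    bg_cls <- rep(names(bg_pool), lengths(bg_pool))
    for (m in ids$miRNA) {
      if (config$background_targets_per_mirna == 0 || !length(bg_ids)) break
      j <- sample(length(bg_ids),
                  min(config$background_targets_per_mirna, length(bg_ids)))
      edges[[length(edges) + 1]] <- data.frame(
        mirna_id = m, target_id = bg_ids[j], target_class = bg_cls[j],
        stringsAsFactors = FALSE)
    }
    targets <- target_map(if (length(edges)) do.call(rbind, edges) else
      data.frame(mirna_id = character(0), target_id = character(0),
                 target_class = character(0), stringsAsFactors = FALSE))

    # --- GMT terms built from truth ------------------------------------
    de_calls <- if (length(de_rows)) do.call(rbind, de_rows) else
      data.frame(transcript_id = character(0), rna_class = character(0),
                 direction = character(0), stringsAsFactors = FALSE)
    planted_mrna <- de_calls$transcript_id[de_calls$rna_class == "mRNA"]
    terms <- list()
    if (length(planted_mrna) >= 2)
      terms[["ALTITUDE_RESPONSE"]] <- sort(planted_mrna)
    for (k in seq_len(config$n_random_terms))
      terms[[sprintf("RANDOM_SET_%02d", k)]] <-
        sort(pick(ids$mRNA, min(20, length(ids$mRNA))))

    triplets <- data.frame(
      a_id = tri_a, b_id = tri_b, b_class = b_class,
      shared_mirnas = vapply(tri_mirnas, paste, "", collapse = ","),
      mirna_direction = tri_dir, stringsAsFactors = FALSE)
    trans_pairs <- triplets[triplets$b_class == "lncRNA",
                            c("b_id", "a_id"), drop = FALSE]
    names(trans_pairs) <- c("lncrna_id", "gene_id")
    truth <- structure(
      list(de_calls = de_calls, triplets = triplets,
           lnc_labels = lnc_truth, trans_pairs = trans_pairs,
           enriched_term = if (length(planted_mrna) >= 2)
             "ALTITUDE_RESPONSE" else NA_character_),
      class = "truth_set")

    list(bundle = bundle, truth = truth, ortholog = omap,
         targets = targets, terms = terms, annotation = annotation)
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d planted DE calls, %d planted triplets, %d trans pairs\n",
              nrow(x$de_calls), nrow(x$triplets), nrow(x$trans_pairs)))
  invisible(x)
}

#' @export
print.expression_bundle <- function(x, ...) {
  for (sp in names(x)) for (cls in names(x[[sp]])) print(x[[sp]][[cls]])
  invisible(x)
}
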