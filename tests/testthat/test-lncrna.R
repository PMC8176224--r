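toy_ann <- function(...) {
  rows <- list(...)
  genomic_annotation(do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1]], chrom = r[[2]], start = r[[3]], end = r[[4]],
               strand = r[[5]], kind = r[[6]],
               exon_count = if (length(r) > 6) r[[7]] else 1,
               length = if (length(r) > 7) r[[8]] else
                 (r[[4]] - r[[3]] + 1), stringsAsFactors = FALSE))))
}

test_that("candidate filter applies strict length and exon thresholds", {
  ann <- toy_ann(
    list("l1", "chr1", 1, 400, "+", "lncRNA", 3, 200),   # length boundary
    list("l2", "chr1", 1, 600, "+", "lncRNA", 2, 500),   # exon boundary
    list("l3", "chr1", 1, 600, "+", "lncRNA", 3, 500),   # passes both
    list("g1", "chr1", 1000, 2000, "+", "gene", 5, 800)  # genes never counted
  )
  expect_equal(filter_lncrna_candidates(ann), "l3")
})

test_that("cis classification uses the inclusive 10-kb gap rule", {
  ann <- toy_ann(
    list("g1", "chr1", 50000, 60000, "+", "gene"),
    list("lA", "chr1", 62001, 63000, "+", "lncRNA"),  # gap 2000
    list("lB", "chr1", 70001, 70500, "-", "lncRNA"),  # gap exactly 10000
    list("lC", "chr1", 70002, 70500, "+", "lncRNA"),  # gap 10001
    list("lD", "chr2", 60500, 61000, "+", "lncRNA")   # other chromosome
  )
  cis <- classify_cis(ann)
  expect_setequal(cis$lncrna_id, c("lA", "lB"))
  expect_equal(cis$evidence[cis$lncrna_id == "lA"], 2000)
  expect_equal(cis$evidence[cis$lncrna_id == "lB"], 10000)
})

test_that("antisense requires opposite-strand overlap, with inclusive lengths", {
  ann <- toy_ann(
    list("g1", "chr1", 100, 200, "+", "gene"),
    list("l1", "chr1", 150, 250, "-", "lncRNA"),  # overlap 51 bp
    list("l2", "chr1", 150, 250, "+", "lncRNA"),  # same strand
    list("l3", "chr1", 201, 300, "-", "lncRNA")   # adjacent, no overlap
  )
  anti <- classify_antisense(ann)
  expect_equal(anti$lncrna_id, "l1")
  expect_equal(anti$evidence, 51)
  expect_equal(attr(anti, "sense_overlaps")$lncrna_id, "l2")
  # the adjacent lncRNA is cis instead
  expect_true("l3" %in% classify_cis(ann)$lncrna_id)
})

test_that("positional calls match a brute-force interval oracle", {
  set.seed(42)
  for (rep in 1:300) {
    n_g <- sample(1:4, 1); n_l <- sample(1:4, 1)
    mk <- function(n, kind, prefix) {
      s <- sample(1:5000, n)
      data.frame(id = paste0(prefix, seq_len(n)),
                 chrom = sample(c("c1", "c2"), n, replace = TRUE),
                 start = s, end = s + sample(1:3000, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 kind = kind, exon_count = 1, length = 1,
                 stringsAsFactors = FALSE)
    }
    g <- mk(n_g, "gene", "g"); l <- mk(n_l, "lncRNA", "l")
    ann <- genomic_annotation(rbind(g, l))
    cis <- classify_cis(ann, lnc_assoc_config(cis_window = 1000))
    anti <- classify_antisense(ann)
    for (i in seq_len(n_l)) for (j in seq_len(n_g)) {
      same_chrom <- l$chrom[i] == g$chrom[j]
      ov <- min(l$end[i], g$end[j]) - max(l$start[i], g$start[j]) + 1
      gap <- max(l$start[i], g$start[j]) - min(l$end[i], g$end[j]) - 1
      in_cis <- any(cis$lncrna_id == l$id[i] & cis$gene_id == g$id[j])
      in_anti <- any(anti$lncrna_id == l$id[i] & anti$gene_id == g$id[j])
      expect_identical(in_cis, same_chrom && ov <= 0 && gap <= 1000)
      expect_identical(in_anti,
                       same_chrom && ov >= 1 && l$strand[i] != g$strand[j])
      if (in_anti)
        expect_equal(anti$evidence[anti$lncrna_id == l$id[i] &
                                     anti$gene_id == g$id[j]], ov)
    }
  }
})

test_that("classification is invariant to feature order", {
  set.seed(9)
  s <- sample(1:20000, 8)
  ann <- genomic_annotation(data.frame(
    id = paste0("f", 1:8), chrom = "c1", start = s, end = s + 2500,
    strand = rep(c("+", "-"), 4), kind = rep(c("gene", "lncRNA"), each = 4),
    exon_count = 1, length = 1, stringsAsFactors = FALSE))
  shuf <- genomic_annotation(ann[sample(8), ])
  norm <- function(d) { rownames(d) <- NULL; d }
  expect_equal(norm(classify_cis(ann)), norm(classify_cis(shuf)))
  expect_equal(norm(as.data.frame(classify_antisense(ann))),
               norm(as.data.frame(classify_antisense(shuf))))
})

test_that("trans calls use the strict PCC gate and honour exclusions", {
  set.seed(13)
  mrna <- matrix(2^rnorm(5 * 9, 5, 1), 5, 9,
                 dimnames = list(paste0("g", 1:5),
                                 paste(rep(c("LAC", "HAC", "LWQY"), each = 3),
                                       1:3, sep = ":")))
  lnc <- matrix(2^rnorm(3 * 9, 5, 1), 3, 9,
                dimnames = list(paste0("l", 1:3), colnames(mrna)))
  lnc[1, ] <- mrna[2, ]  # identical expression => r = 1
  tr <- classify_trans(make_em(lnc, "lncRNA"), make_em(mrna, "mRNA"))
  expect_true(any(tr$lncrna_id == "l1" & tr$gene_id == "g2"))
  expect_true(all(tr$evidence > 0.9))
  # excluded pairs are dropped
  tr2 <- classify_trans(make_em(lnc, "lncRNA"), make_em(mrna, "mRNA"),
                        exclude = data.frame(lncrna_id = "l1",
                                             gene_id = "g2"))
  expect_false(any(tr2$lncrna_id == "l1" & tr2$gene_id == "g2"))
  # sample mismatch is an explicit error
  expect_error(classify_trans(make_em(lnc[, 1:6], "lncRNA"),
                              make_em(mrna, "mRNA")), "samples")

  # independent noise rarely clears 0.9 with 9 samples
  fp <- 0
  for (s in 1:50) {
    set.seed(s)
    a <- matrix(2^rnorm(9, 5, 1), 1, 9,
                dimnames = list("l1", colnames(mrna)))
    b <- matrix(2^rnorm(9, 5, 1), 1, 9,
                dimnames = list("g1", colnames(mrna)))
    fp <- fp + nrow(classify_trans(make_em(a, "lncRNA"), make_em(b, "mRNA")))
  }
  expect_lt(fp, 3)
})

test_that("no lncRNA-gene pair carries two relations", {
  res <- run_pipeline(quick_config(seed = 2))
  assoc <- res$lnc$associations
  expect_equal(anyDuplicated(paste(assoc$lncrna_id, assoc$gene_id)), 0)
})

test_that("annotations round-trip through GTF", {
  ann <- generate_annotation(quick_config(seed = 3))
  f <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, f)
  back <- read_annotation_gtf(f)
  a <- as.data.frame(ann)[order(ann$id), ]
  b <- as.data.frame(back)[order(back$id), ]
  attr(a, "lnc_truth") <- attr(b, "lnc_truth") <- NULL
  rownames(a) <- rownames(b) <- NULL
  b$exon_count <- as.numeric(b$exon_count)
  b$length <- as.numeric(b$length)
  a$exon_count <- as.numeric(a$exon_count)
  a$length <- as.numeric(a$length)
  expect_equal(b, a)
})
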