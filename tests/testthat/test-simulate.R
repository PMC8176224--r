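test_that("config validation rejects incoherent study designs", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_mrna = 50, frac_de = 0.02, n_triplets = 8),
               "triplet")
  expect_error(sim_config(n_mirna = 5, n_triplets = 8, min_shared_mirnas = 3),
               "miRNAs")
  expect_error(generate_annotation(sim_config(chrom_length = 1e5,
                                              n_mrna = 50, n_lncrna = 10)),
               "infeasible")
})

test_that("annotation generation is deterministic and honours empty classes", {
  cfg <- quick_config(seed = 5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  only_genes <- generate_annotation(sim_config(n_lncrna = 0, n_mrna = 80,
                                               n_triplets = 0))
  expect_true(all(only_genes$kind == "gene"))
  expect_equal(nrow(attr(only_genes, "lnc_truth")), 0)
})

test_that("planted positional labels are recovered by the classifiers", {
  cfg <- quick_config(seed = 6)
  ann <- generate_annotation(cfg)
  truth <- attr(ann, "lnc_truth")
  cis <- classify_cis(ann)
  expect_setequal(unique(cis$lncrna_id), truth$id[truth$label == "cis"])
  expect_true(all(cis$evidence == cfg$cis_distance))
  # each planted cis lncRNA pairs with its planted host gene
  key <- paste(cis$lncrna_id, cis$gene_id)
  planted <- with(truth[truth$label == "cis", ], paste(id, gene_id))
  expect_setequal(key, planted)
  anti <- classify_antisense(ann)
  expect_setequal(unique(anti$lncrna_id),
                  truth$id[truth$label == "antisense"])
  # distal lncRNAs always pass the candidate filter
  cand <- filter_lncrna_candidates(ann)
  expect_true(all(truth$id[truth$label == "distal"] %in% cand))
})

test_that("expression generation is seed-deterministic", {
  cfg <- quick_config(seed = 7)
  s1 <- generate_expression(cfg)
  s2 <- generate_expression(cfg)
  expect_identical(s1$bundle$cattle$mRNA$values, s2$bundle$cattle$mRNA$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_expression(quick_config(seed = 8))
  expect_false(identical(s1$bundle$cattle$mRNA$values,
                         s3$bundle$cattle$mRNA$values))
})

test_that("a null configuration plants no fold changes", {
  sim <- generate_expression(null_config(seed = 9, noise_sd = 0.01))
  for (cls in names(sim$bundle$cattle)) {
    em <- sim$bundle$cattle[[cls]]
    for (grp in c("HAC", "LWQY"))
      expect_lt(max(abs(log2_fold_change(em, "LAC", grp))), 1)
  }
  expect_equal(nrow(sim$truth$de_calls), 0)
  expect_equal(nrow(sim$truth$triplets), 0)
})

test_that("planted triplets show the advertised correlation structure", {
  scc_ok <- 0; scc_n <- 0; pcc_ok <- 0; pcc_n <- 0
  for (seed in 1:30) {
    sim <- generate_expression(sim_config(seed = seed))
    expr <- sim$bundle$cattle
    for (k in seq_len(nrow(sim$truth$triplets))) {
      tr <- sim$truth$triplets[k, ]
      a <- log2(expr$mRNA$values[tr$a_id, ] + 1)
      b <- log2(expr[[tr$b_class]]$values[tr$b_id, ] + 1)
      pcc_n <- pcc_n + 1
      pcc_ok <- pcc_ok + (pearson_r(a, b) > 0.9)
      for (m in strsplit(tr$shared_mirnas, ",")[[1]]) {
        mv <- expr$miRNA$values[m, ]
        for (part in list(expr$mRNA$values[tr$a_id, ],
                          expr[[tr$b_class]]$values[tr$b_id, ])) {
          scc_n <- scc_n + 1
          scc_ok <- scc_ok + (spearman_rho(mv, part) < -0.7)
        }
      }
    }
  }
  expect_gte(pcc_ok / pcc_n, 0.8)
  expect_gte(scc_ok / scc_n, 0.8)
})

test_that("ortholog multiplicity and yak copies behave as configured", {
  cfg <- quick_config(seed = 10, ortholog_multiplicity_max = 3)
  sim <- generate_expression(cfg)
  mult <- lengths(sim$ortholog)
  expect_true(all(mult >= 1 & mult <= 3))
  expect_gt(max(mult), 1)  # one-to-many actually occurs
  # yak rows are divergence-noised copies of their cattle source
  cid <- names(sim$ortholog)[1]
  yid <- sim$ortholog[[cid]][1]
  cls <- if (grepl("^cg", cid)) "mRNA" else "other"
  skip_if(cls != "mRNA")
  dif <- log2(sim$bundle$yak$mRNA$values[yid, ]) -
    log2(sim$bundle$cattle$mRNA$values[cid, ])
  expect_lt(max(abs(dif)), 6 * cfg$divergence_sd)
})

test_that("fixtures round-trip losslessly through the readers", {
  cfg <- quick_config(seed = 11)
  sim <- generate_expression(cfg)
  dir <- file.path(tempdir(), "fix11")
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  for (sp in c("cattle", "yak")) for (cls in names(sim$bundle[[sp]])) {
    expect_equal(back$bundle[[sp]][[cls]]$values,
                 sim$bundle[[sp]][[cls]]$values, tolerance = 1e-12)
    expect_equal(nrow(back$bundle[[sp]][[cls]]$values),
                 nrow(sim$bundle[[sp]][[cls]]$values))
  }
  expect_equal(nrow(back$truth$triplets), cfg$n_triplets)
  expect_setequal(back$truth$de_calls$transcript_id,
                  sim$truth$de_calls$transcript_id)
  norm_map <- function(m) lapply(unclass(m)[sort(names(m))], sort)
  expect_equal(norm_map(back$ortholog), norm_map(sim$ortholog))
  expect_setequal(names(back$terms), names(sim$terms))
  expect_error(read_fixture(file.path(tempdir(), "no-such-dir")),
               "not found")
})
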