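# Deterministic toy: 10 miRNAs in the universe, two of which repress both
# partners (anti-monotone by construction), partners perfectly co-expressed.
toy_cerna <- function() {
  samples <- paste(rep(c("LAC", "HAC", "LWQY"), each = 3), 1:3, sep = ":")
  up <- 2^(1:9); down <- 2^(9:1)
  flat <- rep(32, 9)
  mirna <- rbind(m01 = down, m02 = down * 2,
                 matrix(rep(flat, 8), 8, byrow = TRUE,
                        dimnames = list(sprintf("m%02d", 3:10), NULL)))
  colnames(mirna) <- samples
  mrna <- rbind(a1 = up, a2 = flat + (1:9) %% 2)
  colnames(mrna) <- samples
  circ <- rbind(b1 = up * 3)
  colnames(circ) <- samples
  expr <- list(mRNA = make_em(mrna, "mRNA"),
               lncRNA = make_em(mrna[0, , drop = FALSE], "lncRNA"),
               circRNA = make_em(circ, "circRNA"),
               miRNA = make_em(mirna, "miRNA"))
  targets <- target_map(data.frame(
    mirna_id = c("m01", "m02", "m01", "m02", "m03"),
    target_id = c("a1", "a1", "b1", "b1", "a2"),
    target_class = c("mRNA", "mRNA", "circRNA", "circRNA", "mRNA"),
    stringsAsFactors = FALSE))
  codets <- list(mRNA = c(a1 = "up"), lncRNA = character(0),
                 circRNA = c(b1 = "up"), miRNA = c(m01 = "down", m02 = "down"))
  list(expr = expr, targets = targets, codets = codets)
}

test_that("negative target pairs apply the strict Spearman gate and DE filter", {
  toy <- toy_cerna()
  pairs <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                                 toy$expr[c("mRNA", "lncRNA", "circRNA")],
                                 cerna_config())
  # the four anti-monotone edges are retained with SCC = -1
  expect_setequal(paste(pairs$mirna_id, pairs$target_id),
                  c("m01 a1", "m02 a1", "m01 b1", "m02 b1"))
  expect_true(all(pairs$scc == -1))
  # the flat-profile pair (m03, a2) is not retained (SCC undefined or weak)
  expect_false("a2" %in% pairs$target_id)

  # the gate is strictly below scc_max: at scc_max = -1 nothing survives
  none <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                                toy$expr[c("mRNA", "lncRNA", "circRNA")],
                                cerna_config(scc_max = -1))
  expect_equal(nrow(none), 0)

  # DE restriction drops edges whose miRNA or target is not differential
  de_ids <- list(mRNA = "a1", lncRNA = character(0), circRNA = character(0),
                 miRNA = "m01")
  der <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                               toy$expr[c("mRNA", "lncRNA", "circRNA")],
                               cerna_config(), de_ids = de_ids)
  expect_equal(paste(der$mirna_id, der$target_id), "m01 a1")
})

test_that("network assembly enforces all four ceRNA conditions", {
  toy <- toy_cerna()
  pairs <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                                 toy$expr[c("mRNA", "lncRNA", "circRNA")],
                                 cerna_config())
  net <- build_cerna_network(toy$codets, pairs, toy$expr, toy$targets,
                             cerna_config())
  ce <- net$edges[net$edges$kind == "cerna_pair", ]
  expect_equal(nrow(ce), 1)
  expect_setequal(c(ce$source, ce$target), c("a1", "b1"))
  # sponge arithmetic: both regulator sets are {m01, m02} in a universe of 10
  row <- net$sponge[net$sponge$accepted, ]
  expect_equal(row$x, 2); expect_equal(row$M, 2); expect_equal(row$N, 2)
  expect_equal(row$U, 10)
  expect_equal(row$p, 1 / choose(10, 2))
  # supporting miRNA-target edges are present and sign-consistent
  mt <- net$edges[net$edges$kind == "mirna_target", ]
  expect_setequal(paste(mt$source, mt$target),
                  c("m01 a1", "m02 a1", "m01 b1", "m02 b1"))
  expect_equal(net$sign_consistency, 1)

  # single-criterion knockouts empty the network
  expect_equal(nrow(build_cerna_network(
    toy$codets, pairs, toy$expr, toy$targets,
    cerna_config(pcc_min = 0.99999))$edges), 0)
  expect_equal(nrow(build_cerna_network(
    toy$codets, pairs, toy$expr, toy$targets,
    cerna_config(sponge_p_max = 0.01))$edges), 0)
  no_code <- toy$codets; no_code$mRNA <- character(0)
  expect_equal(nrow(build_cerna_network(
    no_code, pairs, toy$expr, toy$targets, cerna_config())$nodes), 0)

  # a universe smaller than a regulator set is an explicit error
  expect_error(build_cerna_network(toy$codets, pairs, toy$expr, toy$targets,
                                   cerna_config(universe_size = 1)),
               "universe")
})

test_that("subnetwork extraction matches a breadth-first oracle", {
  toy <- toy_cerna()
  pairs <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                                 toy$expr[c("mRNA", "lncRNA", "circRNA")],
                                 cerna_config())
  net <- build_cerna_network(toy$codets, pairs, toy$expr, toy$targets,
                             cerna_config())
  sub1 <- extract_subnetwork(net, "m01", radius = 1)
  expect_setequal(sub1$nodes$id, c("m01", "a1", "b1"))
  expect_warning(empty <- extract_subnetwork(net, "nope"), "seed")
  expect_equal(nrow(empty$nodes), 0)

  # BFS oracle on a pipeline-scale network
  res <- run_pipeline(quick_config(seed = 4))
  net2 <- res$network
  skip_if(nrow(net2$nodes) == 0)
  seed_id <- net2$nodes$id[net2$nodes$class == "mRNA"][1]
  for (radius in 1:2) {
    frontier <- seed_id
    reach <- seed_id
    for (step in seq_len(radius)) {
      nb <- with(net2$edges, c(target[source %in% frontier],
                               source[target %in% frontier]))
      frontier <- setdiff(nb, reach)
      reach <- union(reach, frontier)
    }
    sub <- extract_subnetwork(net2, seed_id, radius = radius)
    expect_setequal(sub$nodes$id, reach)
  }
})

test_that("network exports are well-formed", {
  toy <- toy_cerna()
  pairs <- negative_target_pairs(toy$targets, toy$expr$miRNA,
                                 toy$expr[c("mRNA", "lncRNA", "circRNA")],
                                 cerna_config())
  net <- build_cerna_network(toy$codets, pairs, toy$expr, toy$targets,
                             cerna_config())
  sif <- tempfile(); nod <- tempfile()
  write_sif(net, sif); write_node_attributes(net, nod)
  expect_length(readLines(sif), nrow(net$edges))
  expect_equal(nrow(read.delim(nod)), nrow(net$nodes))
})

test_that("target map validation rejects self-targets and bad classes", {
  expect_error(target_map(data.frame(mirna_id = "m1", target_id = "m1",
                                     target_class = "mRNA")), "self")
  expect_error(target_map(data.frame(mirna_id = "m1", target_id = "g1",
                                     target_class = "gene")), "target_class")
  f <- tempfile()
  tm <- target_map(data.frame(mirna_id = c("m1", "m2"),
                              target_id = c("g1", "g1"),
                              target_class = "mRNA"))
  write_target_tsv(tm, f)
  expect_equal(as.data.frame(read_target_tsv(f)), as.data.frame(tm))
})
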