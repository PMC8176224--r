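#' ceRNA inference configuration
#'
#' Thresholds for ceRNA network construction: miRNA-target pairs are
#' retained when their Spearman correlation is strictly below `scc_max`;
#' candidate partner pairs need Pearson correlation strictly above
#' `pcc_min` and a sponge-test p-value below `sponge_p_max`.
#'
#' @param scc_max Spearman gate for miRNA-target anticorrelation
#'   (default -0.7; must lie in \[-1, 0)).
#' @param pcc_min Pearson gate for partner co-expression (default 0.9).
#' @param sponge_p_max sponge-test selection threshold (default 0.05).
#' @param universe_size total number of miRNAs identified (the sponge-test
#'   U); `NULL` (default) uses the number of miRNAs in the expression
#'   universe at build time.
#' @param allowed_pairs list of length-2 character vectors naming the
#'   partner class combinations considered; the default assembles
#'   lncRNA-miRNA-mRNA and circRNA-miRNA-mRNA triplets only.
#' @param adjust_sponge_p apply BH adjustment to sponge p-values before
#'   thresholding (default `FALSE`: selection at raw p, as is conventional
#'   for this test).
#' @return a list of class `cerna_config`.
#' @export
cerna_config <- function(scc_max = -0.7, pcc_min = 0.9, sponge_p_max = 0.05,
                         universe_size = NULL,
                         allowed_pairs = list(c("mRNA", "lncRNA"),
                                              c("mRNA", "circRNA")),
                         adjust_sponge_p = FALSE) {
  stopifnot(scc_max >= -1, scc_max < 0, pcc_min > 0, pcc_min <= 1,
            sponge_p_max > 0, sponge_p_max <= 1)
  if (!is.null(universe_size)) stopifnot(universe_size >= 1)
  structure(list(scc_max = scc_max, pcc_min = pcc_min,
                 sponge_p_max = sponge_p_max, universe_size = universe_size,
                 allowed_pairs = allowed_pairs,
                 adjust_sponge_p = adjust_sponge_p),
            class = "cerna_config")
}

#' Negatively co-expressed miRNA-target pairs
#'
#' Evaluates the Spearman correlation between each predicted miRNA-target
#' pair over the shared samples (on the TPM scale; ranks are invariant to
#' monotone transforms) and keeps pairs strictly below `scc_max`. When
#' `de_ids` is supplied, both the miRNA and the target must appear in the
#' corresponding differential sets: the network is built from
#' differentially expressed RNAs only. Targets or miRNAs absent from the
#' expression matrices are skipped and counted in the `skipped` attribute.
#'
#' @param targets a [target_map].
#' @param mirna_expr [expression_matrix] of miRNAs.
#' @param target_expr named list of [expression_matrix] objects keyed by
#'   RNA class (`mRNA`, `lncRNA`, `circRNA`), same samples as `mirna_expr`.
#' @param config a [cerna_config].
#' @param de_ids optional named list of character vectors of differential
#'   ids per class (including `miRNA`) used to restrict the pairs.
#' @return data.frame `mirna_id, target_id, target_class, scc` of retained
#'   pairs, with attribute `skipped` (ids not found in expression).
#' @export
negative_target_pairs <- function(targets, mirna_expr, target_expr,
                                  config = cerna_config(), de_ids = NULL) {
  stopifnot(inherits(targets, "target_map"))
  edges <- as.data.frame(targets)
  if (!is.null(de_ids)) {
    keep <- edges$mirna_id %in% de_ids$miRNA
    for (cls in unique(edges$target_class)) {
      sel <- edges$target_class == cls
      keep[sel] <- keep[sel] & edges$target_id[sel] %in% de_ids[[cls]]
    }
    edges <- edges[keep, , drop = FALSE]
  }
  skipped <- character(0)
  scc <- rep(NA_real_, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    m <- edges$mirna_id[k]
    t <- edges$target_id[k]
    te <- target_expr[[edges$target_class[k]]]
    if (is.null(te) || !m %in% rownames(mirna_expr$values) ||
        !t %in% rownames(te$values)) {
      skipped <- c(skipped, if (!m %in% rownames(mirna_expr$values)) m else t)
      next
    }
    shared <- intersect(colnames(mirna_expr$values), colnames(te$values))
    scc[k] <- spearman_rho(mirna_expr$values[m, shared], te$values[t, shared])
  }
  edges$scc <- scc
  out <- edges[!is.na(scc) & scc < config$scc_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  attr(out, "skipped") <- unique(skipped)
  out
}

as_direction_map <- function(x) {
  if (inherits(x, "co_de_set")) return(x$direction_of)
  if (inherits(x, "de_table"))
    return(stats::setNames(x$direction[x$significant],
                           x$transcript_id[x$significant]))
  if (is.character(x) && (length(x) == 0 || !is.null(names(x)))) return(x)
  stop("expected a co_de_set, de_table, or named direction vector")
}

#' Build a ceRNA network
#'
#' Assembles the network from co-differential sets per RNA class, retained
#' negatively co-expressed miRNA-target pairs, and expression matrices. A
#' candidate partner pair (a, b) from an allowed class combination enters
#' the network iff:
#' \enumerate{
#'   \item both partners are co-differential,
#'   \item their Pearson correlation of log2(TPM + 1) strictly exceeds
#'     `pcc_min`,
#'   \item they are retained targets of at least one common miRNA, and
#'   \item the sponge test on their full regulator sets scores below
#'     `sponge_p_max`.
#' }
#' All supporting miRNA-target edges (shared, retained miRNAs of accepted
#' pairs) are included. The fraction of miRNA-target edges whose directions
#' oppose (up-regulated miRNA with down-regulated target or vice versa) is
#' reported as `sign_consistency`.
#'
#' @param codets named list per RNA class (`mRNA`, `lncRNA`, `circRNA`,
#'   `miRNA`) of [co_differential()] results, `de_table`s, or named
#'   direction vectors.
#' @param retained_pairs output of [negative_target_pairs()].
#' @param expr named list of [expression_matrix] objects per class, used
#'   for partner Pearson correlations.
#' @param targets the full [target_map], source of the regulator sets
#'   (M, N, x) for the sponge test.
#' @param config a [cerna_config].
#' @return an object of class `cerna_network`: list with `nodes`
#'   (`id, class, direction`), `edges` (`source, target, kind, weight`),
#'   `sponge` (all tested pairs with `gene_a, gene_b, x, M, N, U, p, pcc,
#'   accepted`), `sign_consistency`, and the `config` used.
#' @export
build_cerna_network <- function(codets, retained_pairs, expr, targets,
                                config = cerna_config()) {
  stopifnot(inherits(config, "cerna_config"))
  dirs <- lapply(codets, as_direction_map)
  U <- config$universe_size
  if (is.null(U)) U <- nrow(expr$miRNA$values)
  reg <- regulators_of(targets)
  mirna_universe <- rownames(expr$miRNA$values)
  reg <- lapply(reg, function(m) intersect(m, mirna_universe))
  retained_of <- split(retained_pairs$mirna_id, retained_pairs$target_id)

  log2_of <- lapply(expr, function(e) log2_values(e))
  sponge_rows <- list()
  cerna_edges <- list()
  support <- list()
  for (combo in config$allowed_pairs) {
    a_ids <- intersect(dirs[[combo[1]]] |> names(), names(retained_of))
    b_ids <- intersect(dirs[[combo[2]]] |> names(), names(retained_of))
    a_ids <- intersect(a_ids, rownames(expr[[combo[1]]]$values))
    b_ids <- intersect(b_ids, rownames(expr[[combo[2]]]$values))
    for (a in a_ids) for (b in b_ids) {
      if (a == b) next
      shared_retained <- intersect(retained_of[[a]], retained_of[[b]])
      if (!length(shared_retained)) next
      M <- length(reg[[a]]); N <- length(reg[[b]])
      x <- length(intersect(reg[[a]], reg[[b]]))
      if (M > U || N > U)
        stop("sponge universe U = ", U, " smaller than a regulator set ",
             "(M = ", M, ", N = ", N, "); set universe_size explicitly")
      pcc <- pearson_r(log2_of[[combo[1]]][a, ], log2_of[[combo[2]]][b, ])
      p <- sponge_test(x, U, M, N)
      sponge_rows[[length(sponge_rows) + 1]] <- data.frame(
        gene_a = a, gene_b = b, class_a = combo[1], class_b = combo[2],
        x = x, M = M, N = N, U = U, p = p, pcc = pcc,
        stringsAsFactors = FALSE)
      support[[paste(a, b)]] <- shared_retained
    }
  }
  sponge <- if (length(sponge_rows)) do.call(rbind, sponge_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               class_a = character(0), class_b = character(0),
               x = integer(0), M = integer(0), N = integer(0), U = integer(0),
               p = numeric(0), pcc = numeric(0), stringsAsFactors = FALSE)
  p_sel <- if (config$adjust_sponge_p) benjamini_hochberg(sponge$p) else sponge$p
  sponge$accepted <- !is.na(sponge$pcc) & sponge$pcc > config$pcc_min &
    p_sel < config$sponge_p_max

  nodes <- list(); edges <- list()
  add_node <- function(id, class, direction)
    nodes[[id]] <<- data.frame(id = id, class = class, direction = direction,
                               stringsAsFactors = FALSE)
  acc <- sponge[sponge$accepted, , drop = FALSE]
  for (k in seq_len(nrow(acc))) {
    a <- acc$gene_a[k]; b <- acc$gene_b[k]
    add_node(a, acc$class_a[k], unname(dirs[[acc$class_a[k]]][a]))
    add_node(b, acc$class_b[k], unname(dirs[[acc$class_b[k]]][b]))
    edges[[length(edges) + 1]] <- data.frame(
      source = a, target = b, kind = "cerna_pair", weight = acc$p[k],
      stringsAsFactors = FALSE)
    for (m in support[[paste(a, b)]]) {
      add_node(m, "miRNA", unname(dirs$miRNA[m]))
      for (t in c(a, b)) {
        scc <- retained_pairs$scc[retained_pairs$mirna_id == m &
                                    retained_pairs$target_id == t][1]
        edges[[length(edges) + 1]] <- data.frame(
          source = m, target = t, kind = "mirna_target", weight = scc,
          stringsAsFactors = FALSE)
      }
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = character(0), class = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(0), target = character(0),
               kind = character(0), weight = numeric(0),
               stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$kind, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  mt <- edges[edges$kind == "mirna_target", , drop = FALSE]
  sign_ok <- if (nrow(mt)) {
    md <- nodes$direction[match(mt$source, nodes$id)]
    td <- nodes$direction[match(mt$target, nodes$id)]
    mean((md == "up" & td == "down") | (md == "down" & td == "up"))
  } else NA_real_
  structure(list(nodes = nodes, edges = edges, sponge = sponge,
                 sign_consistency = sign_ok, config = config),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("<cerna_network> %d nodes, %d edges (%d ceRNA pairs, %d miRNA-target)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$kind == "cerna_pair"),
              sum(x$edges$kind == "mirna_target")))
  if (nrow(x$nodes))
    print(table(class = x$nodes$class, direction = x$nodes$direction))
  invisible(x)
}

#' @export
summary.cerna_network <- function(object, ...) {
  list(
    n_nodes = nrow(object$nodes),
    n_edges = nrow(object$edges),
    n_cerna_pairs = sum(object$edges$kind == "cerna_pair"),
    n_mirna_target = sum(object$edges$kind == "mirna_target"),
    nodes_by_class = table(object$nodes$class),
    sign_consistency = object$sign_consistency,
    n_tested_pairs = nrow(object$sponge)
  )
}

cerna_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "kind", "weight")],
    directed = FALSE, vertices = network$nodes)
}

#' Extract a seed-centred subnetwork
#'
#' Induced subgraph of all nodes within `radius` edges of any seed node,
#' preserving node and edge attributes. Radius 2 reaches from a seed mRNA
#' through its miRNAs to the circRNAs and lncRNAs competing for them.
#'
#' @param network a `cerna_network`.
#' @param seed_ids character vector of node ids.
#' @param radius neighbourhood radius in edges (default 2).
#' @return a `cerna_network` restricted to the neighbourhood; empty (with a
#'   warning) when no seed is present in the network.
#' @export
extract_subnetwork <- function(network, seed_ids, radius = 2) {
  stopifnot(inherits(network, "cerna_network"), radius >= 1)
  present <- intersect(seed_ids, network$nodes$id)
  if (!length(present)) {
    warning("none of the seed ids are present in the network")
    out <- network
    out$nodes <- network$nodes[0, ]
    out$edges <- network$edges[0, ]
    return(out)
  }
  g <- cerna_igraph(network)
  keep <- unique(names(unlist(lapply(
    igraph::ego(g, order = radius, nodes = present),
    function(v) stats::setNames(seq_along(v), igraph::V(g)$name[v])))))
  out <- network
  out$nodes <- network$nodes[network$nodes$id %in% keep, , drop = FALSE]
  out$edges <- network$edges[network$edges$source %in% keep &
                               network$edges$target %in% keep, , drop = FALSE]
  rownames(out$nodes) <- rownames(out$edges) <- NULL
  out
}

#' Export a network for external viewers
#'
#' `write_sif` writes the edge list in SIF format
#' (`source<TAB>interaction<TAB>target`); `write_node_attributes` writes a
#' node attribute TSV (`id, class, direction`); `write_sponge_tsv` writes
#' the full sponge-test table.
#'
#' @param network a `cerna_network`.
#' @param path output file path.
#' @export
write_sif <- function(network, path) {
  df <- network$edges[, c("source", "kind", "target")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_node_attributes <- function(network, path) {
  utils::write.table(network$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_sponge_tsv <- function(network, path) {
  utils::write.table(network$sponge, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
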