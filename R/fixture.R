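#' Write a simulated fixture to disk
#'
#' Emits every artifact of a [generate_expression()] run in plain-text
#' formats: one expression TSV per species and RNA class
#' (`expr_<species>_<class>.tsv`), the annotation as GTF
#' (`annotation.gtf`), the ortholog and target maps as TSV, the term map as
#' GMT (`terms.gmt`), and the ground truth in a sectioned key-value text
#' file (`truth.txt`). The file set round-trips losslessly through
#' [read_fixture()] up to numeric text precision.
#'
#' @param sim a [generate_expression()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory '", dir, "'")
  for (sp in names(sim$bundle)) for (cls in names(sim$bundle[[sp]]))
    write_expression_tsv(sim$bundle[[sp]][[cls]],
                         file.path(dir, sprintf("expr_%s_%s.tsv", sp, cls)))
  write_annotation_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_ortholog_tsv(sim$ortholog, file.path(dir, "ortholog_map.tsv"))
  write_target_tsv(sim$targets, file.path(dir, "target_map.tsv"))
  write_gmt(sim$terms, file.path(dir, "terms.gmt"))
  write_truth(sim$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: '", dir, "'")
  bundle <- list()
  for (sp in c("cattle", "yak")) {
    bundle[[sp]] <- list()
    for (cls in c("mRNA", "lncRNA", "miRNA", "circRNA")) {
      f <- file.path(dir, sprintf("expr_%s_%s.tsv", sp, cls))
      if (file.exists(f))
        bundle[[sp]][[cls]] <- read_expression_tsv(f, species = sp,
                                                   rna_class = cls)
    }
  }
  class(bundle) <- "expression_bundle"
  list(bundle = bundle,
       annotation = read_annotation_gtf(file.path(dir, "annotation.gtf")),
       ortholog = read_ortholog_tsv(file.path(dir, "ortholog_map.tsv")),
       targets = read_target_tsv(file.path(dir, "target_map.tsv")),
       terms = read_gmt(file.path(dir, "terms.gmt")),
       truth = read_truth(file.path(dir, "truth.txt")))
}

#' Write / read the simulation ground truth
#'
#' Plain-text sectioned format: lines of `[section]` headers followed by
#' tab-separated rows with a header line per section. Sections:
#' `de_calls` (`transcript_id, rna_class, direction`), `triplets`
#' (`a_id, b_id, b_class, shared_mirnas` comma-joined, `mirna_direction`),
#' `lnc_labels` (`id, label, gene_id`), `trans_pairs`
#' (`lncrna_id, gene_id`), and `meta` (`key, value`).
#'
#' @param truth a `truth_set`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cernet truth v1", con)
  sect <- function(name, df) {
    writeLines(sprintf("[%s]", name), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sect("de_calls", truth$de_calls)
  sect("triplets", truth$triplets)
  sect("lnc_labels", truth$lnc_labels)
  sect("trans_pairs", truth$trans_pairs)
  sect("meta", data.frame(key = "enriched_term",
                          value = as.character(truth$enriched_term),
                          stringsAsFactors = FALSE))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: '", path, "'")
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  heads <- grep("^\\[.*\\]$", lines)
  sections <- list()
  for (i in seq_along(heads)) {
    name <- gsub("\\[|\\]", "", lines[heads[i]])
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    body <- lines[(heads[i] + 1):to]
    body <- body[nzchar(body)]
    sections[[name]] <- utils::read.delim(text = paste(body, collapse = "\n"),
                                          stringsAsFactors = FALSE,
                                          colClasses = "character")
  }
  meta <- sections$meta
  structure(
    list(de_calls = sections$de_calls, triplets = sections$triplets,
         lnc_labels = sections$lnc_labels, trans_pairs = sections$trans_pairs,
         enriched_term = meta$value[meta$key == "enriched_term"]),
    class = "truth_set")
}
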