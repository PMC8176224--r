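#' Ortholog map between cattle and yak identifiers
#'
#' One cattle id may correspond to one or more yak ids (many-to-one from the
#' yak side); a yak id may appear under at most one cattle id. The map is
#' stored as a named list: names are cattle ids, elements are non-empty
#' character vectors of yak ids.
#'
#' @param pairs named list, cattle id -> character vector of yak ids.
#' @return the validated map, classed `ortholog_map`.
#' @export
ortholog_map <- function(pairs) {
  if (!is.list(pairs) || is.null(names(pairs)) || any(names(pairs) == ""))
    stop("'pairs' must be a named list keyed by cattle id")
  if (any(lengths(pairs) == 0))
    stop("ortholog map has cattle ids with no yak ids")
  yak <- unlist(pairs, use.names = FALSE)
  if (anyDuplicated(yak))
    stop("yak ids mapped to more than one cattle id: ",
         paste(unique(yak[duplicated(yak)]), collapse = ", "))
  structure(pairs, class = "ortholog_map")
}

#' @rdname ortholog_map
#' @param path TSV file with two columns `cattle_id<TAB>yak_id`, one pair per
#'   line, with a header row.
#' @export
read_ortholog_tsv <- function(path) {
  if (!file.exists(path)) stop("ortholog map not found: '", path, "'")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ortholog_map(split(df$yak_id, df$cattle_id))
}

#' @rdname ortholog_map
#' @param map an `ortholog_map`.
#' @export
write_ortholog_tsv <- function(map, path) {
  df <- data.frame(cattle_id = rep(names(map), lengths(map)),
                   yak_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project a yak DE table onto cattle identifiers
#'
#' Aggregates yak transcripts mapped to the same cattle id: by default a
#' cattle id is significant as soon as any mapped yak transcript is
#' significant (`aggregate = "any"`; `"all"` requires unanimity of
#' significance). Its direction is the common direction of the significant
#' mapped transcripts; if significant transcripts disagree the id is flagged
#' `"conflict"`. Expression means are averaged over all mapped transcripts.
#' Yak ids absent from the map are dropped and counted in the `unmapped`
#' attribute of the result.
#'
#' @param yak_de a `de_table` keyed by yak transcript ids.
#' @param map an [ortholog_map].
#' @param aggregate `"any"` (default) or `"all"`.
#' @return a `de_table` keyed by cattle id, sorted by id, with attribute
#'   `unmapped` (count of yak ids not covered by the map).
#' @export
project_to_cattle <- function(yak_de, map, aggregate = c("any", "all")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(map, "ortholog_map"))
  cattle_of <- rep(names(map), lengths(map))
  names(cattle_of) <- unlist(map, use.names = FALSE)
  hit <- yak_de$transcript_id %in% names(cattle_of)
  unmapped <- sum(!hit)
  de <- yak_de[hit, , drop = FALSE]
  if (nrow(de) == 0) {
    out <- de
    out$transcript_id <- character(0)
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  grp <- cattle_of[de$transcript_id]
  agg_fun <- if (aggregate == "any") any else all
  rows <- lapply(split(seq_len(nrow(de)), grp), function(i) {
    sub <- de[i, , drop = FALSE]
    sig <- agg_fun(sub$significant) && any(sub$significant)
    dirs <- unique(sub$direction[sub$significant])
    direction <- if (!sig) "none"
      else if (length(dirs) == 1) dirs
      else "conflict"
    use <- if (any(sub$significant)) sub$significant else rep(TRUE, nrow(sub))
    data.frame(
      transcript_id = grp[i[1]],
      mean_a = mean(sub$mean_a), mean_b = mean(sub$mean_b),
      log2fc = mean(sub$log2fc[use]),
      p = min(sub$p), fdr = min(sub$fdr),
      direction = direction, significant = sig,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparison") <- attr(yak_de, "comparison")
  attr(out, "rna_class") <- attr(yak_de, "rna_class")
  attr(out, "unmapped") <- unmapped
  class(out) <- c("de_table", "data.frame")
  out
}

#' Intersect two DE tables into a co-differential set
#'
#' Ids significant in both comparisons form the co-differential set when
#' their directions agree; ids significant in both but with opposite (or
#' unresolved `"conflict"`) directions are excluded and reported in
#' `conflicts`. Venn counts are taken over significant ids only, before
#' conflict filtering, so `venn["shared"]` always equals
#' `length(ids) + length(conflicts)` when direction agreement is required.
#'
#' @param de_1,de_2 `de_table`s keyed on the same (cattle) id namespace.
#' @param require_direction_agreement if `FALSE`, jointly significant ids
#'   are all retained (direction taken from `de_1`) and `conflicts` is empty.
#' @return a list of class `co_de_set` with elements `ids`, `direction_of`
#'   (named character), `conflicts`, and `venn` (named counts `only_1`,
#'   `only_2`, `shared`).
#' @export
co_differential <- function(de_1, de_2, require_direction_agreement = TRUE) {
  sig1 <- de_1$transcript_id[de_1$significant]
  sig2 <- de_2$transcript_id[de_2$significant]
  if (length(sig1) && length(sig2) && !length(intersect(de_1$transcript_id,
                                                        de_2$transcript_id)))
    warning("no shared ids between the two DE tables; id namespaces may differ")
  shared <- intersect(sig1, sig2)
  d1 <- de_1$direction[match(shared, de_1$transcript_id)]
  d2 <- de_2$direction[match(shared, de_2$transcript_id)]
  agree <- d1 == d2 & d1 %in% c("up", "down")
  if (require_direction_agreement) {
    ids <- shared[agree]
    conflicts <- shared[!agree]
    direction_of <- stats::setNames(d1[agree], ids)
  } else {
    ids <- shared
    conflicts <- character(0)
    direction_of <- stats::setNames(ifelse(d1 %in% c("up", "down"), d1, d2),
                                    ids)
  }
  structure(
    list(ids = ids, direction_of = direction_of, conflicts = conflicts,
         venn = c(only_1 = length(setdiff(sig1, sig2)),
                  only_2 = length(setdiff(sig2, sig1)),
                  shared = length(shared))),
    class = "co_de_set"
  )
}

#' @export
print.co_de_set <- function(x, ...) {
  t <- direction_tally(x)
  cat(sprintf(
    "<co_de_set> %d co-differential ids (%d up, %d down), %d direction conflicts\n",
    length(x$ids), t[["n_up"]], t[["n_down"]], length(x$conflicts)))
  cat(sprintf("  Venn: only-1 %d | shared %d | only-2 %d\n",
              x$venn[["only_1"]], x$venn[["shared"]], x$venn[["only_2"]]))
  invisible(x)
}

#' Tally up/down directions
#'
#' Counts significant up- and down-regulated entries of a `de_table` or the
#' members of a `co_de_set`.
#'
#' @param x a `de_table` or `co_de_set`.
#' @return named integer vector `c(n_up, n_down, n_total)` with
#'   `n_total = n_up + n_down`.
#' @export
direction_tally <- function(x) {
  dirs <- if (inherits(x, "co_de_set")) unname(x$direction_of)
          else x$direction[x$significant]
  c(n_up = sum(dirs == "up"), n_down = sum(dirs == "down"),
    n_total = sum(dirs %in% c("up", "down")))
}
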