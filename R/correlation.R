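#' Spearman and Pearson correlation for expression vectors
#'
#' Thin, validating wrappers around [stats::cor()]. `spearman_rho` is the
#' Pearson correlation of average-ranked values (ties share the mean rank);
#' `pearson_r` is the ordinary product-moment coefficient. Either vector
#' being constant makes the coefficient undefined: the functions return
#' `NA_real_` and callers are expected to drop the pair.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @examples
#' spearman_rho(1:4, c(10, 7, 3, 1))  # -1
#' pearson_r(1:5, 2 * (1:5) + 3)      # 1
#' @export
spearman_rho <- function(x, y) {
  check_cor_input(x, y)
  if (constantish(x) || constantish(y)) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @export
pearson_r <- function(x, y) {
  check_cor_input(x, y)
  if (constantish(x) || constantish(y)) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

check_cor_input <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric vectors")
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  invisible(TRUE)
}

constantish <- function(x) max(x) == min(x)
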