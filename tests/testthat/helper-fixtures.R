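# Small deterministic fixtures shared across test files.

# expression_matrix from a plain matrix of TPM values
make_em <- function(values, rna_class = "mRNA", species = "cattle") {
  expression_matrix(values, species = species, rna_class = rna_class)
}

# two-group matrix with given per-group row means (TPM), zero noise
two_group_em <- function(means_a, means_b, n = 3, rna_class = "mRNA",
                         ids = sprintf("t%02d", seq_along(means_a))) {
  m <- cbind(matrix(rep(means_a, n), ncol = n),
             matrix(rep(means_b, n), ncol = n))
  dimnames(m) <- list(ids, c(paste0("A:", 1:n), paste0("B:", 1:n)))
  make_em(m, rna_class)
}

# a hand-built de_table row set
make_de_table <- function(ids, direction, significant = direction != "none",
                          log2fc = ifelse(direction == "up", 2,
                                          ifelse(direction == "down", -2, 0))) {
  n <- length(ids)
  df <- data.frame(transcript_id = ids, mean_a = rep(10, n),
                   mean_b = rep(10, n), log2fc = log2fc,
                   p = rep(0.01, n), fdr = rep(0.01, n),
                   direction = direction, significant = significant,
                   stringsAsFactors = FALSE)
  class(df) <- c("de_table", "data.frame")
  df
}

# small fast simulation configuration for pipeline-level tests
quick_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mrna = 120, n_lncrna = 30, n_mirna = 40,
             n_circrna = 30, n_triplets = 4, ...)
}

# null configuration: nothing planted
null_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mrna = 120, n_lncrna = 12, n_mirna = 12,
             n_circrna = 12, frac_de = 0, n_triplets = 0, ...)
}

# brute-force Spearman: rank with mean ties, then textbook Pearson
oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x, ties.method = "average"),
                 rank(y, ties.method = "average"))
}

# textbook product-moment formula, no cor()
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive hypergeometric upper tail: enumerate all C(U, N) draws
oracle_hyper_tail <- function(x, U, M, N) {
  draws <- utils::combn(U, N)
  hits <- colSums(draws <= M)  # elements 1..M are the marked ones
  sum(hits >= x) / ncol(draws)
}

# direct BH suffix-minimum evaluation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- sapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))))
  out <- numeric(m)
  out[o] <- q
  out
}
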