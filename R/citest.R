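#' G-squared conditional independence test for categorical variables
#'
#' Likelihood-ratio test of `x` independent of `y` given the variables in
#' `Z`: within each configuration of `Z`, `G2 = 2 * sum(O * log(O / E))`
#' over the `x` by `y` contingency table, summed across strata, referred to
#' a chi-square distribution. Nominal degrees of freedom are
#' `(|x| - 1) (|y| - 1) prod(|z|)`; rows and columns whose stratum marginal
#' is zero are dropped and the degrees of freedom reduced accordingly
#' (standard sparse-table correction, which keeps p-values conservative).
#' Zero-count cells contribute nothing to the statistic.
#'
#' @param x,y column names.
#' @param Z character vector of conditioning column names (may be empty).
#' @param data a [tabular_dataset()] of factors.
#' @param alpha significance level in (0, 1).
#' @return list with `statistic`, `degrees_of_freedom`, `p_value` and
#'   `independent` (`TRUE` iff `p_value > alpha`).
#' @export
ci_test_g2 <- function(x, y, Z = character(0), data, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (x %in% Z || y %in% Z) stop("conditioning set must not contain x or y")
  if (x == y) stop("x and y must differ")
  kx <- nlevels(data[[x]])
  ky <- nlevels(data[[y]])
  cx <- as.integer(data[[x]])
  cy <- as.integer(data[[y]])
  n <- nrow(data)
  if (length(Z) == 0) {
    cz <- rep.int(1L, n)
    nz <- 1L
  } else {
    cards <- vapply(Z, function(z) nlevels(data[[z]]), integer(1))
    nz <- prod(cards)
    cz <- rep.int(0L, n)
    mult <- 1L
    for (j in seq_along(Z)) {
      cz <- cz + (as.integer(data[[Z[j]]]) - 1L) * mult
      mult <- mult * cards[j]
    }
    cz <- cz + 1L
  }
  cell <- ((cz - 1L) * ky + (cy - 1L)) * kx + cx
  counts <- array(tabulate(cell, nbins = kx * ky * nz), dim = c(kx, ky, nz))
  stat <- 0
  df <- 0L
  for (s in seq_len(nz)) {
    tab <- counts[, , s, drop = TRUE]
    dim(tab) <- c(kx, ky)
    tot <- sum(tab)
    if (tot == 0) next
    rs <- rowSums(tab); cs <- colSums(tab)
    keep_r <- rs > 0; keep_c <- cs > 0
    if (sum(keep_r) < 2 || sum(keep_c) < 2) next
    tab <- tab[keep_r, keep_c, drop = FALSE]
    e <- outer(rs[keep_r], cs[keep_c]) / tot
    nzc <- tab > 0
    stat <- stat + 2 * sum(tab[nzc] * log(tab[nzc] / e[nzc]))
    df <- df + (sum(keep_r) - 1L) * (sum(keep_c) - 1L)
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, degrees_of_freedom = df, p_value = p,
       independent = p > alpha)
}
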