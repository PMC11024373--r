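#' Realized additive relationship matrix over pools and individuals
#'
#' VanRaden method-1 genomic relationship matrix computed on the shared
#' 0-2 allele scale, so DNA pools (twice the alternate-allele frequency)
#' and individuals (dosages) are treated identically:
#' with column allele frequencies `p_m = colmean/2`,
#' `A = W W' / (2 * sum p_m (1 - p_m))` where `W` is the column-centered
#' matrix `M - 2p`. Monomorphic columns (p = 0 or 1) carry no relationship
#' information and are excluded from both the numerator and the
#' denominator, so adding one leaves `A` unchanged.
#'
#' @param matrix samples x markers matrix on the 0-2 scale, no missing
#'   values (impute first, e.g. via [apply_filters()]).
#' @param ridge nonnegative value added to the diagonal for numerical
#'   stabilization (default 0; [gblup()] applies its own ridge).
#' @return symmetric relationship matrix (class `"matrix"`) with sample
#'   ids as dimnames and the per-column allele frequencies in
#'   `attr(, "allele_freq")`.
#' @examples
#' M <- rbind(a = c(0, 2), b = c(2, 0), c = c(1, 1))
#' additive_relationship(M)
#' @export
additive_relationship <- function(matrix, ridge = 0) {
  if (anyNA(matrix)) stop_input("matrix has missing values; impute first")
  if (nrow(matrix) < 2 || ncol(matrix) < 2)
    stop_input("need at least 2 samples and 2 markers")
  p <- colMeans(matrix) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_input("all markers are monomorphic")
  W <- sweep(matrix[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  A <- tcrossprod(W) / denom
  if (ridge > 0) diag(A) <- diag(A) + ridge
  dimnames(A) <- list(rownames(matrix), rownames(matrix))
  attr(A, "allele_freq") <- p
  A
}
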