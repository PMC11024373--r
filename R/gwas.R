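#' Kinship-corrected single-marker association scan
#'
#' Scans each marker column for association with the phenotype under the
#' mixed model of [gblup()]: the null model carries the fixed effects
#' (e.g. environment), the genomic random effect with covariance
#' `A sigma2_g`, optional per-environment residual variances and an
#' optional extra random effect; each marker is then added as one fixed
#' covariate on the 0-2 allele scale and its coefficient is Wald-tested.
#' In `"p3d"` mode (population parameters previously determined) the
#' variance components are estimated once under the null and reused for
#' every marker — a generalized least squares test per marker. In
#' `"exact"` mode the components are re-estimated for every marker
#' (slower; for small panels). q-values are Benjamini-Hochberg.
#'
#' Markers that are (numerically) collinear with the fixed effects — e.g.
#' a marker identical to an environment indicator — and markers with zero
#' variance get `NA` p-values with a warning count.
#'
#' @param formula,data,kinship,id,residual_by,extra_random,ridge as in
#'   [gblup()].
#' @param markers samples x markers matrix on the 0-2 scale (row names are
#'   sample ids; every id in `data` must appear). Pools and individuals
#'   can be mixed.
#' @param mode `"p3d"` (default) or `"exact"`.
#' @param map optional marker metadata (`marker_id`, `chrom`, `pos`)
#'   joined into the result.
#' @param min_rel_var minimum fraction of a marker's variance left after
#'   projecting on the fixed effects for it to be testable.
#' @return data.frame of class `"gwas_result"`: `marker_id`, optional
#'   `chrom`/`pos`, `af` (allele frequency in the scanned panel),
#'   `effect`, `se`, `statistic`, `df`, `p_value`, `q_value`, `lod`.
#'   The null-model fit is attached as `attr(, "null_fit")`.
#' @export
gwas_scan <- function(formula, data, kinship, markers, id = "sample_id",
                      residual_by = NULL, extra_random = NULL,
                      mode = c("p3d", "exact"), map = NULL,
                      ridge = 1e-6, min_rel_var = 1e-8) {
  mode <- match.arg(mode)
  fit0 <- gblup(formula, data, kinship, id = id, residual_by = residual_by,
                extra_random = extra_random, ridge = ridge)
  ids <- fit0$ids
  missing <- setdiff(ids, rownames(markers))
  if (length(missing))
    stop_input("samples without marker data: %s",
               paste(head(missing, 5), collapse = ", "))
  Mk <- markers[ids, , drop = FALSE]
  m <- ncol(Mk)
  y <- fit0$y; X <- fit0$X; n <- fit0$n; p <- fit0$p
  df <- n - p - 1
  if (df < 1) stop_input("not enough records for a marker test (df < 1)")

  eff <- se <- tstat <- rep(NA_real_, m)
  if (mode == "p3d") {
    Vinv <- fit0$Vinv
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    XtVinvX_inv <- solve(XtVinvX)
    XtVinvy <- crossprod(VinvX, y)
    bhat0 <- drop(XtVinvX_inv %*% XtVinvy)
    resid0 <- y - drop(X %*% bhat0)
    rPr0 <- drop(crossprod(resid0, Vinv %*% resid0))
    VinvM <- Vinv %*% Mk
    XtVinvM <- crossprod(VinvX, Mk)          # p x m
    cmm <- colSums(Mk * VinvM)               # x'Vinv x
    cmy <- drop(crossprod(VinvM, y))         # x'Vinv y
    AtXi <- XtVinvX_inv %*% XtVinvM          # p x m
    schur <- cmm - colSums(XtVinvM * AtXi)   # x'Px
    num <- cmy - drop(crossprod(XtVinvM, bhat0))
    # collinearity / zero variance guard on the V-metric projection
    testable <- !is.na(schur) & schur > min_rel_var * pmax(cmm, min_rel_var)
    b <- num / schur
    # residual scale re-estimated per marker (GLS F-test form); with
    # V proportional to I this reduces exactly to the OLS t-test
    s2 <- pmax(rPr0 - num^2 / schur, 0) / df
    v <- s2 / schur
    eff[testable] <- b[testable]
    se[testable] <- sqrt(v[testable])
    tstat <- eff / se
  } else {
    for (j in seq_len(m)) {
      x <- Mk[, j]
      if (var(x) < min_rel_var) next
      dat_j <- data
      dat_j[[".marker"]] <- x[match(as.character(data[[id]]), ids)]
      f_j <- stats::update(formula, . ~ . + .marker)
      fit_j <- tryCatch(
        gblup(f_j, dat_j, kinship, id = id, residual_by = residual_by,
              extra_random = extra_random, ridge = ridge),
        error = function(e) NULL)
      if (is.null(fit_j) || !".marker" %in% names(fit_j$beta)) next
      k <- which(names(fit_j$beta) == ".marker")
      eff[j] <- fit_j$beta[k]
      se[j] <- sqrt(fit_j$vcov_beta[k, k])
      tstat[j] <- eff[j] / se[j]
    }
  }
  pval <- 2 * pt(-abs(tstat), df)
  n_flagged <- sum(is.na(pval))
  if (n_flagged)
    warning(sprintf("%d marker(s) untestable (zero variance or collinear with fixed effects)",
                    n_flagged))
  out <- data.frame(marker_id = colnames(Mk) %||% sprintf("m%d", seq_len(m)),
                    af = colMeans(Mk) / 2,
                    effect = eff, se = se, statistic = tstat,
                    df = df, p_value = pval,
                    q_value = bh_qvalues(pval),
                    lod = -log10(pval),
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    idx <- match(out$marker_id, map$marker_id)
    out$chrom <- map$chrom[idx]
    out$pos <- map$pos[idx]
    out <- out[, c("marker_id", "chrom", "pos",
                   setdiff(names(out), c("marker_id", "chrom", "pos")))]
  }
  rownames(out) <- NULL
  attr(out, "null_fit") <- fit0
  attr(out, "mode") <- mode
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_i = \min_{j: p_j \ge p_i} m\,p_j / \mathrm{rank}_j}, capped at 1.
#' Missing p-values are propagated and excluded from the number of tests
#' `m`.
#'
#' @param p numeric vector of p-values in `(0, 1]` (`NA` allowed).
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_qvalues <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1))
    stop_input("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Significant markers with breeding-direction labels
#'
#' Filters a scan to markers with `q < q_threshold` and labels each hit by
#' whether its minor allele moves the trait in the favorable direction.
#' The minor allele is taken from the scanned panel's folded frequency;
#' its effect sign is the marker effect sign, flipped when the alternate
#' allele is the major one. For traits where lower values are better
#' (`favorable_direction = -1`, e.g. seed dormancy and pod dehiscence), a
#' minor allele with a negative effect is `"favorable"`.
#'
#' @param result a [gwas_scan()] result.
#' @param q_threshold FDR threshold (default 0.01).
#' @param favorable_direction `+1` or `-1`: the effect sign that improves
#'   the trait.
#' @return the significant subset of `result` with columns
#'   `minor_allele_effect_sign` and `direction`
#'   (`"favorable"`/`"unfavorable"`).
#' @export
significant_hits <- function(result, q_threshold = 0.01,
                             favorable_direction = -1) {
  stopifnot(favorable_direction %in% c(-1, 1))
  sel <- !is.na(result$q_value) & result$q_value < q_threshold
  hits <- result[sel, , drop = FALSE]
  if (nrow(hits) == 0) {
    hits$minor_allele_effect_sign <- integer(0)
    hits$direction <- character(0)
    return(hits)
  }
  minor_sign <- ifelse(hits$af <= 0.5, sign(hits$effect), -sign(hits$effect))
  hits$minor_allele_effect_sign <- as.integer(minor_sign)
  hits$direction <- ifelse(minor_sign == favorable_direction,
                           "favorable", "unfavorable")
  rownames(hits) <- NULL
  hits
}
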