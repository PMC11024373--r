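#' Fit a GBLUP mixed model by REML
#'
#' Fits the genomic best linear unbiased prediction model
#' \deqn{y = X\beta + Z g + \epsilon, \qquad g \sim N(0, A\,\sigma^2_g),}
#' where `A` is a realized additive relationship matrix (typically from
#' [additive_relationship()]) over any mix of DNA pools and individuals,
#' `X` holds an intercept plus the fixed effects in `formula` (for
#' multi-environment data, the site-year factor), and the residuals are
#' independent with either a common variance or a separate variance per
#' `residual_by` group (a diagonal heteroscedastic structure across
#' environments). An optional additional independent random effect (e.g.
#' maternal line x environment) is supported via `extra_random`.
#'
#' Variance components are estimated by REML: the homogeneous-residual
#' model uses the eigendecomposition of `Z A Z'` and a one-dimensional
#' profile over the residual/genetic variance ratio; heterogeneous
#' residuals (and the extra random effect) are fitted by direct
#' Nelder-Mead maximization of the dense restricted log-likelihood,
#' started from the homogeneous solution. GEBVs are computed for every row
#' of `A`, including pools and unphenotyped individuals.
#'
#' Fixed-effect factors use treatment contrasts with the lexicographically
#' first level as reference; character columns are converted to factors
#' with sorted levels, and factor terms with fewer than two observed
#' levels are dropped (e.g. the environment effect when training on a
#' single environment).
#'
#' @param formula model formula, response on the left and fixed effects on
#'   the right, e.g. `value ~ environment`.
#' @param data data.frame of phenotype records; must contain the formula
#'   variables and the `id` column mapping each record to a row of
#'   `kinship`. Pool records simply carry the pool's mean phenotype.
#' @param kinship relationship matrix with dimnames covering all ids in
#'   `data` (extra rows are fine — they get GEBVs too).
#' @param id name of the sample-id column (default `"sample_id"`).
#' @param residual_by optional column name grouping residual variances
#'   (one \eqn{\sigma^2_{e,k}} per group, typically the environment).
#' @param extra_random optional column name for an additional iid random
#'   intercept (its grouping factor).
#' @param ridge added to `diag(A)` for invertibility (default `1e-6`).
#' @param tol relative convergence tolerance of the REML optimizer.
#' @param max_iter maximum optimizer iterations.
#' @return Object of class `"gblup"` with components `beta` (fixed
#'   effects), `vcov_beta`, `varcomp` (list: `sigma2_g`, `sigma2_e` named
#'   per residual group, optional `sigma2_extra`), `gebv` (named, all `A`
#'   rows), `logLik` (restricted), `converged`, `fitted`, `residuals`,
#'   `h2` (\eqn{\sigma^2_g / (\sigma^2_g + \bar\sigma^2_e)}), and the
#'   internal design pieces reused by [gwas_scan()].
#' @examples
#' set.seed(1)
#' M <- matrix(rbinom(40 * 60, 2, 0.4), 40, 60,
#'             dimnames = list(sprintf("s%02d", 1:40), NULL))
#' A <- additive_relationship(M)
#' g <- drop(M %*% rnorm(60, 0, 0.15)); g <- g - mean(g)
#' d <- data.frame(sample_id = rownames(M),
#'                 environment = rep(c("E1", "E2"), each = 20),
#'                 value = g + rnorm(40))
#' fit <- gblup(value ~ environment, d, A, residual_by = "environment")
#' fit
#' cor(predict(fit, rownames(M)), g)
#' @export
gblup <- function(formula, data, kinship, id = "sample_id",
                  residual_by = NULL, extra_random = NULL,
                  ridge = 1e-6, tol = 1e-8, max_iter = 2000) {
  stopifnot(is.data.frame(data), id %in% names(data))
  vars <- unique(c(all.vars(formula), id, residual_by, extra_random))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_input("columns not in `data`: %s", paste(missing_cols, collapse = ", "))
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (nrow(data) < 3) stop_input("fewer than 3 complete records")

  ids <- as.character(data[[id]])
  a_ids <- rownames(kinship)
  if (is.null(a_ids)) stop_input("`kinship` needs row/column names")
  unknown <- setdiff(ids, a_ids)
  if (length(unknown))
    stop_input("ids not in kinship matrix: %s",
               paste(head(unknown, 5), collapse = ", "))

  # sorted-level factors => reproducible treatment contrasts
  for (v in setdiff(all.vars(formula)[-1], id)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]], sort(unique(data[[v]])))
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }
  formula <- drop_single_level_terms(formula, data)

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n < p + 2) stop_input("need n >= number of fixed effects + 2")

  A <- kinship
  diag(A) <- diag(A) + ridge
  q <- nrow(A)
  Z <- matrix(0, n, q, dimnames = list(NULL, a_ids))
  Z[cbind(seq_len(n), match(ids, a_ids))] <- 1
  M <- Z %*% A %*% t(Z)

  groups <- if (is.null(residual_by)) factor(rep("all", n))
            else factor(as.character(data[[residual_by]]),
                        sort(unique(as.character(data[[residual_by]]))))
  K <- nlevels(groups)
  Mf <- NULL
  if (!is.null(extra_random)) {
    fg <- factor(as.character(data[[extra_random]]))
    Zf <- stats::model.matrix(~ fg - 1)
    Mf <- tcrossprod(Zf)
  }

  vfloor <- 1e-8 * max(var(y), 1e-12)

  # -- stage 1: homogeneous-residual fit via eigendecomposition ------------
  hom <- reml_eigen(y, X, M, vfloor, tol)

  if (K == 1 && is.null(Mf)) {
    sg2 <- hom$sigma2_g
    se2 <- setNames(rep(hom$sigma2_e, K), levels(groups))
    sf2 <- NULL
    converged <- TRUE
    iterations <- hom$iterations
  } else {
    theta0 <- log(pmax(c(hom$sigma2_g, rep(hom$sigma2_e, K),
                         if (!is.null(Mf)) 0.25 * hom$sigma2_e), vfloor))
    nll <- function(theta) {
      v <- exp(theta)
      reml_nll_dense(v[1], v[2:(1 + K)], if (!is.null(Mf)) v[2 + K],
                     y, X, M, Mf, groups)
    }
    opt <- optim(theta0, nll, method = "Nelder-Mead",
                 control = list(reltol = tol * 1e-2, maxit = max_iter))
    v <- pmax(exp(opt$par), vfloor)
    sg2 <- v[1]
    se2 <- setNames(v[2:(1 + K)], levels(groups))
    sf2 <- if (!is.null(Mf)) v[2 + K] else NULL
    converged <- opt$convergence == 0
    iterations <- opt$counts[["function"]]
  }

  # -- final dense solve at the REML estimates -----------------------------
  V <- sg2 * M + diag(se2[as.integer(groups)], n)
  if (!is.null(Mf)) V <- V + sf2 * Mf
  R <- tryCatch(chol(V), error = function(e)
    stop_input("V is numerically singular; increase `ridge`"))
  Vinv <- chol2inv(R)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  vcov_beta <- solve(XtVinvX)
  beta <- drop(vcov_beta %*% crossprod(VinvX, y))
  names(beta) <- colnames(X)
  resid_mar <- y - drop(X %*% beta)
  Pres <- drop(Vinv %*% resid_mar)
  gebv <- drop(sg2 * A %*% crossprod(Z, Pres))
  names(gebv) <- a_ids
  fitted <- drop(X %*% beta) + gebv[ids]
  logdetV <- 2 * sum(log(diag(R)))
  logdetX <- determinant(XtVinvX, logarithm = TRUE)$modulus
  rPr <- sum(resid_mar * Pres)
  ll <- -0.5 * (logdetV + logdetX + rPr + (n - p) * log(2 * pi))

  structure(list(
    call = match.call(),
    beta = beta, vcov_beta = vcov_beta,
    varcomp = c(list(sigma2_g = sg2, sigma2_e = se2),
                if (!is.null(sf2)) list(sigma2_extra = sf2)),
    h2 = sg2 / (sg2 + mean(se2)),
    gebv = gebv,
    logLik = as.numeric(ll),
    converged = converged, iterations = iterations,
    fitted = fitted, residuals = y - fitted,
    y = y, X = X, Z = Z, ids = ids, groups = groups,
    Vinv = Vinv, A_ids = a_ids, n = n, p = p,
    formula = formula
  ), class = "gblup")
}

# drop factor terms with < 2 observed levels (single-environment training)
drop_single_level_terms <- function(formula, data) {
  tl <- attr(terms(formula), "term.labels")
  drop <- vapply(tl, function(tm) {
    v <- all.vars(as.formula(paste("~", tm)))
    any(vapply(v, function(x) {
      col <- data[[x]]
      (is.factor(col) || is.character(col)) && length(unique(col)) < 2
    }, logical(1)))
  }, logical(1))
  if (!any(drop)) return(formula)
  keep <- tl[!drop]
  rhs <- if (length(keep)) paste(keep, collapse = " + ") else "1"
  as.formula(paste(deparse(formula[[2]]), "~", rhs), env = environment(formula))
}

# EMMA-style REML: V = sigma2_g * (M + delta I); profile the restricted
# likelihood over delta on the eigenbasis of M
reml_eigen <- function(y, X, M, vfloor, tol) {
  n <- length(y); p <- ncol(X)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(log_delta) {
    w <- d + exp(log_delta)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    bt <- tryCatch(solve(XtWX, crossprod(Xw, yt)), error = function(e) NULL)
    if (is.null(bt)) return(1e10)
    r <- yt - drop(Xt %*% bt)
    rss <- sum(r^2 / w)
    sg2 <- max(rss / (n - p), .Machine$double.xmin)
    ld <- determinant(XtWX, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(sg2) + sum(log(w)) + as.numeric(ld) + (n - p))
  }
  grid <- seq(-16, 16, length.out = 121)
  vals <- vapply(grid, prof, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  op <- optimize(prof, c(lo, hi), tol = 1e-10)
  delta <- exp(op$minimum)
  w <- d + delta
  Xw <- Xt / w
  XtWX <- crossprod(Xt, Xw)
  bt <- solve(XtWX, crossprod(Xw, yt))
  rss <- sum((yt - drop(Xt %*% bt))^2 / w)
  sg2 <- max(rss / (n - p), vfloor)
  list(sigma2_g = sg2, sigma2_e = max(delta * sg2, vfloor),
       iterations = length(grid))
}

# dense negative restricted log-likelihood (constants dropped)
reml_nll_dense <- function(sg2, se2, sf2, y, X, M, Mf, groups) {
  n <- length(y)
  V <- sg2 * M + diag(se2[as.integer(groups)], n)
  if (!is.null(Mf) && !is.null(sf2)) V <- V + sf2 * Mf
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  Vinv <- chol2inv(R)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  ldX <- determinant(XtVinvX, logarithm = TRUE)
  if (ldX$sign <= 0) return(1e10)
  beta <- tryCatch(solve(XtVinvX, crossprod(VinvX, y)), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  r <- y - drop(X %*% beta)
  rPr <- drop(crossprod(r, Vinv %*% r))
  0.5 * (2 * sum(log(diag(R))) + as.numeric(ldX$modulus) + rPr)
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit (REML)\n")
  cat(sprintf("  records: %d; relationship rows: %d; fixed effects: %d\n",
              x$n, length(x$gebv), x$p))
  cat(sprintf("  sigma2_g = %.4g; sigma2_e = %s%s\n",
              x$varcomp$sigma2_g,
              paste(sprintf("%s %.4g", names(x$varcomp$sigma2_e),
                            x$varcomp$sigma2_e), collapse = ", "),
              if (!is.null(x$varcomp$sigma2_extra))
                sprintf("; sigma2_extra = %.4g", x$varcomp$sigma2_extra) else ""))
  cat(sprintf("  h2 = %.3f; restricted logLik = %.3f; converged: %s\n",
              x$h2, x$logLik, x$converged))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  coef_table <- cbind(Estimate = object$beta, `Std. Error` = se,
                      `z value` = object$beta / se)
  out <- list(coef = coef_table, varcomp = object$varcomp, h2 = object$h2,
              logLik = object$logLik, n = object$n,
              converged = object$converged)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("GBLUP mixed model (REML)\n\nFixed effects:\n")
  print(round(x$coef, 4))
  cat("\nVariance components:\n")
  cat(sprintf("  genetic:  %.5g\n", x$varcomp$sigma2_g))
  for (g in names(x$varcomp$sigma2_e))
    cat(sprintf("  residual [%s]: %.5g\n", g, x$varcomp$sigma2_e[[g]]))
  if (!is.null(x$varcomp$sigma2_extra))
    cat(sprintf("  extra random: %.5g\n", x$varcomp$sigma2_extra))
  cat(sprintf("\nh2 = %.3f; n = %d; restricted logLik = %.3f\n",
              x$h2, x$n, x$logLik))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$residuals

#' @export
logLik.gblup <- function(object, ...) {
  structure(object$logLik, df = object$p + length(object$varcomp$sigma2_e) + 1,
            class = "logLik")
}

#' Predict genomic estimated breeding values
#'
#' Returns the fit's GEBVs for the requested samples. Any row of the
#' relationship matrix can be predicted, including pools and individuals
#' that contributed no phenotype records.
#'
#' @param object a [gblup()] fit.
#' @param ids sample ids (default: all rows of the relationship matrix).
#' @param ... unused.
#' @return named numeric vector of GEBVs.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  if (is.null(ids)) return(object$gebv)
  unknown <- setdiff(ids, names(object$gebv))
  if (length(unknown))
    stop_input("ids not in the relationship matrix: %s",
               paste(head(unknown, 10), collapse = ", "))
  object$gebv[ids]
}
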