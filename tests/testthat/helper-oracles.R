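# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive, direct-formula implementations kept separate from the
# package's code paths.

# dense GLS/BLUP closed form: beta = (X'V^-1X)^-1 X'V^-1 y,
# g = sg2 * A Z' V^-1 (y - X beta), with V = sg2 ZAZ' + diag(se2 by group)
oracle_blup <- function(y, X, Z, A, sg2, se2, groups = NULL, ridge = 1e-6) {
  Ar <- A
  diag(Ar) <- diag(Ar) + ridge
  n <- length(y)
  se2v <- if (is.null(groups)) rep(se2, n) else se2[as.integer(groups)]
  V <- sg2 * (Z %*% Ar %*% t(Z)) + diag(se2v, n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  g <- sg2 * (Ar %*% t(Z) %*% (Vi %*% r))
  list(beta = drop(beta), gebv = drop(g))
}

# negative restricted log-likelihood, direct dense formula
oracle_reml_nll <- function(sg2, se2, y, X, Z, A, ridge = 1e-6) {
  Ar <- A
  diag(Ar) <- diag(Ar) + ridge
  n <- length(y)
  V <- sg2 * (Z %*% Ar %*% t(Z)) + diag(se2, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  beta <- tryCatch(solve(XtViX, t(X) %*% Vi %*% y), error = function(e) NULL)
  if (is.null(beta)) return(Inf)
  r <- y - X %*% beta
  as.numeric(0.5 * (2 * sum(log(diag(ch))) +
                      determinant(XtViX, logarithm = TRUE)$modulus +
                      t(r) %*% Vi %*% r))
}

# 2-D nested grid search over (sg2, se2) maximizing the restricted
# likelihood; log-spaced grid refined around the incumbent
oracle_grid_reml <- function(y, X, Z, A, ridge = 1e-6,
                             n_grid = 41, n_refine = 6) {
  vy <- var(y)
  lo <- rep(log(1e-9 * vy), 2)
  hi <- rep(log(50 * vy), 2)
  best <- c(NA, NA)
  for (it in seq_len(n_refine)) {
    g1 <- seq(lo[1], hi[1], length.out = n_grid)
    g2 <- seq(lo[2], hi[2], length.out = n_grid)
    vals <- outer(g1, g2, Vectorize(function(a, b)
      oracle_reml_nll(exp(a), exp(b), y, X, Z, A, ridge)))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    step1 <- g1[2] - g1[1]; step2 <- g2[2] - g2[1]
    lo <- best - 2 * c(step1, step2)
    hi <- best + 2 * c(step1, step2)
  }
  out <- list(sigma2_g = exp(best[1]), sigma2_e = exp(best[2]),
              nll = oracle_reml_nll(exp(best[1]), exp(best[2]), y, X, Z, A, ridge))
  # boundary slices: optimum may sit at (essentially) zero for one component
  floor_v <- 1e-9 * vy
  for (side in 1:2) {
    lo1 <- log(1e-9 * vy); hi1 <- log(50 * vy)
    b <- NA
    for (it in seq_len(n_refine)) {
      g <- seq(lo1, hi1, length.out = n_grid)
      vals <- vapply(g, function(a) {
        if (side == 1) oracle_reml_nll(exp(a), floor_v, y, X, Z, A, ridge)
        else oracle_reml_nll(floor_v, exp(a), y, X, Z, A, ridge)
      }, numeric(1))
      i <- which.min(vals)
      b <- g[i]; step <- g[2] - g[1]
      lo1 <- b - 2 * step; hi1 <- b + 2 * step
    }
    cand_nll <- if (side == 1) oracle_reml_nll(exp(b), floor_v, y, X, Z, A, ridge)
                else oracle_reml_nll(floor_v, exp(b), y, X, Z, A, ridge)
    if (cand_nll < out$nll) {
      out <- if (side == 1) list(sigma2_g = exp(b), sigma2_e = floor_v, nll = cand_nll)
             else list(sigma2_g = floor_v, sigma2_e = exp(b), nll = cand_nll)
    }
  }
  out
}

# brute-force BH step-up: q_i = min over {j: p_j >= p_i} of m * p_j / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / rk[cand]))
  }, numeric(1))
}

# random small GBLUP instance on simulated marker data
make_instance <- function(seed, n = NULL, n_env = NULL, m = 60) {
  set.seed(seed)
  n <- n %||% sample(10:30, 1)
  n_env <- n_env %||% sample(1:3, 1)
  ids <- sprintf("s%02d", seq_len(n))
  M <- matrix(rbinom(n * m, 2, rep(runif(m, 0.15, 0.85), each = n)), n, m,
              dimnames = list(ids, NULL))
  while (all(apply(M, 2, var) == 0)) M <- M + rbinom(length(M), 1, 0.5)
  A <- poolgp::additive_relationship(M)
  env <- factor(sort(rep_len(paste0("E", seq_len(n_env)), n)))
  g <- drop(M %*% rnorm(m, 0, 0.15)); g <- g - mean(g)
  y <- g + as.numeric(env) * 0.5 + rnorm(n, 0, 1)
  data <- data.frame(sample_id = ids, environment = as.character(env), value = y)
  X <- if (n_env > 1) stats::model.matrix(~ environment, data)
       else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- diag(n); dimnames(Z) <- list(NULL, ids)
  list(data = data, A = A, X = X, Z = Z, y = y, env = env, M = M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
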