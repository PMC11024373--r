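#' Reference ("true") GEBVs from the full individual panel
#'
#' Fits GBLUP on all individual phenotype records — environment fixed
#' effects, per-environment residual variances — and returns the GEBVs.
#' These serve as the reference breeding values that pool-trained or
#' subset-trained models are scored against.
#'
#' @param records individual phenotype records (`sample_id`,
#'   `environment`, `value`).
#' @param kinship relationship matrix covering all record ids.
#' @param ... passed to [gblup()].
#' @return named GEBV vector over all rows of `kinship`.
#' @export
true_gebvs <- function(records, kinship, ...) {
  fit <- gblup(value ~ environment, records, kinship,
               residual_by = "environment", ...)
  fit$gebv
}

#' Predictive ability of a GEBV vector
#'
#' Pearson correlation between predicted and reference GEBVs over the
#' target individuals, with a standard error by nonparametric bootstrap
#' over targets (default) or by the analytic Fisher-z formula
#' \eqn{(1 - r^2)/\sqrt{n - 3}}.
#'
#' @param pred,truth named numeric vectors; scored over the intersection
#'   of their names (or positionally if unnamed).
#' @param se_method `"bootstrap"` or `"fisher_z"`.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @param label optional comparison label.
#' @return one-row data.frame: `comparison`, `r`, `se`, `n`, `se_method`.
#' @export
predictive_ability <- function(pred, truth, se_method = c("bootstrap", "fisher_z"),
                               n_boot = 1000, seed = 1L, label = NA_character_) {
  se_method <- match.arg(se_method)
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    common <- intersect(names(pred), names(truth))
    pred <- pred[common]; truth <- truth[common]
  }
  ok <- is.finite(pred) & is.finite(truth)
  pred <- pred[ok]; truth <- truth[ok]
  n <- length(pred)
  if (n < 4) stop_input("need at least 4 aligned targets (have %d)", n)
  if (sd(pred) == 0 || sd(truth) == 0) {
    warning("zero-variance vector; predictive ability undefined")
    return(data.frame(comparison = label, r = NA_real_, se = NA_real_,
                      n = n, se_method = se_method, stringsAsFactors = FALSE))
  }
  r <- cor(pred, truth)
  se <- if (se_method == "fisher_z") {
    (1 - r^2) / sqrt(n - 3)
  } else {
    set.seed(seed)
    rb <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (sd(pred[i]) == 0 || sd(truth[i]) == 0) NA_real_
      else cor(pred[i], truth[i])
    }, numeric(1))
    sd(rb, na.rm = TRUE)
  }
  data.frame(comparison = label, r = r, se = se, n = n,
             se_method = se_method, stringsAsFactors = FALSE)
}

#' Run a suite of training-subset prediction comparisons
#'
#' Replicates the pooled-DNA validation design: for each named training
#' subset (e.g. "all pools", "Wisconsin pools only", a single
#' environment's individuals), fit GBLUP on the subset's records, predict
#' the target individuals, and score the predictions against reference
#' GEBVs. The environment fixed effect is dropped automatically for
#' single-environment subsets.
#'
#' @param records phenotype records for all candidate training samples
#'   (`sample_id`, `environment`, `value`).
#' @param kinship relationship matrix over training samples and targets.
#' @param subsets named list; each element is a character vector of
#'   sample ids defining one training subset.
#' @param targets sample ids to predict.
#' @param truth named reference vector (e.g. [true_gebvs()] output or
#'   simulated true breeding values).
#' @param se_method,n_boot,seed passed to [predictive_ability()].
#' @param ... passed to [gblup()] (e.g. `residual_by`).
#' @return data.frame, one row per subset: `comparison`, `n_train`
#'   (records), `r`, `se`, `n`, `se_method`. Empty subsets are skipped
#'   with a warning.
#' @export
run_comparison_suite <- function(records, kinship, subsets, targets, truth,
                                 se_method = "bootstrap", n_boot = 1000,
                                 seed = 1L, ...) {
  out <- list()
  for (nm in names(subsets)) {
    recs <- records[records$sample_id %in% subsets[[nm]], , drop = FALSE]
    if (nrow(recs) == 0) {
      warning(sprintf("subset '%s' has no records; skipped", nm))
      next
    }
    fit <- gblup(value ~ environment, recs, kinship, ...)
    pred <- predict(fit, targets)
    pa <- predictive_ability(pred, truth[targets], se_method = se_method,
                             n_boot = n_boot, seed = seed, label = nm)
    pa$n_train <- nrow(recs)
    out[[nm]] <- pa
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("comparison", "n_train", "r", "se", "n", "se_method")]
}
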