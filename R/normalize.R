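#' Impute left-censored missing values
#'
#' Two strategies, matching the two analysis arms:
#' * `"zero"` (diagnostic arm): missing values are treated as below the
#'   detection limit and set to a hard floor. Because log2(0) is undefined,
#'   the matrix is first shifted so the smallest observed log2 value maps to
#'   1; every missing cell then receives the floor value 0. The shift is
#'   recorded in `attr(, "floor_shift")`.
#' * `"min_det"` (exploratory arm): deterministic minimal-value imputation —
#'   each missing cell receives the `min_det_quantile` quantile (type 7) of
#'   that sample's observed log2 values.
#'
#' Observed cells are never altered; the mask is retained as provenance.
#'
#' @param m protein `ExpressionMatrix` at log2 scale.
#' @param method `"min_det"` or `"zero"`.
#' @param min_det_quantile per-sample quantile for `"min_det"`
#'   (default 0.01; must lie in (0, 0.5) or be exactly 0 for the sample
#'   minimum).
#' @return complete `ExpressionMatrix` (scale `"log2"`), mask retained,
#'   with attributes `impute_method` and (zero method) `floor_shift`.
#' @export
impute_missing <- function(m, method = c("min_det", "zero"),
                           min_det_quantile = 0.01) {
  assert_em(m, layer = "protein", scale = "log2")
  method <- match.arg(method)
  if (min_det_quantile < 0 || min_det_quantile >= 0.5) {
    stop("`min_det_quantile` must lie in [0, 0.5)", call. = FALSE)
  }
  v <- m$values
  n_obs <- colSums(!m$mask)
  if (any(n_obs == 0L)) {
    stop("sample(s) with zero observed values: ",
         paste(em_samples(m)[n_obs == 0L], collapse = ", "), call. = FALSE)
  }
  out <- m
  if (method == "zero") {
    shift <- min(v[!m$mask]) - 1
    v <- v - shift
    v[m$mask] <- 0
    attr(v, "floor_shift") <- NULL
    out$values <- v
    attr(out, "floor_shift") <- shift
  } else {
    for (j in seq_len(ncol(v))) {
      mis <- m$mask[, j]
      if (any(mis)) {
        v[mis, j] <- stats::quantile(v[!mis, j], probs = min_det_quantile,
                                     type = 7, names = FALSE)
      }
    }
    out$values <- v
  }
  attr(out, "impute_method") <- method
  out
}

#' Quantile normalization
#'
#' Classic rank-mean scheme: the k-th order statistic of every sample is
#' replaced by the mean across samples of the k-th order statistics. Ties
#' within a sample receive the mean of the reference values at their tied
#' positions (average ranks). Afterwards every sample has an identical
#' empirical distribution.
#'
#' @param m a complete (post-imputation) `ExpressionMatrix`.
#' @return normalized `ExpressionMatrix` (scale `"normalized"`).
#' @export
quantile_normalize <- function(m) {
  assert_em(m)
  v <- m$values
  if (anyNA(v)) stop("quantile_normalize requires a complete matrix", call. = FALSE)
  ref <- rowMeans(apply(v, 2L, sort, method = "radix"))
  out_v <- v
  for (j in seq_len(ncol(v))) {
    r <- rank(v[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out_v[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out <- m
  out$values <- out_v
  out$scale <- "normalized"
  out
}

#' Robust linear regression normalization
#'
#' Each sample is regressed on the per-gene median pseudo-reference by
#' iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345, at most 50 iterations, convergence 1e-8), then corrected by
#' inverting the fitted line. Outlying genes barely influence the fit, so a
#' handful of wild values cannot distort a sample's scaling. On
#' non-convergence the sample falls back to ordinary least squares with a
#' warning, recorded in `attr(, "rlr_fallback")`.
#'
#' @param m a complete `ExpressionMatrix`.
#' @return normalized `ExpressionMatrix` (scale `"normalized"`).
#' @export
rlr_normalize <- function(m) {
  assert_em(m)
  v <- m$values
  if (anyNA(v)) stop("rlr_normalize requires a complete matrix", call. = FALSE)
  ref <- apply(v, 1L, stats::median)
  out_v <- v
  fallback <- character(0)
  for (j in seq_len(ncol(v))) {
    # an (almost) exactly affine sample defeats the IRLS scale estimate;
    # OLS is the exact solution there, so use it directly
    ols <- stats::lm(v[, j] ~ ref)
    if (max(abs(stats::residuals(ols))) <= 1e-10 * (stats::sd(v[, j]) + 1)) {
      cf <- stats::coef(ols)
      out_v[, j] <- (v[, j] - cf[1L]) / cf[2L]
      next
    }
    fit <- suppressWarnings(
      MASS::rlm(v[, j] ~ ref, psi = MASS::psi.huber, k = 1.345,
                maxit = 50, acc = 1e-8)
    )
    if (!fit$converged) {
      warning(sprintf("rlm did not converge for sample '%s'; using OLS",
                      colnames(v)[j]), call. = FALSE)
      fallback <- c(fallback, colnames(v)[j])
      fit <- stats::lm(v[, j] ~ ref)
    }
    cf <- stats::coef(fit)
    out_v[, j] <- (v[, j] - cf[1L]) / cf[2L]
  }
  out <- m
  out$values <- out_v
  out$scale <- "normalized"
  attr(out, "rlr_fallback") <- fallback
  out
}

#' Variance-stabilizing transform for targeted RNA counts
#'
#' Median-of-ratios size factors (the bulk RNA-seq standard): per sample, the
#' median across genes of count / per-gene geometric mean, with genes
#' containing any zero excluded from the median. Size factors are rescaled
#' to median 1, which anchors the reference to the bulk of the cohort:
#' rescaling one sample's counts then rescales only that sample's size
#' factor, up to re-identification of the median anchor (an O(1/n_genes^0.5)
#' drift). If no gene is zero-free the size factors fall back to
#' total-count ratios, with a message. Transformed value:
#' `log2(count / size_factor + pseudocount)`.
#'
#' @param m rna `ExpressionMatrix` at linear (count) scale.
#' @param pseudocount added before the log (default 1).
#' @return `ExpressionMatrix` at scale `"vst"`, with `attr(, "size_factors")`.
#' @export
vst_rna <- function(m, pseudocount = 1) {
  assert_em(m, layer = "rna", scale = "linear")
  assert_scalar_number(pseudocount, "pseudocount", lower = 1e-12)
  v <- m$values
  nonzero <- rowSums(v == 0) == 0L
  if (any(nonzero)) {
    logg <- rowMeans(log(v[nonzero, , drop = FALSE]))
    sf <- apply(v[nonzero, , drop = FALSE], 2L, function(col) {
      stats::median(exp(log(col) - logg))
    })
  } else {
    stage_log("vst", "no zero-free gene; falling back to total-count size factors")
    tot <- colSums(v)
    sf <- tot / stats::median(tot)
  }
  sf <- sf / stats::median(sf)
  out <- m
  out$values <- log2(sweep(v, 2L, sf, "/") + pseudocount)
  out$scale <- "vst"
  attr(out, "size_factors") <- stats::setNames(sf, em_samples(m))
  out
}

#' Normalization quality metrics
#'
#' Internal replacement for an external normalization-comparison report: the
#' pooled coefficient of variation (per-gene sd/|mean| across samples,
#' averaged over genes, within groups when given) and the median absolute
#' deviation of per-sample medians. Lower is better on both; used to choose
#' between quantile and RLR normalization.
#'
#' @param before,after matched `ExpressionMatrix` objects.
#' @param groups optional per-sample group labels (e.g. batches) for the
#'   intragroup CV; default: one group.
#' @return list with `before` / `after` sublists of `pooled_cv` and
#'   `sample_median_mad`.
#' @export
assess_normalization <- function(before, after, groups = NULL) {
  assert_em(before); assert_em(after)
  stopifnot(identical(dim(before$values), dim(after$values)))
  metric <- function(m) {
    v <- m$values
    if (is.null(groups)) groups <- rep("all", ncol(v))
    cvs <- unlist(lapply(split(seq_len(ncol(v)), groups), function(idx) {
      if (length(idx) < 2L) return(numeric(0))
      sub <- v[, idx, drop = FALSE]
      mu <- rowMeans(sub)
      sdv <- apply(sub, 1L, stats::sd)
      ok <- abs(mu) > 1e-12
      sdv[ok] / abs(mu[ok])
    }))
    list(pooled_cv = mean(cvs),
         sample_median_mad = stats::mad(apply(v, 2L, stats::median)))
  }
  list(before = metric(before), after = metric(after))
}
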