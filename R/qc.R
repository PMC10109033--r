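#' Filter decision record
#'
#' Every filtering stage returns one of these so the funnel is auditable:
#' kept and dropped ids partition the input, each drop carries a reason.
#'
#' @param stage stage name.
#' @param kept,dropped id vectors (disjoint; union = input).
#' @param reasons character vector parallel to `dropped`.
#' @param threshold the threshold applied.
#' @return a list of class `FilterDecision` with a `percent_kept` field
#'   (half-up integer percentage).
#' @export
filter_decision <- function(stage, kept, dropped, reasons = rep("", length(dropped)),
                            threshold = NA_real_) {
  stopifnot(length(intersect(kept, dropped)) == 0L, length(reasons) == length(dropped))
  n_in <- length(kept) + length(dropped)
  structure(list(stage = stage, kept = kept, dropped = dropped,
                 reasons = stats::setNames(reasons, dropped), threshold = threshold,
                 n_input = n_in,
                 percent_kept = if (n_in > 0) funnel_percent(length(kept), n_in) else NA_real_),
            class = "FilterDecision")
}

#' @export
print.FilterDecision <- function(x, ...) {
  cat(sprintf("FilterDecision [%s]: kept %d / %d (%s%%), threshold %s\n",
              x$stage, length(x$kept), x$n_input, x$percent_kept,
              format(x$threshold)))
  invisible(x)
}

#' PCA of samples for eligibility screening
#'
#' Computed on log2 values. Missing cells are filled with the per-gene
#' minimum of observed values for the projection only (the data are never
#' modified); the minimum is the fill consistent with left-censored dropout
#' and keeps high-missingness samples visibly displaced, which is what the
#' eligibility screen must detect. Genes missing in more than half the
#' samples are excluded from the projection. Scores are centered by
#' construction.
#'
#' @param m an `ExpressionMatrix` (linear protein input is log2-transformed
#'   internally).
#' @param n_pc number of components to return (default 2).
#' @return list with `scores` (samples x PCs), `explained_variance`
#'   (fractions), and `genes_used`.
#' @export
pca_samples <- function(m, n_pc = 2L) {
  assert_em(m)
  if (ncol(m$values) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  if (m$scale == "linear" && m$layer == "protein") m <- em_log2(m)
  v <- m$values
  v[m$mask] <- NA_real_
  mv_frac <- rowMeans(m$mask)
  use <- mv_frac <= 0.5 & apply(v, 1L, function(r) sum(!is.na(r)) >= 2L)
  v <- v[use, , drop = FALSE]
  gmin <- apply(v, 1L, min, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- gmin[idx[, 1L]]
  fit <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  k <- min(n_pc, ncol(fit$x))
  scores <- fit$x[, seq_len(k), drop = FALSE]
  list(scores = scores,
       explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)],
       genes_used = rownames(v))
}

#' Per-sample QC report
#'
#' Collects, per sample: missing-value proportion, total observed linear
#' abundance, and PC1/PC2 coordinates; plus the missingness-vs-abundance
#' regression (over all proteins and over targeted proteins only, i.e.
#' excluding RBC/plasma background) and the abundance-density summary for
#' genes with vs without missing values.
#'
#' @param m protein `ExpressionMatrix` at linear scale.
#' @param annot a [gene_annotation()] (for the targeted-only regression).
#' @return list of class `QcReport`.
#' @export
qc_report <- function(m, annot = NULL) {
  assert_em(m, layer = "protein", scale = "linear")
  if (is.null(annot)) annot <- gene_annotation(em_genes(m))
  pca <- pca_samples(m)
  per_sample <- data.frame(
    sample = em_samples(m),
    mv_prop = colMeans(m$mask),
    total_abundance = colSums(ifelse(m$mask, 0, m$values), na.rm = TRUE),
    PC1 = pca$scores[, 1L],
    PC2 = if (ncol(pca$scores) >= 2L) pca$scores[, 2L] else 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rep <- list(
    per_sample = per_sample,
    n_genes = nrow(m$values),
    regression_all = mv_regression(m, annot, use_targeted_only = FALSE),
    regression_targeted = mv_regression(m, annot, use_targeted_only = TRUE),
    density = mv_density_summary(m),
    explained_variance = pca$explained_variance
  )
  class(rep) <- "QcReport"
  rep
}

#' Flag outlier samples from a QC report
#'
#' A sample is flagged when it sits more than `k_mad` robust deviations from
#' the cohort on either screen:
#' * PC space: per-coordinate robust z, `|pc - median| / MAD`, exceeding
#'   `k_mad` on any component;
#' * missingness: MV proportion above `median + k_mad * spread`, where the
#'   spread is the MAD floored at the binomial sampling noise
#'   `sqrt(p(1-p)/n_genes)` of the proportion itself (the raw MAD of a
#'   tightly clustered cohort underestimates that noise and over-flags).
#'
#' A reproducible replacement for by-eye PCA exclusion.
#'
#' @param qc a [qc_report()].
#' @param k_mad robustness multiplier (default 4).
#' @return a [filter_decision()] over sample ids.
#' @export
flag_outlier_samples <- function(qc, k_mad = 4) {
  stopifnot(inherits(qc, "QcReport"))
  ps <- qc$per_sample
  robust_z <- function(x) {
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    abs(x - stats::median(x)) / s
  }
  pc_flag <- pmax(robust_z(ps$PC1), robust_z(ps$PC2)) > k_mad
  p_med <- stats::median(ps$mv_prop)
  spread <- max(stats::mad(ps$mv_prop),
                sqrt(p_med * (1 - p_med) / max(qc$n_genes, 1L)))
  mv_flag <- ps$mv_prop > p_med + k_mad * spread
  flag <- pc_flag | mv_flag
  if (all(flag)) stop("all samples flagged as outliers; refusing to continue",
                      call. = FALSE)
  reasons <- ifelse(pc_flag & mv_flag, "pca_distance+mv_proportion",
                    ifelse(pc_flag, "pca_distance", "mv_proportion"))[flag]
  stage_log("qc", sprintf("flagged %d / %d samples at k_mad=%g",
                          sum(flag), nrow(ps), k_mad))
  filter_decision("outlier_samples", kept = ps$sample[!flag],
                  dropped = ps$sample[flag], reasons = reasons, threshold = k_mad)
}

#' Regression of missing-value proportion on total abundance
#'
#' Ordinary least squares of per-sample MV proportion on per-sample total
#' observed linear abundance. With `use_targeted_only = TRUE`, RBC/plasma
#' background proteins are excluded from both quantities; on left-censored
#' data this typically raises the R-squared markedly because the background
#' dominates total abundance without driving dropout of the proteins of
#' interest.
#'
#' @param m protein `ExpressionMatrix`, linear scale.
#' @param annot a [gene_annotation()].
#' @param use_targeted_only drop `nontarget_category != "none"` genes first.
#' @return list with `slope`, `intercept`, `r_squared`, `n_samples`.
#' @export
mv_regression <- function(m, annot, use_targeted_only = FALSE) {
  assert_em(m, layer = "protein", scale = "linear")
  if (ncol(m$values) < 3L) stop("regression needs at least 3 samples", call. = FALSE)
  if (use_targeted_only) {
    ann <- annot_lookup(annot, em_genes(m))
    m <- em_subset(m, genes = em_genes(m)[ann$nontarget_category == "none"])
  }
  y <- colMeans(m$mask)
  x <- colSums(ifelse(m$mask, 0, m$values), na.rm = TRUE)
  if (stats::sd(x) == 0) stop("zero variance in total abundance: fit undefined",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n_samples = length(y))
}

#' Abundance summary for genes with vs without missing values
#'
#' Per-gene mean observed log2 abundance, summarized separately for genes
#' with at least one missing value and genes with none. Under left-censored
#' dropout the with-MV group sits at lower abundance.
#'
#' @param m protein `ExpressionMatrix` (linear input log2-transformed).
#' @return list with per-group `mean`, `median`, `n`; empty groups yield `NA`
#'   summaries with a note rather than an error.
#' @export
mv_density_summary <- function(m) {
  assert_em(m, layer = "protein")
  if (m$scale == "linear") m <- em_log2(m)
  v <- m$values
  v[m$mask] <- NA_real_
  gene_mean <- rowMeans(v, na.rm = TRUE)
  has_mv <- rowSums(m$mask) > 0L
  grp <- function(sel) {
    x <- gene_mean[sel & is.finite(gene_mean)]
    list(mean = if (length(x)) mean(x) else NA_real_,
         median = if (length(x)) stats::median(x) else NA_real_,
         n = length(x))
  }
  out <- list(with_mv = grp(has_mv), without_mv = grp(!has_mv))
  out$note <- if (out$with_mv$n == 0L) "no genes with missing values"
              else if (out$without_mv$n == 0L) "no genes without missing values"
              else ""
  out
}

#' Filter proteins by missing-value fraction
#'
#' Keeps genes whose missing fraction over the given samples is at most
#' `max_mv_fraction` (inclusive boundary).
#'
#' @param m protein `ExpressionMatrix`.
#' @param max_mv_fraction threshold in `[0, 1]` (default 0.3).
#' @param samples samples to count over (default: all; pass the non-excluded
#'   set after outlier flagging).
#' @return a [filter_decision()] over gene ids.
#' @export
filter_proteins_by_mv <- function(m, max_mv_fraction = 0.3, samples = NULL) {
  assert_em(m, layer = "protein")
  assert_scalar_number(max_mv_fraction, "max_mv_fraction", 0, 1)
  if (!is.null(samples)) m <- em_subset(m, samples = samples)
  frac <- rowMeans(m$mask)
  keep <- frac <= max_mv_fraction
  stage_log("filter", sprintf("mv filter: kept %d / %d genes at <= %g",
                              sum(keep), length(keep), max_mv_fraction))
  filter_decision("protein_mv_filter", kept = em_genes(m)[keep],
                  dropped = em_genes(m)[!keep],
                  reasons = sprintf("mv_fraction=%.3f", frac[!keep]),
                  threshold = max_mv_fraction)
}

#' Filter RNA genes by total read count
#'
#' Keeps genes with total counts of at least `min_total`; genes with fewer
#' (strictly less) are dropped.
#'
#' @param m rna `ExpressionMatrix` at linear (count) scale.
#' @param min_total minimum total count (default 1000).
#' @return a [filter_decision()] over gene ids.
#' @export
filter_rna_by_total_count <- function(m, min_total = 1000) {
  assert_em(m, layer = "rna", scale = "linear")
  tot <- rowSums(m$values, na.rm = TRUE)
  keep <- tot >= min_total
  stage_log("filter", sprintf("rna count filter: kept %d / %d genes at >= %g",
                              sum(keep), length(keep), min_total))
  filter_decision("rna_total_count_filter", kept = em_genes(m)[keep],
                  dropped = em_genes(m)[!keep],
                  reasons = sprintf("total_count=%g", tot[!keep]),
                  threshold = min_total)
}

#' Protein/RNA gene-set overlap report
#'
#' Noncoding genes are removed from the RNA side before intersecting; the
#' coverage percentage is `100 * |intersection| / |RNA side|`, rounded
#' half-up to an integer.
#'
#' @param protein_kept,rna_kept gene id vectors after filtering.
#' @param annot a [gene_annotation()] (supplies `coding`).
#' @return list with `n_protein`, `n_rna` (after noncoding removal),
#'   `n_overlap`, `n_noncoding_removed`, `percent`.
#' @export
overlap_genes <- function(protein_kept, rna_kept, annot) {
  ann <- annot_lookup(annot, rna_kept)
  rna_coding <- rna_kept[ann$coding]
  ov <- intersect(protein_kept, rna_coding)
  list(n_protein = length(protein_kept),
       n_rna = length(rna_coding),
       n_overlap = length(ov),
       n_noncoding_removed = length(rna_kept) - length(rna_coding),
       overlap = ov,
       percent = if (length(rna_coding)) funnel_percent(length(ov), length(rna_coding))
                 else 0)
}
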