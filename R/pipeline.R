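#' Preprocess a protein matrix for one analysis arm
#'
#' Convenience wrapper chaining log2 transform, imputation and
#' normalization. The diagnostic arm pairs zero imputation with the chosen
#' normalization; the exploratory arm uses minimum-deterministic imputation.
#'
#' @param m protein `ExpressionMatrix` at linear scale.
#' @param impute `"zero"` or `"min_det"`.
#' @param norm `"quantile"`, `"rlr"` or `"none"`.
#' @param min_det_quantile passed to [impute_missing()].
#' @return normalized `ExpressionMatrix` with the original mask retained.
#' @export
preprocess_protein <- function(m, impute = c("zero", "min_det"),
                               norm = c("quantile", "rlr", "none"),
                               min_det_quantile = 0.01) {
  impute <- match.arg(impute)
  norm <- match.arg(norm)
  assert_em(m, layer = "protein")
  if (m$scale == "linear") m <- em_log2(m)
  imp <- impute_missing(m, method = impute, min_det_quantile = min_det_quantile)
  out <- switch(norm,
                quantile = quantile_normalize(imp),
                rlr = rlr_normalize(imp),
                none = imp)
  attr(out, "impute_method") <- impute
  out
}

#' Single-case diagnostic calls for one sample
#'
#' The diagnostic arm end-to-end: cohort z-scores on the zero-imputed
#' normalized protein matrix and on the VST RNA matrix, patient-vs-HC fold
#' changes, archetype classification, and candidate ranking.
#'
#' @param protein_norm diagnostic-arm protein matrix
#'   (see [preprocess_protein()]).
#' @param rna_vst VST RNA matrix from [vst_rna()] (optional).
#' @param meta a [cohort_meta()].
#' @param case_sample the case to diagnose.
#' @param annot optional [gene_annotation()].
#' @param targeted_only restrict the report to panel genes.
#' @param thr a [diagnostic_thresholds()].
#' @return a `DiagnosticCallSet` (see [rank_candidates()]).
#' @export
diagnose_sample <- function(protein_norm, rna_vst = NULL, meta, case_sample,
                            annot = NULL, targeted_only = FALSE,
                            thr = diagnostic_thresholds()) {
  active <- meta_active_samples(meta)
  zp <- cohort_zscores(protein_norm, samples = intersect(active, em_samples(protein_norm)))
  zr <- if (!is.null(rna_vst)) {
    cohort_zscores(rna_vst, samples = intersect(active, em_samples(rna_vst)))
  }
  hc <- case_vs_hc(protein_norm, meta, case_sample, thr)
  rank_candidates(zp, zr, case_sample, hc_table = hc, annot = annot,
                  targeted_only = targeted_only, thr = thr)
}
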