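#' Diagnostic thresholds
#'
#' `|z| >= z_cut` (inclusive) defines a significant single-case change;
#' `lfc < lfc_cut` (strict) defines an extreme reduction versus healthy
#' controls (log2 fold change below -5 means below 1/32 of the HC mean).
#'
#' @param z_cut positive z threshold (default 2).
#' @param lfc_cut negative log2-fold-change threshold (default -5).
#' @export
diagnostic_thresholds <- function(z_cut = 2, lfc_cut = -5) {
  assert_scalar_number(z_cut, "z_cut", lower = 1e-12)
  if (lfc_cut >= 0) stop("`lfc_cut` must be negative", call. = FALSE)
  structure(list(z_cut = z_cut, lfc_cut = lfc_cut), class = "DiagnosticThresholds")
}

#' Cohort z-scores
#'
#' Standardizes each gene across all non-excluded samples (the case sample
#' included): `z = (x - mean) / sd`, sd with the n-1 denominator. Genes with
#' zero variance get `NA` z-scores (undefined, not 0).
#'
#' @param m a normalized `ExpressionMatrix` (zero-imputed protein for the
#'   diagnostic arm; VST RNA).
#' @param samples samples defining the cohort distribution (default: all).
#' @param leave_one_out if `TRUE`, each sample's z uses mean/sd computed
#'   without that sample.
#' @return numeric z matrix (genes x samples).
#' @export
cohort_zscores <- function(m, samples = NULL, leave_one_out = FALSE) {
  assert_em(m)
  if (!is.null(samples)) m <- em_subset(m, samples = samples)
  v <- m$values
  if (ncol(v) < 3L) stop("z-scores need at least 3 samples", call. = FALSE)
  if (anyNA(v)) stop("cohort_zscores requires a complete (imputed) matrix",
                     call. = FALSE)
  if (!leave_one_out) {
    mu <- rowMeans(v)
    sdv <- apply(v, 1L, stats::sd)
    sdv[sdv == 0] <- NA_real_
    z <- (v - mu) / sdv
  } else {
    n <- ncol(v)
    tot <- rowSums(v); totsq <- rowSums(v^2)
    z <- v
    for (j in seq_len(n)) {
      mu_j <- (tot - v[, j]) / (n - 1)
      var_j <- (totsq - v[, j]^2 - (n - 1) * mu_j^2) / (n - 2)
      sd_j <- sqrt(pmax(var_j, 0))
      sd_j[sd_j == 0] <- NA_real_
      z[, j] <- (v[, j] - mu_j) / sd_j
    }
  }
  z
}

#' Classify the diagnostic archetype of a (gene, sample) z pair
#'
#' With threshold `t = z_cut` (boundary inclusive):
#' * `concordant_down`: protein and mRNA z both <= -t;
#' * `protein_only_down`: protein z <= -t, mRNA z absent (`NA`) or > -t;
#' * `mrna_only_down`: mRNA z <= -t, protein z > -t;
#' * `concordant_up`: both >= +t;
#' * otherwise `none`.
#'
#' Genes not on the RNA panel have absent (not zero) mRNA z.
#'
#' @param z_protein,z_rna numeric vectors (recycled); `z_rna` may be `NA`.
#' @param thr a [diagnostic_thresholds()].
#' @return character vector of archetype labels.
#' @export
classify_archetype <- function(z_protein, z_rna = NA_real_,
                               thr = diagnostic_thresholds()) {
  n <- max(length(z_protein), length(z_rna))
  zp <- rep_len(z_protein, n); zr <- rep_len(z_rna, n)
  t <- thr$z_cut
  out <- rep("none", n)
  p_dn <- !is.na(zp) & zp <= -t
  r_dn <- !is.na(zr) & zr <= -t
  p_up <- !is.na(zp) & zp >= t
  r_up <- !is.na(zr) & zr >= t
  out[p_dn & r_dn] <- "concordant_down"
  out[p_dn & !r_dn] <- "protein_only_down"
  out[!p_dn & r_dn] <- "mrna_only_down"
  out[p_up & r_up] <- "concordant_up"
  out[is.na(zp)] <- NA_character_
  out
}

#' Single case versus healthy controls
#'
#' Per gene: `lfc = case_log2 - mean(HC log2)` and
#' `mean_expr = mean(case and HC log2 values)` — the MA-plot coordinates.
#' Genes missing in the case before imputation carry `case_missing = TRUE`
#' (these form the floor line in the lower left of the MA plot, since the
#' zero-imputed case value is the detection floor). Genes missing in all
#' HCs are excluded with a reason. `lfc_extreme` flags `lfc < lfc_cut`
#' (strict).
#'
#' @param m diagnostic-arm protein matrix (zero-imputed, log2/normalized);
#'   its retained mask supplies pre-imputation missingness.
#' @param meta a [cohort_meta()]; HCs are non-excluded controls.
#' @param case_sample the case's sample id (must not be a control).
#' @param thr a [diagnostic_thresholds()].
#' @return list with `table` (data.frame gene, lfc, mean_expr, case_missing,
#'   lfc_extreme) and `excluded` (genes missing in every HC).
#' @export
case_vs_hc <- function(m, meta, case_sample, thr = diagnostic_thresholds()) {
  assert_em(m, layer = "protein")
  hcs <- meta_active_samples(meta, role = "control")
  if (length(hcs) < 2L) stop("need at least 2 healthy controls", call. = FALSE)
  if (case_sample %in% hcs) stop("case sample is in the control set", call. = FALSE)
  if (!(case_sample %in% em_samples(m))) {
    stop("unknown case sample: ", case_sample, call. = FALSE)
  }
  v <- m$values
  if (anyNA(v)) stop("case_vs_hc expects an imputed matrix", call. = FALSE)
  hc_mask <- m$mask[, hcs, drop = FALSE]
  all_hc_missing <- rowSums(!hc_mask) == 0L
  hc_vals <- v[, hcs, drop = FALSE]
  lfc <- v[, case_sample] - rowMeans(hc_vals)
  mean_expr <- rowMeans(cbind(v[, case_sample], hc_vals))
  tab <- data.frame(
    gene = em_genes(m),
    lfc = lfc,
    mean_expr = mean_expr,
    case_missing = m$mask[, case_sample],
    lfc_extreme = lfc < thr$lfc_cut,
    stringsAsFactors = FALSE, row.names = NULL
  )
  excluded <- tab$gene[all_hc_missing]
  tab <- tab[!all_hc_missing, , drop = FALSE]
  list(table = tab,
       excluded = data.frame(gene = excluded,
                             reason = rep("missing in all HCs", length(excluded)),
                             stringsAsFactors = FALSE))
}

#' Rank candidate disease genes for one case
#'
#' Assembles per-gene diagnostic calls for a case (protein z, mRNA z where
#' the gene is on the RNA panel, LFC vs HCs, archetype, flags) and ranks by
#' protein z ascending with a lexicographic gene-id tie-break. When no gene
#' reaches `|z| >= z_cut`, the status is `"no candidate"` and the table is
#' empty.
#'
#' @param z_protein,z_rna z matrices from [cohort_zscores()] (`z_rna` may be
#'   `NULL` or cover fewer genes).
#' @param case_sample sample id.
#' @param hc_table output of [case_vs_hc()] for this case (optional; adds
#'   lfc columns).
#' @param annot a [gene_annotation()]; with `targeted_only = TRUE` only panel
#'   genes are reported.
#' @param targeted_only restrict to targeted-panel genes.
#' @param thr a [diagnostic_thresholds()].
#' @return list of class `DiagnosticCallSet`: `case`, `status`
#'   (`"candidates"` / `"no candidate"`), `calls` data.frame.
#' @export
rank_candidates <- function(z_protein, z_rna = NULL, case_sample,
                            hc_table = NULL, annot = NULL,
                            targeted_only = FALSE,
                            thr = diagnostic_thresholds()) {
  if (!(case_sample %in% colnames(z_protein))) {
    stop("case sample not in z matrix: ", case_sample, call. = FALSE)
  }
  genes <- rownames(z_protein)
  zp <- z_protein[, case_sample]
  zr <- rep(NA_real_, length(genes))
  if (!is.null(z_rna) && case_sample %in% colnames(z_rna)) {
    idx <- match(genes, rownames(z_rna))
    zr[!is.na(idx)] <- z_rna[idx[!is.na(idx)], case_sample]
  }
  calls <- data.frame(
    gene = genes, sample = case_sample, z_protein = zp, z_rna = zr,
    archetype = classify_archetype(zp, zr, thr),
    z_significant = !is.na(zp) & abs(zp) >= thr$z_cut,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(hc_table)) {
    tab <- if (is.list(hc_table) && !is.data.frame(hc_table)) hc_table$table else hc_table
    idx <- match(calls$gene, tab$gene)
    calls$lfc_vs_hc <- tab$lfc[idx]
    calls$mean_expr <- tab$mean_expr[idx]
    calls$lfc_extreme <- tab$lfc_extreme[idx]
  }
  if (targeted_only) {
    if (is.null(annot)) stop("targeted_only needs an annotation", call. = FALSE)
    ann <- annot_lookup(annot, calls$gene)
    calls <- calls[ann$targeted_panel, , drop = FALSE]
  }
  calls <- calls[!is.na(calls$z_protein), , drop = FALSE]
  ord <- order(calls$z_protein, calls$gene, method = "radix")
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  if (!any(calls$z_significant)) {
    return(structure(list(case = case_sample, status = "no candidate",
                          calls = calls[0, , drop = FALSE]),
                     class = "DiagnosticCallSet"))
  }
  structure(list(case = case_sample, status = "candidates", calls = calls),
            class = "DiagnosticCallSet")
}
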