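#' Per-gene protein-mRNA Spearman correlation
#'
#' For every gene present on both layers, the Spearman rank correlation of
#' its protein and mRNA profiles across the shared samples (average ranks
#' for ties). Genes with zero variance on either layer are excluded with a
#' reason — their rank correlation is undefined. Run on the exploratory-arm
#' protein matrix (min_det imputation); zero-imputation would create
#' artifactual ties at the floor.
#'
#' @param protein_m,rna_m `ExpressionMatrix` objects on comparable (log2-ish)
#'   scales.
#' @param samples shared samples to use (default: intersection; >= 5 needed).
#' @param annot optional [gene_annotation()] to tag records with their cell
#'   marker.
#' @return list with `records` (data.frame gene, rho, n_pairs, strength,
#'   cell_marker) and `excluded` (gene, reason).
#' @export
spearman_per_gene <- function(protein_m, rna_m, samples = NULL, annot = NULL) {
  assert_em(protein_m); assert_em(rna_m)
  if (is.null(samples)) {
    samples <- intersect(em_samples(protein_m), em_samples(rna_m))
  }
  if (length(samples) < 5L) {
    stop("need at least 5 shared samples for correlation", call. = FALSE)
  }
  genes <- intersect(em_genes(protein_m), em_genes(rna_m))
  pv <- em_subset(protein_m, genes, samples)$values
  rv <- em_subset(rna_m, genes, samples)$values
  rho <- rep(NA_real_, length(genes))
  reason <- rep(NA_character_, length(genes))
  for (i in seq_along(genes)) {
    x <- pv[i, ]; y <- rv[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      reason[i] <- if (stats::sd(x) == 0) "zero variance (protein)" else "zero variance (rna)"
      next
    }
    rho[i] <- stats::cor(x, y, method = "spearman")
  }
  ok <- is.na(reason)
  marker <- if (is.null(annot)) rep("none", length(genes)) else
    annot_lookup(annot, genes)$cell_marker
  records <- data.frame(
    gene = genes[ok], rho = rho[ok],
    n_pairs = rep(length(samples), sum(ok)),
    strength = as.character(bin_strength(rho[ok])),
    cell_marker = marker[ok],
    stringsAsFactors = FALSE, row.names = NULL
  )
  excluded <- data.frame(gene = genes[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  list(records = records, excluded = excluded)
}

#' Bin a correlation coefficient by strength
#'
#' On `|rho|`, left-inclusive bins: `>= 0.7` strong, `[0.4, 0.7)` moderate,
#' `[0.2, 0.4)` weak, `< 0.2` none.
#'
#' @param rho numeric vector of correlation coefficients in `[-1, 1]`.
#' @return character vector of `"strong"`, `"moderate"`, `"weak"`, `"none"`.
#' @export
bin_strength <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) stop("|rho| must be <= 1", call. = FALSE)
  a <- abs(rho)
  out <- ifelse(a >= 0.7, "strong",
                ifelse(a >= 0.4, "moderate",
                       ifelse(a >= 0.2, "weak", "none")))
  out[is.na(rho)] <- NA_character_
  out
}

#' Summarize a set of correlation records
#'
#' Median and interquartile range (type-7 linear-interpolation quartiles)
#' over defined coefficients, the strength-bin histogram, and per-marker
#' group medians (b_cell / t_cell / none).
#'
#' @param records the `records` data.frame from [spearman_per_gene()] (or any
#'   data.frame with `rho`, `strength`, optionally `cell_marker`).
#' @return list with `n`, `median`, `iqr` (lower, upper), `strength_counts`,
#'   `group_medians`.
#' @export
summarize_correlations <- function(records) {
  if (nrow(records) < 1L) stop("need at least one correlation record", call. = FALSE)
  rho <- records$rho
  q <- stats::quantile(rho, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  counts <- table(factor(records$strength,
                         levels = c("strong", "moderate", "weak", "none")))
  groups <- if ("cell_marker" %in% names(records)) records$cell_marker
            else rep("none", nrow(records))
  gm <- vapply(split(rho, groups), stats::median, numeric(1))
  list(n = nrow(records),
       median = q[2L],
       iqr = c(lower = q[1L], upper = q[3L]),
       strength_counts = as.list(counts),
       group_medians = as.list(gm))
}
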