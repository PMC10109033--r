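#' Moderated two-group differential expression
#'
#' Per-gene log2 fold change (first contrast level minus second) with an
#' empirical-Bayes moderated t-statistic: the prior degrees of freedom `d0`
#' and prior variance `s0^2` are estimated by moment matching on the log
#' sample variances (Smyth-style: `Var(log s^2) = trigamma(d/2) +
#' trigamma(d0/2)`, solved with a Newton trigamma inverse), the posterior
#' variance is `(d0 s0^2 + d s^2) / (d0 + d)`, and p-values come from a t
#' distribution with `d0 + d` degrees of freedom. A degenerate fit
#' (`d0 -> Inf`, i.e. observed log-variance spread no larger than the
#' sampling noise) is capped at `d0 = 10 d`.
#'
#' @param m a complete exploratory-arm `ExpressionMatrix` (log2-ish values).
#' @param groups per-sample labels, named by sample id or in matrix column
#'   order; exactly two distinct labels, each with >= 2 samples.
#' @param contrast character(2): lfc and t are `contrast[1] - contrast[2]`
#'   (default: deficient minus other when those labels are present, else the
#'   two labels sorted).
#' @param prior_df override the estimated `d0` (0 gives the ordinary
#'   two-sample equal-variance t-test).
#' @return data.frame (gene, lfc, t_moderated, p, adj_p, significant_down)
#'   with attributes `prior_df` and `prior_var`. `significant_down` applies
#'   the strict p < 0.05, lfc < -1.5 rule.
#' @export
moderated_dea <- function(m, groups, contrast = NULL, prior_df = NULL) {
  assert_em(m)
  v <- m$values
  if (anyNA(v)) stop("moderated_dea requires a complete matrix", call. = FALSE)
  if (!is.null(names(groups))) groups <- groups[em_samples(m)]
  groups <- as.character(groups)
  if (length(groups) != ncol(v)) stop("one group label per sample required", call. = FALSE)
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  if (is.null(contrast)) {
    contrast <- if (all(c("deficient", "other") %in% lev)) c("deficient", "other") else lev
  }
  if (!setequal(contrast, lev)) stop("contrast must name the two group labels", call. = FALSE)
  i1 <- groups == contrast[1L]; i2 <- groups == contrast[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples", call. = FALSE)

  m1 <- rowMeans(v[, i1, drop = FALSE]); m2 <- rowMeans(v[, i2, drop = FALSE])
  lfc <- m1 - m2
  ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2) else 0
  }
  if (!is.finite(d0) || d0 > 10 * d) {
    d0 <- 10 * d
    s02 <- exp(mean(log(s2[s2 > 0]))) # refit scale at the capped df
  }
  s2_post <- if (d0 > 0) (d0 * s02 + d * s2) / (d0 + d) else s2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- lfc / se
  p <- 2 * stats::pt(-abs(t_mod), df = d0 + d)
  res <- data.frame(
    gene = em_genes(m), lfc = lfc, t_moderated = t_mod, p = p,
    adj_p = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$significant_down <- res$p < 0.05 & res$lfc < -1.5
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  attr(res, "residual_df") <- d
  res
}

# moment-matching fit of the scaled inverse-chi-square variance prior
# on z = log(s^2): Var(z) = trigamma(d/2) + trigamma(d0/2)
fit_variance_prior <- function(s2, d) {
  pos <- s2 > 0
  if (sum(pos) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2[pos])
  excess <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) return(list(d0 = Inf, s02 = exp(mean(z))))
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(y) = x, x > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Significantly downregulated genes
#'
#' Strict thresholds on both criteria (`p < p_cut` and `lfc < lfc_cut`);
#' boundary values are excluded. Deterministic order: p ascending, then
#' gene id.
#'
#' @param results output of [moderated_dea()].
#' @param p_cut p-value threshold (default 0.05, raw p; set
#'   `use_adjusted = TRUE` to threshold `adj_p` instead).
#' @param lfc_cut log2-fold-change threshold (default -1.5).
#' @param use_adjusted threshold BH-adjusted p-values.
#' @return character vector of gene ids.
#' @export
significant_down <- function(results, p_cut = 0.05, lfc_cut = -1.5,
                             use_adjusted = FALSE) {
  p <- if (use_adjusted) results$adj_p else results$p
  sel <- p < p_cut & results$lfc < lfc_cut
  sub <- results[sel, , drop = FALSE]
  sub$gene[order(if (use_adjusted) sub$adj_p else sub$p, sub$gene, method = "radix")]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene list and
#' each set, both intersected with the universe of tested genes; BH
#' adjustment across all tested sets; `significant` means `adj_p < 0.01`.
#' The full table is returned ordered by adjusted then raw p, with the top
#' `top_n` rows in `attr(, "top")`.
#'
#' @param gene_list character vector of hit genes (subset of `universe`).
#' @param gene_sets a [read_gmt()] collection (or named list of gene id
#'   vectors).
#' @param universe all genes tested (the DEA gene universe, not the genome).
#' @param top_n rows to surface in the `top` attribute (default 10).
#' @param adj_p_cut significance cutoff on adjusted p (default 0.01).
#' @return data.frame (set, set_size, overlap, universe_size, draw_size, p,
#'   adj_p, significant); zero rows for an empty gene list.
#' @export
enrich <- function(gene_list, gene_sets, universe, top_n = 10L, adj_p_cut = 0.01) {
  universe <- unique(universe)
  gene_list <- intersect(unique(gene_list), universe)
  sets <- lapply(gene_sets, intersect, universe)
  sets <- sets[vapply(sets, length, 1L) > 0L]
  if (length(gene_list) == 0L || length(sets) == 0L) {
    out <- data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), universe_size = integer(0),
                      draw_size = integer(0), p = numeric(0),
                      adj_p = numeric(0), significant = logical(0))
    attr(out, "top") <- out
    return(out)
  }
  N <- length(universe); k <- length(gene_list)
  tab <- data.frame(
    set = names(sets),
    set_size = vapply(sets, length, 1L),
    overlap = vapply(sets, function(s) length(intersect(s, gene_list)), 1L),
    universe_size = N, draw_size = k,
    stringsAsFactors = FALSE, row.names = NULL
  )
  # P(X >= overlap), X ~ Hypergeom(set_size successes, N - set_size, k drawn)
  tab$p <- stats::phyper(tab$overlap - 1L, tab$set_size, N - tab$set_size, k,
                         lower.tail = FALSE)
  tab$adj_p <- bh_adjust(tab$p)
  tab$significant <- tab$adj_p < adj_p_cut
  tab <- tab[order(tab$adj_p, tab$p, tab$set, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "top") <- utils::head(tab, top_n)
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control with monotonicity enforcement
#' (`cummin` over descending p), order-preserving and bounded by 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (n == 0L) return(out)
  if (n == 1L) { out[ok] <- p[ok]; return(out) }
  ord <- ok[order(p[ok], decreasing = TRUE)]
  adj <- pmin(1, cummin(n / (n:1) * p[ord]))
  out[ord] <- adj
  out
}
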