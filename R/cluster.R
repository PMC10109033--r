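#' Select marker genes for a cell type
#'
#' Protein layer: candidates annotated for the cell type are ranked by
#' missing-value fraction ascending, then specificity score descending, then
#' gene id, and the top `n_select` (default 3) are taken. RNA layer
#' (target-enriched, no missing values): all candidates passing the
#' specificity criterion are used.
#'
#' @param m an `ExpressionMatrix`.
#' @param annot a [gene_annotation()] carrying `cell_marker` and
#'   `specificity`.
#' @param cell_type `"b_cell"`, `"t_cell"` or `"nk_cell"`.
#' @param n_select markers to select on the protein layer (default 3).
#' @param min_specificity minimum specificity score for RNA-layer selection
#'   (default 0: all annotated candidates).
#' @return list of class `MarkerPanel`: `cell_type`, `candidates`
#'   (data.frame with mv_fraction and specificity), `selected`.
#' @export
select_markers <- function(m, annot, cell_type = c("b_cell", "t_cell", "nk_cell"),
                           n_select = 3L, min_specificity = 0) {
  assert_em(m)
  cell_type <- match.arg(cell_type)
  ann <- annot_lookup(annot, em_genes(m))
  cand_ids <- ann$gene[ann$cell_marker == cell_type]
  if (length(cand_ids) == 0L) {
    stop(sprintf("no %s marker candidates present in the matrix", cell_type),
         call. = FALSE)
  }
  cand <- data.frame(
    gene = cand_ids,
    mv_fraction = rowMeans(m$mask[cand_ids, , drop = FALSE]),
    specificity = ann$specificity[match(cand_ids, ann$gene)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (m$layer == "rna") {
    sel <- cand$gene[cand$specificity >= min_specificity]
    sel <- sel[order(sel, method = "radix")]
  } else {
    if (nrow(cand) < n_select) {
      stop(sprintf("only %d %s candidates available (%s); need %d",
                   nrow(cand), cell_type, paste(cand$gene, collapse = ", "),
                   n_select), call. = FALSE)
    }
    ord <- order(cand$mv_fraction, -cand$specificity, cand$gene, method = "radix")
    sel <- cand$gene[ord][seq_len(n_select)]
  }
  structure(list(cell_type = cell_type, candidates = cand, selected = sel),
            class = "MarkerPanel")
}

# k-means++ seeding (Arthur & Vassilvitskii) over rows of x
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

# best-of-restarts Lloyd k-means with k-means++ seeding
kmeans_pp <- function(x, k, restarts = 50L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- kmeanspp_centers(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = ctr, iter.max = 100L, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' k-means clustering of samples on a marker panel
#'
#' Panel genes are z-normalized across samples (n-1 sd); samples are
#' clustered in that marker z-space by k-means with k-means++ seeding and 50
#' restarts under a fixed seed. At `k = 2` the cluster with the lower mean
#' marker z is labeled `deficient`, the other `other`. Constant panel genes
#' are dropped with a warning; an all-constant panel is an error.
#'
#' @param m exploratory-arm `ExpressionMatrix` (complete values).
#' @param panel a [select_markers()] panel (or character vector of genes).
#' @param k number of clusters (>= 2; default 2, required for the
#'   deficient/other labeling).
#' @param seed RNG seed for the restarts.
#' @param restarts number of k-means++ restarts (default 50).
#' @return list of class `ClusterResult`: `panel`, `z` (panel z matrix),
#'   `assignment` (named `"deficient"`/`"other"` at k = 2, else cluster ids),
#'   `deficient_samples`, `tot_withinss`, `k`, `seed`.
#' @export
cluster_samples <- function(m, panel, k = 2L, seed = 1L, restarts = 50L) {
  assert_em(m)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  genes <- if (inherits(panel, "MarkerPanel")) panel$selected else panel
  v <- em_subset(m, genes = genes)$values
  if (anyNA(v)) stop("cluster_samples requires a complete (imputed) matrix",
                     call. = FALSE)
  sdv <- apply(v, 1L, stats::sd)
  if (any(sdv == 0)) {
    warning("dropping constant panel gene(s): ",
            paste(genes[sdv == 0], collapse = ", "), call. = FALSE)
    v <- v[sdv > 0, , drop = FALSE]
    if (nrow(v) == 0L) stop("all panel genes constant across samples", call. = FALSE)
  }
  z <- (v - rowMeans(v)) / apply(v, 1L, stats::sd)
  x <- t(z)  # samples in rows, ordered deterministically
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  set.seed(seed)
  fit <- kmeans_pp(x, k, restarts = restarts)
  cl <- stats::setNames(fit$cluster, rownames(x))
  cl <- cl[em_samples(m)]  # restore matrix order
  if (k == 2L) {
    mean_z <- vapply(1:2, function(i) mean(x[fit$cluster == i, , drop = FALSE]),
                     numeric(1))
    deficient_id <- which.min(mean_z)
    assignment <- ifelse(cl == deficient_id, "deficient", "other")
    names(assignment) <- names(cl)
  } else {
    assignment <- cl
  }
  structure(list(
    panel = if (inherits(panel, "MarkerPanel")) panel else
      structure(list(cell_type = NA, candidates = NULL, selected = genes),
                class = "MarkerPanel"),
    z = z,
    assignment = assignment,
    deficient_samples = if (k == 2L) names(assignment)[assignment == "deficient"]
                        else character(0),
    tot_withinss = fit$tot.withinss,
    k = k, seed = seed
  ), class = "ClusterResult")
}

#' Within-cluster sum-of-squares curve and elbow point
#'
#' Runs [cluster_samples()]'s k-means engine over `k_range` and reports the
#' total within-cluster SS per k. The elbow is the k maximizing the discrete
#' second difference of the curve (ties broken toward smaller k). When the
#' maximum curvature is small relative to the total SS drop (< 10%), the
#' curve is near-linear and the elbow carries `low_confidence = TRUE`.
#'
#' @param m,panel,seed,restarts as in [cluster_samples()].
#' @param k_range candidate k values (must lie in `[1, n_samples)`).
#' @return list with `k`, `withinss`, `elbow_k`, `second_diff`,
#'   `low_confidence`.
#' @export
elbow_curve <- function(m, panel, k_range = 1:8, seed = 1L, restarts = 50L) {
  assert_em(m)
  genes <- if (inherits(panel, "MarkerPanel")) panel$selected else panel
  v <- em_subset(m, genes = genes)$values
  sdv <- apply(v, 1L, stats::sd)
  v <- v[sdv > 0, , drop = FALSE]
  z <- (v - rowMeans(v)) / apply(v, 1L, stats::sd)
  x <- t(z)
  x <- x[order(rownames(x), method = "radix"), , drop = FALSE]
  if (min(k_range) < 1L || max(k_range) >= nrow(x)) {
    stop("k_range must lie within [1, n_samples)", call. = FALSE)
  }
  set.seed(seed)
  ss <- vapply(k_range, function(k) {
    if (k == 1L) sum(scale(x, scale = FALSE)^2)
    else kmeans_pp(x, k, restarts = restarts)$tot.withinss
  }, numeric(1))
  elbow <- elbow_from_ss(ss, k_range)
  c(list(k = k_range, withinss = ss), elbow)
}

# elbow = argmax of second difference; ties -> smaller k
elbow_from_ss <- function(ss, k_range = seq_along(ss)) {
  if (length(ss) < 3L) {
    return(list(elbow_k = k_range[1L], second_diff = numeric(0),
                low_confidence = TRUE))
  }
  inner <- 2:(length(ss) - 1L)
  d2 <- ss[inner - 1L] - 2 * ss[inner] + ss[inner + 1L]
  best <- inner[which.max(d2)]  # which.max takes the first = smallest k on ties
  total_drop <- ss[1L] - ss[length(ss)]
  list(elbow_k = k_range[best],
       second_diff = stats::setNames(d2, k_range[inner]),
       low_confidence = !is.finite(total_drop) || total_drop <= 0 ||
         max(d2) < 0.1 * total_drop)
}

#' Agreement between two layers' deficient clusters
#'
#' @param result_a,result_b `ClusterResult`s over the same sample universe
#'   (conventionally protein and RNA).
#' @return list with set sizes, `intersection`, `only_a`, `only_b`,
#'   `jaccard`, and `containment` = |A intersect B| / |A|.
#' @export
compare_layers <- function(result_a, result_b) {
  sa <- names(result_a$assignment); sb <- names(result_b$assignment)
  if (!setequal(sa, sb)) stop("cluster results cover different samples", call. = FALSE)
  A <- result_a$deficient_samples
  B <- result_b$deficient_samples
  inter <- intersect(A, B); uni <- union(A, B)
  list(n_a = length(A), n_b = length(B),
       intersection = inter,
       only_a = setdiff(A, B), only_b = setdiff(B, A),
       jaccard = if (length(uni)) length(inter) / length(uni) else 1,
       containment = if (length(A)) length(inter) / length(A) else NA_real_)
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two partitions agree (same/different
#' cluster); used to score cluster recovery against planted truth.
#'
#' @param a,b equal-length cluster label vectors (matched by name when both
#'   are named).
#' @return the Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
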