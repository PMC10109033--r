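#' Expression matrix with an explicit missingness mask
#'
#' The central container of the package: a genes x samples numeric matrix
#' plus a boolean mask recording which cells are missing. The mask is carried
#' through imputation as provenance, so downstream stages (e.g. the MA plot
#' floor line, marker selection by missing-value fraction) can always tell an
#' observed value from an imputed one.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Missing cells are `NA`.
#' @param layer `"protein"` or `"rna"`.
#' @param scale one of `"linear"`, `"log2"`, `"normalized"`, `"vst"`.
#'   Protein intensities enter on the linear scale; the `rna` layer at
#'   `scale = "linear"` must hold non-negative integer counts.
#' @param mask logical matrix of the same dimension; `TRUE` marks a missing
#'   cell. Defaults to `is.na(values)`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, layer = c("protein", "rna"),
                              scale = c("linear", "log2", "normalized", "vst"),
                              mask = NULL) {
  layer <- match.arg(layer)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate gene id: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop(sprintf("duplicate sample id: '%s'", dup), call. = FALSE)
  }
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix matching `values`", call. = FALSE)
  }
  dimnames(mask) <- dimnames(values)
  obs <- values[!mask]
  if (scale == "linear") {
    if (any(obs < 0, na.rm = TRUE)) {
      stop("linear-scale values must be non-negative", call. = FALSE)
    }
    if (layer == "rna" && any(obs != floor(obs), na.rm = TRUE)) {
      stop("rna layer at linear scale must contain integer counts", call. = FALSE)
    }
  }
  structure(
    list(values = values, mask = mask, layer = layer, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s, %s]: %d genes x %d samples, %.1f%% missing\n",
              x$layer, x$scale, nrow(x$values), ncol(x$values),
              100 * mean(x$mask)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
em_genes <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
em_samples <- function(m) colnames(m$values)

#' @rdname expression_matrix
#' @export
em_values <- function(m) m$values

#' @rdname expression_matrix
#' @export
em_mask <- function(m) m$mask

is_em <- function(m) inherits(m, "ExpressionMatrix")

assert_em <- function(m, layer = NULL, scale = NULL) {
  if (!is_em(m)) stop("expected an ExpressionMatrix", call. = FALSE)
  if (!is.null(layer) && !(m$layer %in% layer)) {
    stop(sprintf("expected layer %s, got '%s'",
                 paste(sQuote(layer), collapse = " or "), m$layer),
         call. = FALSE)
  }
  if (!is.null(scale) && !(m$scale %in% scale)) {
    stop(sprintf("expected scale %s, got '%s'",
                 paste(sQuote(scale), collapse = " or "), m$scale),
         call. = FALSE)
  }
  invisible(m)
}

#' Subset an expression matrix by gene and/or sample ids
#'
#' @param m an `ExpressionMatrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return the subsetted `ExpressionMatrix`.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  assert_em(m)
  if (is.null(genes)) genes <- em_genes(m)
  if (is.null(samples)) samples <- em_samples(m)
  missing_g <- setdiff(genes, em_genes(m))
  missing_s <- setdiff(samples, em_samples(m))
  if (length(missing_g)) {
    stop("unknown gene id(s): ", paste(utils::head(missing_g, 3), collapse = ", "),
         call. = FALSE)
  }
  if (length(missing_s)) {
    stop("unknown sample id(s): ", paste(utils::head(missing_s, 3), collapse = ", "),
         call. = FALSE)
  }
  out <- m
  out$values <- m$values[genes, samples, drop = FALSE]
  out$mask <- m$mask[genes, samples, drop = FALSE]
  out
}

#' Log2-transform a linear-scale protein matrix
#'
#' Observed intensities are log2-transformed; missing cells stay `NA`. The
#' `scale` tag guards against double transformation. Zero intensities (allowed
#' as "observed zero" by the reader) are floored at the smallest positive
#' observed intensity to keep the transform finite.
#'
#' @param m an `ExpressionMatrix` at `scale = "linear"`.
#' @return the matrix at `scale = "log2"`.
#' @export
em_log2 <- function(m) {
  assert_em(m, scale = "linear")
  v <- m$values
  obs <- v[!m$mask]
  floor_pos <- min(obs[obs > 0], na.rm = TRUE)
  v[!m$mask & v <= 0] <- floor_pos
  v <- log2(v)
  v[m$mask] <- NA_real_
  out <- m
  out$values <- v
  out$scale <- "log2"
  out
}
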