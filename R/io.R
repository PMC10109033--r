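#' Read an expression matrix from TSV
#'
#' Expected layout: first column = gene id, header row = sample ids, one gene
#' per row. Empty cells and `NA` are recorded as missing in the mask; a
#' literal `0` is an observed zero unless `zero_as_missing = TRUE` (the two
#' are deliberately distinct: zero-imputation must not be conflated with
#' missingness).
#'
#' @param path TSV file path.
#' @param layer `"protein"` or `"rna"`.
#' @param zero_as_missing treat literal 0 as missing (default `FALSE`).
#' @param scale scale tag of the stored values (default `"linear"`).
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, layer = c("protein", "rna"),
                        zero_as_missing = FALSE, scale = "linear") {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nfields <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nfields)) != 1L) {
    bad <- which(nfields != nfields[1L])[1L]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, nfields[bad], nfields[1L]), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("matrix TSV needs a gene-id column plus >=1 sample", call. = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene id in %s: '%s'",
                 basename(path), genes[duplicated(genes)][1L]), call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  vals[vals == ""] <- NA
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(df)[-1L][bad[1, 2]]), call. = FALSE)
  }
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) && scale == "linear") {
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 genes[neg[1, 1]], colnames(df)[-1L][neg[1, 2]]), call. = FALSE)
  }
  rownames(num) <- genes
  colnames(num) <- colnames(df)[-1L]
  mask <- is.na(num)
  if (zero_as_missing) {
    mask <- mask | (!is.na(num) & num == 0)
    num[mask] <- NA_real_
  }
  expression_matrix(num, layer = layer, scale = scale, mask = mask)
}

#' Write an expression matrix to TSV
#'
#' Canonical text form: gene ids in the first column (`gene` header), missing
#' cells written as empty fields, numbers in C `%.10g` format. Writing the
#' result of [read_matrix()] reproduces the canonical file byte-for-byte.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  assert_em(m)
  v <- m$values
  txt <- matrix(sprintf("%.10g", v), nrow = nrow(v))
  txt[m$mask] <- ""
  lines <- c(
    paste(c("gene", colnames(v)), collapse = "\t"),
    paste(rownames(v), apply(txt, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Cohort metadata constructor
#'
#' @param sample sample ids (unique).
#' @param role `"patient"` or `"control"` per sample.
#' @param batch batch label per sample.
#' @param excluded logical exclusion flag (default all `FALSE`).
#' @param exclusion_reason reason text (empty where not excluded).
#' @return a `data.frame` of class `CohortMeta`.
#' @export
cohort_meta <- function(sample, role, batch,
                        excluded = rep(FALSE, length(sample)),
                        exclusion_reason = rep("", length(sample))) {
  stopifnot(!anyDuplicated(sample), all(role %in% c("patient", "control")))
  df <- data.frame(sample = as.character(sample), role = as.character(role),
                   batch = as.character(batch), excluded = as.logical(excluded),
                   exclusion_reason = as.character(exclusion_reason),
                   stringsAsFactors = FALSE)
  class(df) <- c("CohortMeta", "data.frame")
  df
}

#' Active (non-excluded) sample ids of a cohort
#' @param meta a `CohortMeta`.
#' @param role optional role filter (`"patient"` / `"control"`).
#' @export
meta_active_samples <- function(meta, role = NULL) {
  keep <- !meta$excluded
  if (!is.null(role)) keep <- keep & meta$role %in% role
  meta$sample[keep]
}

#' Gene annotation constructor
#'
#' Genes absent from the table default to
#' `{targeted_panel = FALSE, nontarget_category = "none", cell_marker = "none",
#' coding = TRUE}` when looked up via [annot_lookup()].
#'
#' @param gene gene ids (unique).
#' @param targeted_panel logical: member of the targeted RNA panel.
#' @param nontarget_category `"none"`, `"rbc"` or `"plasma"`.
#' @param cell_marker `"none"`, `"b_cell"`, `"t_cell"` or `"nk_cell"`.
#' @param coding logical: protein-coding.
#' @param specificity numeric cell-type specificity score (optional; used by
#'   marker selection).
#' @return a `data.frame` of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene,
                            targeted_panel = rep(FALSE, length(gene)),
                            nontarget_category = rep("none", length(gene)),
                            cell_marker = rep("none", length(gene)),
                            coding = rep(TRUE, length(gene)),
                            specificity = rep(0, length(gene))) {
  stopifnot(!anyDuplicated(gene),
            all(nontarget_category %in% c("none", "rbc", "plasma")),
            all(cell_marker %in% c("none", "b_cell", "t_cell", "nk_cell")))
  df <- data.frame(gene = as.character(gene),
                   targeted_panel = as.logical(targeted_panel),
                   nontarget_category = as.character(nontarget_category),
                   cell_marker = as.character(cell_marker),
                   coding = as.logical(coding),
                   specificity = as.numeric(specificity),
                   stringsAsFactors = FALSE)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Look up annotation rows for a gene set, defaulting absent genes
#' @param annot a `GeneAnnotation`.
#' @param genes gene ids.
#' @export
annot_lookup <- function(annot, genes) {
  idx <- match(genes, annot$gene)
  out <- annot[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  def <- is.na(idx)
  out$gene <- genes
  out$targeted_panel[def] <- FALSE
  out$nontarget_category[def] <- "none"
  out$cell_marker[def] <- "none"
  out$coding[def] <- TRUE
  out$specificity[def] <- 0
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, tab-separated `id`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (class `GeneSetCollection`) with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: need id, description, >=1 gene", bad[1L]),
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a named list of results as pretty JSON
#'
#' @param results a (possibly nested) list of results.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

# metadata / annotation TSV round trip ---------------------------------------

#' @rdname cohort_meta
#' @param meta,path write `meta` to TSV / read it back.
#' @export
write_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_meta
#' @export
read_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  cohort_meta(df$sample, df$role, df$batch, df$excluded, df$exclusion_reason)
}

#' @rdname gene_annotation
#' @param annot,path write `annot` to TSV / read it back.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname gene_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  gene_annotation(df$gene, df$targeted_panel, df$nontarget_category,
                  df$cell_marker, df$coding, df$specificity)
}
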