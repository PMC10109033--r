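#' Simulation configuration
#'
#' Defines the statistical world the analysis assumes: log2-normal protein
#' intensities with batch shifts, abundance-dependent left-censored dropout
#' (logistic in log2 abundance), negative-binomial targeted RNA counts with
#' library-size variation, a shared latent abundance inducing a tunable
#' per-gene protein-mRNA correlation, and latent per-sample B-/T-cell levels
#' that drive marker-gene abundance on both layers.
#'
#' Defaults mirror the desk-scale cohort used throughout the test suite:
#' 63 patients + 6 healthy controls across 3 patient batches, 2000 protein
#' genes of which 500 are on the targeted RNA panel.
#'
#' @param n_patients,n_controls cohort sizes (controls >= 2).
#' @param n_genes_protein number of protein genes.
#' @param n_genes_targeted targeted-panel size (subset of protein genes).
#' @param n_batches number of patient batches.
#' @param batch_shift_sd sd of per-batch log2 shifts.
#' @param base_mean_log2,gene_sd_log2 distribution of per-gene mean log2
#'   intensity.
#' @param noise_sd_log2 within-gene biological/technical sd (log2).
#' @param censor_midpoint log2 abundance at which dropout probability is 0.5.
#' @param censor_slope logistic steepness of dropout (1/log2 units; > 0).
#' @param rna_dispersion negative-binomial dispersion of counts (> 0).
#' @param libsize_sd_log sd of log library-size factors.
#' @param rna_mean_log2 mean log2 expected count at library factor 1.
#' @param rho_marker latent protein-mRNA correlation of cell-marker genes.
#' @param rho_default latent correlation of non-marker genes.
#' @param cell_sd sd of the latent per-sample B-/T-cell level (log2).
#' @param rna_cell_gain multiplier on the cell-level effect for the RNA
#'   layer (>= 1 reproduces the "RNA effect >= protein effect" regime).
#' @param n_b_markers,n_t_markers marker genes per cell type (on the panel).
#' @param n_nontarget number of high-abundance RBC/plasma background genes
#'   (off the panel).
#' @param nontarget_shift_log2 abundance bonus of nontarget genes.
#' @param n_noncoding noncoding genes on the RNA panel.
#' @param seed integer RNG seed.
#' @return a validated list of class `SimConfig`.
#' @export
sim_config <- function(n_patients = 63, n_controls = 6,
                       n_genes_protein = 2000, n_genes_targeted = 500,
                       n_batches = 3, batch_shift_sd = 0.3,
                       base_mean_log2 = 20, gene_sd_log2 = 2,
                       noise_sd_log2 = 0.6,
                       censor_midpoint = 16, censor_slope = 3,
                       rna_dispersion = 0.1, libsize_sd_log = 0.2,
                       rna_mean_log2 = 8,
                       rho_marker = 0.85, rho_default = 0.3,
                       cell_sd = 0.5, rna_cell_gain = 1,
                       n_b_markers = 10, n_t_markers = 13,
                       n_nontarget = 100, nontarget_shift_log2 = 4,
                       n_noncoding = 3, seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    n_controls = assert_count(n_controls, "n_controls", min = 2L),
    n_genes_protein = assert_count(n_genes_protein, "n_genes_protein"),
    n_genes_targeted = assert_count(n_genes_targeted, "n_genes_targeted"),
    n_batches = assert_count(n_batches, "n_batches"),
    batch_shift_sd = assert_scalar_number(batch_shift_sd, "batch_shift_sd", 0),
    base_mean_log2 = assert_scalar_number(base_mean_log2, "base_mean_log2"),
    gene_sd_log2 = assert_scalar_number(gene_sd_log2, "gene_sd_log2", 0),
    noise_sd_log2 = assert_scalar_number(noise_sd_log2, "noise_sd_log2", 0),
    censor_midpoint = assert_scalar_number(censor_midpoint, "censor_midpoint"),
    censor_slope = assert_scalar_number(censor_slope, "censor_slope", 1e-12),
    rna_dispersion = assert_scalar_number(rna_dispersion, "rna_dispersion", 1e-12),
    libsize_sd_log = assert_scalar_number(libsize_sd_log, "libsize_sd_log", 0),
    rna_mean_log2 = assert_scalar_number(rna_mean_log2, "rna_mean_log2"),
    rho_marker = assert_scalar_number(rho_marker, "rho_marker", -1, 1),
    rho_default = assert_scalar_number(rho_default, "rho_default", -1, 1),
    cell_sd = assert_scalar_number(cell_sd, "cell_sd", 0),
    rna_cell_gain = assert_scalar_number(rna_cell_gain, "rna_cell_gain", 0),
    n_b_markers = assert_count(n_b_markers, "n_b_markers", min = 0L),
    n_t_markers = assert_count(n_t_markers, "n_t_markers", min = 0L),
    n_nontarget = assert_count(n_nontarget, "n_nontarget", min = 0L),
    nontarget_shift_log2 = assert_scalar_number(nontarget_shift_log2,
                                                "nontarget_shift_log2"),
    n_noncoding = assert_count(n_noncoding, "n_noncoding", min = 0L),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_genes_targeted > cfg$n_genes_protein) {
    stop("n_genes_targeted must not exceed n_genes_protein", call. = FALSE)
  }
  if (cfg$n_b_markers + cfg$n_t_markers + cfg$n_noncoding > cfg$n_genes_targeted) {
    stop("markers + noncoding exceed the targeted panel size", call. = FALSE)
  }
  if (cfg$n_nontarget > cfg$n_genes_protein - cfg$n_genes_targeted) {
    stop("n_nontarget exceeds the off-panel gene count", call. = FALSE)
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Planted-effect specification
#'
#' The two diagnostic archetypes (`concordant_down`: protein and mRNA both
#' reduced; `protein_only_down`: protein reduced, mRNA intact) plus their
#' mirror (`mrna_only_down`), planted immune-cell deficiencies
#' (`b_cell_deficient`, `t_cell_deficient`) which lower the sample's latent
#' cell level and hence all marker genes on both layers, and
#' `global_dropout_outlier`, which raises a sample's censoring midpoint by
#' `effect_log2` (the stand-in for excluded high-missingness samples).
#'
#' @param kind one of the six kinds above.
#' @param sample target sample id.
#' @param gene target gene id (single-gene kinds only).
#' @param effect_log2 log2-fold reduction (> 0).
#' @return a list of class `PlantSpec`.
#' @export
plant_spec <- function(kind = c("concordant_down", "protein_only_down",
                                "mrna_only_down", "b_cell_deficient",
                                "t_cell_deficient", "global_dropout_outlier"),
                       sample, gene = NULL, effect_log2 = 5) {
  kind <- match.arg(kind)
  assert_scalar_number(effect_log2, "effect_log2", lower = 1e-12)
  single_gene <- kind %in% c("concordant_down", "protein_only_down", "mrna_only_down")
  if (single_gene && (is.null(gene) || length(gene) != 1L)) {
    stop(sprintf("kind '%s' requires exactly one target gene", kind), call. = FALSE)
  }
  if (!single_gene && !is.null(gene)) {
    stop(sprintf("kind '%s' takes no target gene", kind), call. = FALSE)
  }
  structure(list(kind = kind, sample = as.character(sample),
                 gene = if (single_gene) as.character(gene) else NULL,
                 effect_log2 = effect_log2),
            class = "PlantSpec")
}

# layers a single-gene plant touches (for duplicate detection)
plant_layers <- function(kind) {
  switch(kind,
         concordant_down = c("protein", "rna"),
         protein_only_down = "protein",
         mrna_only_down = "rna",
         character(0))
}

#' Simulate a proteome + targeted-RNA cohort with ground truth
#'
#' Model, per gene g and sample s (all on log2 scale):
#' \deqn{a_{gs} = m_g + b_{batch(s)} + \gamma_g c_s + \sigma(\rho_g T_{gs} +
#'   \sqrt{1-\rho_g^2}\,e_{gs})}
#' with gene mean `m_g ~ N(base_mean_log2, gene_sd_log2)`, batch shift
#' `b ~ N(0, batch_shift_sd)`, latent cell level `c_s ~ N(0, cell_sd)`
#' entering only marker genes, shared latent `T` and protein-specific noise
#' `e`. The RNA latent reuses `T` directly, so the protein-mRNA correlation
#' of gene g is governed by `rho_g`. Planted effects are subtracted before
#' censoring; protein cells then drop out with probability
#' `plogis((censor_midpoint - a_gs) * censor_slope)`. RNA counts are
#' NB(mu = libsize * 2^latent, size = 1/dispersion).
#'
#' @param config a [sim_config()].
#' @param plants list of [plant_spec()] objects.
#' @return list with elements `protein`, `rna` ([expression_matrix()]s),
#'   `meta` ([cohort_meta()]), `annot` ([gene_annotation()]) and `truth`
#'   (planted effects and all latent parameters).
#' @export
simulate_cohort <- function(config = sim_config(), plants = list()) {
  if (!inherits(config, "SimConfig")) config <- do.call(sim_config, config)
  if (inherits(plants, "PlantSpec")) plants <- list(plants)
  set.seed(config$seed)

  ng <- config$n_genes_protein
  genes <- sprintf("G%05d", seq_len(ng))
  panel <- genes[seq_len(config$n_genes_targeted)]
  samples <- c(sprintf("P%03d", seq_len(config$n_patients)),
               sprintf("C%02d", seq_len(config$n_controls)))
  ns <- length(samples)
  role <- rep(c("patient", "control"), c(config$n_patients, config$n_controls))
  batch <- c(paste0("B", rep_len(seq_len(config$n_batches), config$n_patients)),
             rep("Ctrl", config$n_controls))

  # annotation: markers + noncoding inside the panel, rbc/plasma outside it
  marker <- rep("none", ng)
  b_idx <- seq_len(config$n_b_markers)
  t_idx <- config$n_b_markers + seq_len(config$n_t_markers)
  marker[b_idx] <- "b_cell"
  marker[t_idx] <- "t_cell"
  coding <- rep(TRUE, ng)
  if (config$n_noncoding > 0) {
    nc_idx <- config$n_genes_targeted - seq_len(config$n_noncoding) + 1L
    coding[nc_idx] <- FALSE
  }
  nontarget <- rep("none", ng)
  if (config$n_nontarget > 0) {
    nt_idx <- ng - seq_len(config$n_nontarget) + 1L
    nontarget[nt_idx] <- rep_len(c("rbc", "plasma"), config$n_nontarget)
  }
  specificity <- ifelse(marker == "none", 0, 2 + stats::runif(ng, -0.2, 0.2))

  # validate plants against ids, reject duplicates per (gene, sample, layer)
  seen <- character(0)
  for (p in plants) {
    if (!inherits(p, "PlantSpec")) stop("plants must be plant_spec() objects", call. = FALSE)
    if (!(p$sample %in% samples)) {
      stop(sprintf("plant references unknown sample '%s'", p$sample), call. = FALSE)
    }
    if (!is.null(p$gene)) {
      if (!(p$gene %in% genes)) {
        stop(sprintf("plant references unknown gene '%s'", p$gene), call. = FALSE)
      }
      keys <- paste(p$gene, p$sample, plant_layers(p$kind), sep = "|")
      if (any(keys %in% seen)) {
        stop(sprintf("duplicate plant on gene '%s', sample '%s'", p$gene, p$sample),
             call. = FALSE)
      }
      seen <- c(seen, keys)
    }
  }

  # latent parameters ---------------------------------------------------------
  m_g <- stats::rnorm(ng, config$base_mean_log2, config$gene_sd_log2)
  m_g[nontarget != "none"] <- m_g[nontarget != "none"] + config$nontarget_shift_log2
  batch_levels <- unique(batch)
  b_shift <- stats::setNames(stats::rnorm(length(batch_levels), 0, config$batch_shift_sd),
                             batch_levels)
  rho <- ifelse(marker != "none", config$rho_marker, config$rho_default)
  cell_b <- stats::rnorm(ns, 0, config$cell_sd)
  cell_t <- stats::rnorm(ns, 0, config$cell_sd)
  libsize <- exp(stats::rnorm(ns, 0, config$libsize_sd_log))
  names(cell_b) <- names(cell_t) <- names(libsize) <- samples

  for (p in plants) {
    si <- match(p$sample, samples)
    if (p$kind == "b_cell_deficient") cell_b[si] <- cell_b[si] - p$effect_log2
    if (p$kind == "t_cell_deficient") cell_t[si] <- cell_t[si] - p$effect_log2
  }

  latent_T <- matrix(stats::rnorm(ng * ns), ng, ns)
  noise_p <- matrix(stats::rnorm(ng * ns), ng, ns)

  cell_term <- outer(as.numeric(marker == "b_cell"), cell_b) +
    outer(as.numeric(marker == "t_cell"), cell_t)

  prot_log2 <- matrix(m_g, ng, ns) +
    matrix(b_shift[batch], ng, ns, byrow = TRUE) +
    cell_term +
    config$noise_sd_log2 * (rho * latent_T + sqrt(1 - rho^2) * noise_p)
  rna_log2 <- matrix(m_g - config$base_mean_log2 + config$rna_mean_log2, ng, ns) +
    config$rna_cell_gain * cell_term +
    config$noise_sd_log2 * latent_T

  # planted single-gene effects (before censoring) -----------------------------
  for (p in plants) {
    if (is.null(p$gene)) next
    gi <- match(p$gene, genes); si <- match(p$sample, samples)
    if (p$kind %in% c("concordant_down", "protein_only_down")) {
      prot_log2[gi, si] <- prot_log2[gi, si] - p$effect_log2
    }
    if (p$kind %in% c("concordant_down", "mrna_only_down")) {
      rna_log2[gi, si] <- rna_log2[gi, si] - p$effect_log2
    }
  }

  # left-censored dropout -------------------------------------------------------
  midpoint_s <- rep(config$censor_midpoint, ns)
  names(midpoint_s) <- samples
  for (p in plants) {
    if (p$kind == "global_dropout_outlier") {
      midpoint_s[p$sample] <- midpoint_s[p$sample] + p$effect_log2
    }
  }
  p_miss <- stats::plogis((matrix(midpoint_s, ng, ns, byrow = TRUE) - prot_log2) *
                            config$censor_slope)
  mask <- matrix(stats::runif(ng * ns) < p_miss, ng, ns)

  prot_lin <- 2^prot_log2
  prot_lin[mask] <- NA_real_
  dimnames(prot_lin) <- dimnames(mask) <- list(genes, samples)

  # RNA counts on the panel ------------------------------------------------------
  panel_idx <- seq_len(config$n_genes_targeted)
  mu <- matrix(libsize, length(panel_idx), ns, byrow = TRUE) * 2^rna_log2[panel_idx, , drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$rna_dispersion),
                   nrow = nrow(mu))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(panel, samples)

  protein <- expression_matrix(prot_lin, layer = "protein", scale = "linear",
                               mask = mask)
  rna <- expression_matrix(counts, layer = "rna", scale = "linear")
  meta <- cohort_meta(samples, role, batch)
  annot <- gene_annotation(genes, targeted_panel = genes %in% panel,
                           nontarget_category = nontarget, cell_marker = marker,
                           coding = coding, specificity = specificity)
  truth <- list(
    planted = plants,
    true_gene_corr = stats::setNames(rho, genes),
    censor_midpoint = config$censor_midpoint,
    censor_slope = config$censor_slope,
    sample_censor_midpoint = midpoint_s,
    libsize = libsize,
    batch = stats::setNames(batch, samples),
    cell_level = list(b_cell = cell_b, t_cell = cell_t),
    gene_mean_log2 = stats::setNames(m_g, genes),
    seed = config$seed,
    config = config
  )
  class(truth) <- "SyntheticTruth"
  list(protein = protein, rna = rna, meta = meta, annot = annot, truth = truth)
}

#' Serialize a simulated cohort to a directory of plain-text files
#'
#' Writes `protein.tsv`, `rna.tsv`, `meta.tsv`, `annot.tsv` and `truth.json`;
#' matrices round-trip losslessly through [read_matrix()].
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop("cannot write to directory: ", dir, call. = FALSE)
  }
  write_matrix(sim$protein, file.path(dir, "protein.tsv"))
  write_matrix(sim$rna, file.path(dir, "rna.tsv"))
  write_meta(sim$meta, file.path(dir, "meta.tsv"))
  write_annotation(sim$annot, file.path(dir, "annot.tsv"))
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  truth$planted <- lapply(truth$planted, unclass)
  jsonlite::write_json(lapply(unclass(truth), function(x) x), # drop classes
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#' @param dir fixture directory.
#' @return list with `protein`, `rna`, `meta`, `annot`, `truth`.
#' @export
read_fixture <- function(dir) {
  list(protein = read_matrix(file.path(dir, "protein.tsv"), layer = "protein"),
       rna = read_matrix(file.path(dir, "rna.tsv"), layer = "rna"),
       meta = read_meta(file.path(dir, "meta.tsv")),
       annot = read_annotation(file.path(dir, "annot.tsv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
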