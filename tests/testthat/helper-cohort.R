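# Shared fixtures: all simulated in code at test time.

# A small, fast cohort; override any sim_config field via ...
small_cfg <- function(seed = 1L, ...) {
  args <- list(n_patients = 20, n_controls = 4, n_genes_protein = 300,
               n_genes_targeted = 80, n_nontarget = 20, n_b_markers = 5,
               n_t_markers = 5, n_noncoding = 2, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

small_sim <- function(seed = 1L, plants = list(), ...) {
  simulate_cohort(small_cfg(seed = seed, ...), plants)
}

# Bare ExpressionMatrix from a numeric matrix (auto gene/sample names)
make_em <- function(v, layer = "protein", scale = "log2", mask = NULL) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  expression_matrix(v, layer = layer, scale = scale, mask = mask)
}

# Pick a well-expressed, unmarked panel gene as a disease-gene target.
# Gene means are reproducible for a given seed irrespective of plants, so a
# plant-free run of the same config exposes them.
pick_target_genes <- function(cfg, n = 1L, rng_seed = cfg$seed + 5000L) {
  sim0 <- simulate_cohort(cfg, list())
  np <- cfg$n_genes_targeted
  gm <- sim0$truth$gene_mean_log2[seq_len(np)]
  ok <- names(gm)[gm >= cfg$base_mean_log2 & gm <= cfg$base_mean_log2 + 2 &
                    sim0$annot$cell_marker[seq_len(np)] == "none" &
                    sim0$annot$coding[seq_len(np)]]
  set.seed(rng_seed)
  sample(ok, n)
}

# MCAR generator: logistic censoring made abundance-independent by pushing
# the midpoint far out at a near-zero slope, so p(missing) ~ rate everywhere.
mcar_cfg <- function(seed, rate = 0.03, ...) {
  slope <- 1e-6
  small_cfg(seed = seed, censor_slope = slope,
            censor_midpoint = 20 + stats::qlogis(rate) / slope, ...)
}
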