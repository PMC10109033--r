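test_that("pca_samples matches an eigendecomposition oracle on complete data", {
  set.seed(4)
  v <- matrix(stats::rnorm(200, 16, 2), 20, 10)
  m <- make_em(v)
  pc <- pca_samples(m, n_pc = 3L)
  # oracle: eigendecomposition of the sample covariance of centered columns
  x <- t(v) - colMeans(t(v))[col(t(v))]
  x <- scale(t(v), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(x))
  expect_equal(pc$explained_variance,
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-10)
  for (k in 1:3) {
    expect_equal(unname(abs(pc$scores[, k])), abs(drop(x %*% eig$vectors[, k])),
                 tolerance = 1e-8)
  }
})

test_that("pca_samples handles degenerate and missing-data inputs", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 1, 4))
  rownames(v) <- paste0("g", 1:3)
  pc <- pca_samples(make_em(v))
  expect_equal(pc$scores["s1", ], pc$scores["s2", ], tolerance = 1e-10)
  expect_error(pca_samples(make_em(v[, 1:2])), "3 samples")

  # a global-dropout sample sits farthest from the centroid
  sim <- small_sim(seed = 3, plants = list(
    plant_spec("global_dropout_outlier", "P007", effect_log2 = 4)))
  pc2 <- pca_samples(sim$protein)
  d <- sqrt(rowSums(scale(pc2$scores, scale = FALSE)^2))
  expect_identical(names(which.max(d)), "P007")
})

test_that("flag_outlier_samples: clean nulls, planted recovery, infinite k", {
  # homogeneous cohorts (no batch structure): at most 1 spurious flag in 20
  n_flags <- sum(vapply(1:20, function(s) {
    sim <- small_sim(seed = s, batch_shift_sd = 0)
    length(flag_outlier_samples(qc_report(sim$protein, sim$annot))$dropped)
  }, numeric(1)))
  expect_lte(n_flags, 1)

  # three planted dropout outliers: exactly those flagged
  out <- c("P003", "P011", "P017")
  sim <- small_sim(seed = 2, plants = lapply(out, function(x)
    plant_spec("global_dropout_outlier", x, effect_log2 = 4)))
  fd <- flag_outlier_samples(qc_report(sim$protein, sim$annot))
  expect_setequal(fd$dropped, out)
  expect_setequal(c(fd$kept, fd$dropped), em_samples(sim$protein))

  # k_mad -> infinity flags nothing
  fd_inf <- flag_outlier_samples(qc_report(sim$protein, sim$annot), k_mad = Inf)
  expect_length(fd_inf$dropped, 0L)
})

test_that("mv_regression: exact fit, censoring sign, targeted-only contrast", {
  # perfectly collinear points give R^2 = 1
  v <- matrix(2^16, 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  mask <- matrix(FALSE, 4, 5, dimnames = dimnames(v))
  v[1, 1] <- NA; mask[1, 1] <- TRUE           # s1: 1/4 missing
  v[1:2, 2] <- NA; mask[1:2, 2] <- TRUE       # s2: 2/4 missing
  m <- make_em(v, scale = "linear", mask = mask)
  fit <- suppressWarnings(mv_regression(m, gene_annotation(rownames(v))))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$slope, 0)

  # censored cohort: negative slope, and excluding high-abundance nontarget
  # background raises R^2 (background dominates abundance, not dropout)
  sim <- small_sim(seed = 6, censor_midpoint = 18, n_genes_protein = 600,
                   n_nontarget = 60, nontarget_shift_log2 = 6)
  all_fit <- mv_regression(sim$protein, sim$annot, use_targeted_only = FALSE)
  tgt_fit <- mv_regression(sim$protein, sim$annot, use_targeted_only = TRUE)
  expect_lt(all_fit$slope, 0)
  expect_gt(tgt_fit$r_squared, all_fit$r_squared)

  # zero abundance variance is an undefined fit
  v0 <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_error(mv_regression(make_em(v0, scale = "linear"),
                             gene_annotation(paste0("g", 1:3))),
               "zero variance")
})

test_that("mv_density_summary orders groups under censoring and handles edges", {
  sim <- small_sim(seed = 9, censor_midpoint = 18)
  den <- mv_density_summary(sim$protein)
  expect_lt(den$with_mv$mean, den$without_mv$mean)
  expect_identical(den$note, "")

  # no missing values anywhere: with-MV group empty, informative note
  off <- small_sim(seed = 9, censor_midpoint = -100, censor_slope = 50)
  den2 <- mv_density_summary(off$protein)
  expect_identical(den2$with_mv$n, 0L)
  expect_match(den2$note, "no genes with")

  # single half-missing gene at known abundance: hand-computable means
  v <- rbind(g1 = c(2^10, 2^10, NA, NA), g2 = c(2^12, 2^12, 2^12, 2^12))
  colnames(v) <- paste0("s", 1:4)
  den3 <- mv_density_summary(make_em(v, scale = "linear"))
  expect_equal(den3$with_mv$mean, 10)
  expect_equal(den3$without_mv$mean, 12)
})

test_that("protein MV filter is boundary-inclusive and recount-exact", {
  v <- matrix(2^15, 3, 10, dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:10)))
  mask <- matrix(FALSE, 3, 10, dimnames = dimnames(v))
  mask["gB", 1:2] <- TRUE   # 2/10 = 0.2 -> kept at threshold 0.2
  mask["gC", 1:3] <- TRUE   # 3/10 = 0.3 -> dropped at threshold 0.2
  v[mask] <- NA
  fd <- filter_proteins_by_mv(make_em(v, scale = "linear", mask = mask),
                              max_mv_fraction = 0.2)
  expect_setequal(fd$kept, c("gA", "gB"))
  expect_identical(fd$dropped, "gC")
  fd_all <- filter_proteins_by_mv(make_em(v, scale = "linear", mask = mask),
                                  max_mv_fraction = 1)
  expect_length(fd_all$dropped, 0L)

  # recount oracle on a censored cohort
  sim <- small_sim(seed = 13, censor_midpoint = 18)
  fd2 <- filter_proteins_by_mv(sim$protein, 0.3)
  manual <- rowSums(sim$protein$mask) / ncol(sim$protein$mask) <= 0.3
  expect_setequal(fd2$kept, em_genes(sim$protein)[manual])
  expect_identical(length(fd2$kept) + length(fd2$dropped), nrow(sim$protein$values))
})

test_that("RNA count filter drops strictly-below-threshold genes", {
  v <- rbind(g1 = c(500, 499), g2 = c(500, 500), g3 = c(501, 500),
             g4 = c(0, 0))
  colnames(v) <- c("s1", "s2")
  m <- make_em(v, layer = "rna", scale = "linear")
  fd <- filter_rna_by_total_count(m, min_total = 1000)
  expect_setequal(fd$kept, c("g2", "g3"))
  expect_setequal(fd$dropped, c("g1", "g4"))
  expect_error(filter_rna_by_total_count(make_em(v), 1000), "layer")

  sim <- small_sim(seed = 14)
  fd2 <- filter_rna_by_total_count(sim$rna, 1000)
  expect_setequal(fd2$kept, em_genes(sim$rna)[rowSums(sim$rna$values) >= 1000])
})

test_that("overlap percentages reproduce the printed funnel figures", {
  # coverage after filtering: 314 of 496 coding genes -> 63%
  rna_side <- sprintf("r%03d", 1:499)
  annot <- gene_annotation(rna_side,
                           coding = c(rep(TRUE, 496), rep(FALSE, 3)))
  prot_side <- c(sprintf("r%03d", 1:314), sprintf("p%04d", 1:6184))
  ov <- overlap_genes(prot_side, rna_side, annot)
  expect_identical(ov$n_rna, 496L)
  expect_identical(ov$n_overlap, 314L)
  expect_identical(ov$percent, 63)

  # pre-filter coverage: 399 of 496 -> 80%
  prot_side2 <- c(sprintf("r%03d", 1:399), sprintf("p%04d", 1:8242))
  ov2 <- overlap_genes(prot_side2, rna_side, annot)
  expect_identical(ov2$percent, 80)

  ov3 <- overlap_genes(c("a", "b"), c("c", "d"), gene_annotation(c("c", "d")))
  expect_identical(ov3$percent, 0)
})
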