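test_that("imputation fills missing cells only, by the documented rules", {
  v <- rbind(g1 = c(4, 5), g2 = c(6, NA), g3 = c(8, 7))
  colnames(v) <- c("s1", "s2")
  m <- make_em(v)

  # min_det at q = 0: the sample minimum
  imp <- impute_missing(m, "min_det", min_det_quantile = 0)
  expect_equal(imp$values["g2", "s2"], 5)
  expect_equal(imp$values[!m$mask], v[!m$mask])
  expect_identical(imp$mask, m$mask)   # provenance retained

  # zero method: every missing cell at the floor, observed shifted-min at 1
  impz <- impute_missing(m, "zero")
  expect_equal(impz$values["g2", "s2"], 0)
  expect_equal(min(impz$values[!m$mask]), 1)
  expect_equal(impz$values[!m$mask] - v[!m$mask],
               rep(attr(impz, "floor_shift") * -1, 5))

  # min_det quantile equals the brute-force order-statistic quantile
  set.seed(1)
  big <- matrix(stats::rnorm(2000, 15, 2), 1000, 2)
  big[c(5, 700), 1] <- NA
  mb <- make_em(big)
  impq <- impute_missing(mb, "min_det", min_det_quantile = 0.01)
  obs <- sort(big[!is.na(big[, 1]), 1])
  h <- (length(obs) - 1) * 0.01
  oracle <- obs[floor(h) + 1] + (h - floor(h)) * (obs[floor(h) + 2] - obs[floor(h) + 1])
  expect_equal(unname(impq$values[5, 1]), oracle, tolerance = 1e-12)

  # a sample with nothing observed is an error naming the sample
  v2 <- v; v2[, "s2"] <- NA
  expect_error(impute_missing(make_em(v2), "zero"), "s2")
})

test_that("min_det preserves a planted knockdown's rank minimum", {
  cfg <- small_cfg(seed = 31)
  g <- pick_target_genes(cfg)
  sim <- simulate_cohort(cfg, list(plant_spec("concordant_down", "P004",
                                              gene = g, effect_log2 = 7)))
  imp <- impute_missing(em_log2(sim$protein), "min_det")
  expect_identical(names(which.min(imp$values[g, ])), "P004")
})

test_that("quantile normalization: hand oracle, defining property, idempotence", {
  v <- cbind(s1 = c(5, 2, 3), s2 = c(4, 1, 4), s3 = c(3, 4, 6))
  rownames(v) <- paste0("g", 1:3)
  qn <- quantile_normalize(make_em(v))
  # hand-computed rank-mean table (row means of sorted columns: 2, 11/3, 5)
  ref <- c(2, 11/3, 5)
  expect_equal(unname(qn$values[, "s1"]), ref[c(3, 1, 2)], tolerance = 1e-12)
  # s2 has a tie at 4 (ranks 2.5): both get the mean of ref[2:3]
  expect_equal(unname(qn$values[c(1, 3), "s2"]),
               rep(mean(ref[2:3]), 2), tolerance = 1e-12)

  # cross-check against the limma reference implementation
  skip_if_not_installed("limma")
  set.seed(2)
  r <- matrix(stats::rnorm(600, 12, 3), 100, 6)
  qn2 <- quantile_normalize(make_em(r))
  expect_equal(unname(qn2$values), unname(limma::normalizeQuantiles(r)),
               tolerance = 1e-9)

  # identical samples unchanged; per-sample quantile vectors equal; idempotent
  same <- make_em(cbind(s1 = c(1, 5, 9), s2 = c(1, 5, 9)))
  expect_equal(quantile_normalize(same)$values, same$values, ignore_attr = TRUE)
  qv <- apply(qn2$values, 2L, sort)
  expect_lt(max(abs(qv - qv[, 1])), 1e-9)
  expect_equal(quantile_normalize(qn2)$values, qn2$values, tolerance = 1e-9)
})

test_that("RLR normalization removes affine shifts and resists outliers", {
  set.seed(7)
  base <- stats::rnorm(400, 14, 2)
  v <- cbind(s1 = base, s2 = base, s3 = base + 1.7)
  rownames(v) <- sprintf("g%03d", 1:400)
  out <- rlr_normalize(make_em(v))
  expect_equal(unname(out$values[, "s3"]), base, tolerance = 1e-6)
  # identity cohort unchanged
  ident <- rlr_normalize(make_em(cbind(s1 = base, s2 = base, s3 = base)))
  expect_equal(unname(ident$values[, "s1"]), base, tolerance = 1e-8)

  # 5% wild outlier genes: robust slope within 1% of the clean fit; OLS is not
  contaminated <- base * 1.1 + 0.5
  idx <- sample(400, 20)
  contaminated[idx] <- contaminated[idx] + stats::rnorm(20, 8, 1)
  ref <- apply(cbind(base, base, contaminated), 1L, stats::median)
  clean_slope <- 1.1
  rob <- MASS::rlm(contaminated ~ base, psi = MASS::psi.huber, k = 1.345,
                   maxit = 50, acc = 1e-8)
  ols <- stats::lm(contaminated ~ base)
  expect_lt(abs(stats::coef(rob)[2] - clean_slope) / clean_slope, 0.01)
  expect_gt(abs(stats::coef(ols)[2] - clean_slope) / clean_slope, 0.01)
})

test_that("VST: unit size factors, doubling equivariance, variance flattening", {
  v <- matrix(rep(c(10, 200, 3000, 45), 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  m <- make_em(v, layer = "rna", scale = "linear")
  out <- vst_rna(m)
  expect_equal(unname(attr(out, "size_factors")), rep(1, 3), tolerance = 1e-12)

  # doubling one sample's counts doubles its size factor and leaves the
  # transform invariant (size factors are anchored at median 1)
  set.seed(5)
  counts <- matrix(stats::rnbinom(80 * 9, mu = 300, size = 10), 80, 9,
                   dimnames = list(sprintf("g%02d", 1:80), sprintf("s%02d", 1:9)))
  counts[counts == 0] <- 1
  m1 <- make_em(counts, layer = "rna", scale = "linear")
  doubled <- counts; doubled[, 4] <- 2 * doubled[, 4]
  m2 <- make_em(doubled, layer = "rna", scale = "linear")
  t1 <- vst_rna(m1); t2 <- vst_rna(m2)
  # invariance up to the median anchor re-identifying itself among the
  # near-tied size factors (drift ~ dispersion / sqrt(n_genes) ~ 0.02)
  expect_equal(attr(t2, "size_factors")[[4]], 2 * attr(t1, "size_factors")[[4]],
               tolerance = 0.02)
  expect_equal(t2$values, t1$values, tolerance = 0.02)

  # fallback when every gene has a zero
  withzero <- counts; withzero[cbind(1:80, rep_len(1:9, 80))] <- 0
  expect_no_error(suppressMessages(
    vst_rna(make_em(withzero, layer = "rna", scale = "linear"))))

  # stabilization: sd roughly flat across the top 3 mean-quartiles
  set.seed(6)
  mu <- 2^stats::runif(400, 4, 12)
  nb <- matrix(stats::rnbinom(400 * 30, mu = rep(mu, 30), size = 1 / 0.1),
               400, 30, dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:30)))
  tv <- vst_rna(make_em(nb, layer = "rna", scale = "linear"))$values
  qt <- cut(rowMeans(nb), stats::quantile(rowMeans(nb), 0:4 / 4),
            include.lowest = TRUE, labels = FALSE)
  sds <- tapply(apply(tv, 1L, stats::sd), qt, mean)[2:4]
  expect_lt(max(sds) / min(sds), 2)
})

test_that("normalization assessment metrics behave as advertised", {
  # genes with distinct means (so the median reference tracks each sample)
  # plus per-sample scale shifts that normalization should remove
  set.seed(9)
  gene_means <- stats::rnorm(100, 14, 3)
  base <- matrix(gene_means + stats::rnorm(300, 0, 0.3), 100, 3,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:3)))
  shifted <- base + rep(c(0, 2, 4), each = 100)
  m <- make_em(shifted)
  aq <- assess_normalization(m, quantile_normalize(m))
  ar <- assess_normalization(m, rlr_normalize(m))
  expect_equal(aq$after$sample_median_mad, 0, tolerance = 1e-12)
  expect_lt(aq$after$pooled_cv, aq$before$pooled_cv)
  expect_lt(ar$after$pooled_cv, ar$before$pooled_cv)
  expect_lt(ar$after$sample_median_mad, ar$before$sample_median_mad)
  same <- assess_normalization(m, m)
  expect_identical(same$before, same$after)
})
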