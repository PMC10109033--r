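dea_matrix <- function(n_genes, n1, n2, effect_genes = integer(0), effect = 0,
                       seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * (n1 + n2), 10, 1), n_genes, n1 + n2,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n1 + n2))))
  v[effect_genes, seq_len(n1)] <- v[effect_genes, seq_len(n1)] + effect
  list(m = make_em(v),
       groups = rep(c("deficient", "other"), c(n1, n2)))
}

test_that("moderated DEA: exact lfc, label-swap antisymmetry, t-test limit", {
  d <- dea_matrix(50, 4, 4, seed = 2)
  d$m$values[1, 1:4] <- d$m$values[1, 5:8] - 2
  res <- moderated_dea(d$m, d$groups)
  expect_equal(res$lfc[1], -2, tolerance = 1e-12)

  swapped <- moderated_dea(d$m, ifelse(d$groups == "deficient", "other", "deficient"))
  expect_equal(swapped$lfc, -res$lfc, tolerance = 1e-10)
  expect_equal(swapped$t_moderated, -res$t_moderated, tolerance = 1e-10)
  expect_equal(swapped$p, res$p, tolerance = 1e-10)

  # prior_df = 0 collapses to the ordinary equal-variance two-sample t
  res0 <- moderated_dea(d$m, d$groups, prior_df = 0)
  oracle <- apply(d$m$values, 1L, function(x) {
    tt <- stats::t.test(x[1:4], x[5:8], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(res0$t_moderated, unname(oracle[1, ]), tolerance = 1e-8)
  expect_equal(res0$p, unname(oracle[2, ]), tolerance = 1e-8)

  expect_error(moderated_dea(d$m, rep("a", 8)), "two groups")
  expect_error(moderated_dea(d$m, c("a", rep("b", 7))), "at least 2")
})

test_that("empirical-Bayes moderation tracks the limma reference", {
  skip_if_not_installed("limma")
  # heteroscedastic genes so the variance prior is genuinely finite:
  # per-gene variances drawn from a scaled inverse-chi-square with d0 = 4
  set.seed(5)
  n_genes <- 400; n1 <- 6; n2 <- 7
  sd_g <- sqrt(4 * 1 / stats::rchisq(n_genes, df = 4))
  v <- matrix(stats::rnorm(n_genes * (n1 + n2), 10, rep(sd_g, n1 + n2)),
              n_genes, n1 + n2,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              sprintf("s%02d", seq_len(n1 + n2))))
  groups <- rep(c("deficient", "other"), c(n1, n2))
  res <- moderated_dea(make_em(v), groups)
  fit <- limma::eBayes(limma::lmFit(v, cbind(1, groups == "deficient")))
  expect_gt(stats::cor(res$t_moderated, fit$t[, 2]), 0.999)
  expect_equal(res$lfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  # prior df from moment matching lands near limma's (and near truth d0 = 4)
  expect_equal(log(attr(res, "prior_df")), log(fit$df.prior), tolerance = 1)
})

test_that("moderated t is calibrated under the null (smoke scale)", {
  rates <- vapply(1:5, function(s) {
    d <- dea_matrix(1000, 15, 16, seed = s)
    mean(moderated_dea(d$m, d$groups)$p < 0.05)
  }, numeric(1))
  expect_true(all(rates > 0.02 & rates < 0.08))
})

test_that("significant_down applies strict boundaries in deterministic order", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                    lfc = c(-2, -1.5, -2, -2, -1.6),
                    p = c(0.05, 0.01, 0.002, 0.002, 0.04))
  expect_identical(significant_down(res), c("g3", "g4", "g5"))
  # p = 0.05 exactly and lfc = -1.5 exactly are both excluded

  # planted deficiency: all selected markers strongly down
  def <- sprintf("P%03d", 1:6)
  sim <- small_sim(seed = 25, plants = lapply(def, function(x)
    plant_spec("b_cell_deficient", x, effect_log2 = 3)))
  prot <- preprocess_protein(sim$protein, "min_det", "quantile")
  groups <- stats::setNames(ifelse(em_samples(prot) %in% def, "deficient", "other"),
                            em_samples(prot))
  down <- significant_down(moderated_dea(prot, groups))
  markers <- sim$annot$gene[sim$annot$cell_marker == "b_cell"]
  expect_true(all(markers %in% down))
})

test_that("hypergeometric enrichment agrees with exhaustive enumeration", {
  # closed-form corner: universe 20, set 5, draw 5, full overlap
  uni <- sprintf("u%02d", 1:20)
  sets <- list(S = uni[1:5])
  res <- enrich(uni[1:5], sets, uni)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$overlap, 5L)

  # enumeration oracle over all draws for small universes
  for (seed in 1:5) {
    set.seed(seed)
    N <- sample(10:25, 1); k <- sample(3:5, 1); s_size <- sample(3:7, 1)
    uni <- sprintf("u%02d", seq_len(N))
    set_genes <- sample(uni, s_size)
    hits <- sample(uni, k)
    obs <- length(intersect(set_genes, hits))
    draws <- utils::combn(N, k)
    in_set <- seq_len(N) %in% match(set_genes, uni)
    counts <- colSums(matrix(in_set[draws], nrow = k))
    oracle_p <- mean(counts >= obs)
    res2 <- enrich(hits, list(S = set_genes), uni)
    expect_equal(res2$p, oracle_p, tolerance = 1e-12)
  }

  # empty gene list: empty result, not an error
  expect_identical(nrow(enrich(character(0), sets, uni)), 0L)

  # identical set and list with a 10x universe: overlap = |list|, minimal p
  uni2 <- sprintf("v%02d", 1:50)
  res3 <- enrich(uni2[1:5], list(S = uni2[1:5]), uni2)
  expect_identical(res3$overlap, 5L)
  expect_lt(res3$p, 1e-5)
})

test_that("enrichment p-values are calibrated under random draws", {
  # the p-value is discrete, so a naive KS test against the continuous
  # uniform would reject on support alone; calibration is asserted against
  # the exact null distribution of the overlap instead, plus the
  # superuniformity bound P(p <= a) <= a that valid p-values must satisfy
  set.seed(99)
  uni <- sprintf("u%03d", 1:60)
  set_genes <- uni[1:15]
  ps <- vapply(1:1000, function(i) {
    enrich(sample(uni, 10), list(S = set_genes), uni)$p
  }, numeric(1))
  support <- stats::phyper(0:10 - 1, 15, 45, 10, lower.tail = FALSE)
  probs <- stats::dhyper(0:10, 15, 45, 10)
  obs <- vapply(seq_along(support),
                function(i) sum(abs(ps - support[i]) < 1e-12), numeric(1))
  keep <- probs > 5 / 1000          # merge rare tail classes for the GOF test
  gof <- suppressWarnings(
    stats::chisq.test(c(obs[keep], sum(obs[!keep])),
                      p = c(probs[keep], sum(probs[!keep]))))
  expect_gt(gof$p.value, 0.01)
  for (a in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 1000))
  }
})

test_that("BH adjustment matches the reference step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3), tolerance = 1e-12)
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(4)
  p <- stats::runif(1000)^2
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone in sorted-p order, bounded by 1
  adj <- bh_adjust(p)[order(p)]
  expect_true(all(diff(adj) >= -1e-15))
  expect_lte(max(adj), 1)
})
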