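test_that("Pearson correlations hit the exact endpoints", {
  d <- tidyr::expand_grid(sample_id = sprintf("s%d", 1:6),
                          band = factor(c("inner_margin", "outer_margin"),
                                        levels = band_levels()),
                          subset = c("cd8_t", "b_cell"))
  d$density <- as.numeric(seq_len(nrow(d)))
  # identical densities in both regions -> PCC 1
  d1 <- d
  d1$density <- rep(match(d1$sample_id, unique(d1$sample_id)), 1) +
    match(d1$subset, unique(d1$subset)) * 10
  pcc1 <- region_pair_pcc(d1, "inner_margin", "outer_margin")
  expect_true(all(pcc1$pcc == 1))
  # anti-sorted -> PCC -1
  d2 <- d
  for (s in unique(d$subset)) {
    i <- d2$band == "inner_margin" & d2$subset == s
    o <- d2$band == "outer_margin" & d2$subset == s
    d2$density[i] <- 1:6
    d2$density[o] <- 6:1
  }
  pcc2 <- region_pair_pcc(d2, "inner_margin", "outer_margin")
  expect_true(all(pcc2$pcc == -1))
  # constant vector -> missing with reason
  d3 <- dplyr::mutate(d, density = ifelse(band == "inner_margin", 5, runif(24)))
  pcc3 <- region_pair_pcc(d3, "inner_margin", "outer_margin")
  expect_true(all(is.na(pcc3$pcc)))
  expect_true(all(pcc3$reason == "constant variable"))
})

test_that("a generating cross-region correlation of 0.8 is recovered within its Fisher-z interval", {
  set.seed(0)
  n <- 30; rho <- 0.8
  z <- matrix(rnorm(2 * n), n, 2)
  x <- z[, 1]; y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  d <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("s%d", 1:n), band = "inner_margin",
                   subset = "cd8_t", density = 100 + 20 * x),
    tibble::tibble(sample_id = sprintf("s%d", 1:n), band = "outer_margin",
                   subset = "cd8_t", density = 150 + 30 * y))
  d$band <- factor(d$band, levels = band_levels())
  est <- region_pair_pcc(d, "inner_margin", "outer_margin")$pcc
  zlim <- atanh(rho) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3)
  expect_gte(est, tanh(zlim[1]))
  expect_lte(est, tanh(zlim[2]))
  # PCC invariant under positive affine transforms
  d_aff <- dplyr::mutate(d, density = ifelse(band == "inner_margin",
                                             3 * density + 7, density))
  expect_equal(region_pair_pcc(d_aff, "inner_margin", "outer_margin")$pcc, est)
})

test_that("paired R-squared behaves at both ends of the null", {
  prim <- tibble::tibble(patient_id = sprintf("p%d", 1:10), band = "core",
                         subset = "cd4_t", density = (1:10) * 10)
  met <- dplyr::mutate(prim, density = density * 0.7 + 2)  # proportional
  expect_equal(paired_site_r2(prim, met, "core")$r2, 1)
  # independent pairs: R^2 below 0.3 in at least 95% of 100 seeded cohorts of n = 13
  r2s <- vapply(1:100, function(s) {
    set.seed(s)
    a <- dplyr::mutate(prim[1:13 %% 10 + 1, ], patient_id = sprintf("q%d", 1:13),
                       density = rnorm(13))
    b <- dplyr::mutate(a, density = rnorm(13))
    paired_site_r2(a, b, "core")$r2
  }, numeric(1))
  expect_gte(mean(r2s < 0.3), 0.95)
  # fewer than 3 pairs -> missing
  expect_true(is.na(paired_site_r2(prim[1:2, ], met[1:2, ], "core")$r2))
})

test_that("LA-immune correlations handle zero counts and planted coupling", {
  n <- 20
  la <- tibble::tibble(sample_id = sprintf("s%d", 1:n), n_intratumoral_la = 0L)
  sp <- tibble::tibble(sample_id = sprintf("s%d", 1:n), band = "core",
                       subset = "b_cell", density = runif(n))
  out0 <- la_immune_pcc(la, sp)
  expect_true(is.na(out0$pcc))
  # planted positive coupling: sign correct in >= 95% of seeds
  signs <- vapply(1:40, function(s) {
    set.seed(s)
    counts <- rpois(n, 3)
    la2 <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                          n_intratumoral_la = counts)
    sp2 <- tibble::tibble(sample_id = sprintf("s%d", 1:n), band = "core",
                          subset = "b_cell",
                          density = 50 + 30 * counts + rnorm(n, 0, 10))
    sign(la_immune_pcc(la2, sp2)$pcc)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
  # exchangeability: permuting one variable gives mean PCC ~ 0
  set.seed(99)
  perm <- vapply(1:200, function(i) {
    la3 <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                          n_intratumoral_la = sample(rpois(n, 3)))
    sp3 <- tibble::tibble(sample_id = sprintf("s%d", 1:n), band = "core",
                          subset = "b_cell", density = runif(n, 10, 100))
    la_immune_pcc(la3, sp3)$pcc
  }, numeric(1))
  expect_lt(abs(mean(perm)), 0.05)
})

test_that("rank-sum tests match exact enumeration and handle identical groups", {
  # {1,2,3} vs {10,11,12}: exact two-sided p = 0.1 over the C(6,3) = 20 splits
  expect_equal(enumerate_ranksum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  res <- wilcoxon_bh(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1)
  # enumeration oracle matches the implementation for random small groups
  for (s in 1:5) {
    set.seed(s)
    a <- sample(100, 5); b <- sample(200:300, 6)
    res_s <- wilcoxon_bh(c(a, b), rep(c("g1", "g2"), c(5, 6)))
    expect_equal(res_s$p, enumerate_ranksum_p(a, b), tolerance = 1e-12)
  }
  # identical groups -> p = 1, q = 1 (normal approximation with ties)
  res_id <- wilcoxon_bh(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(res_id$p, 1)
  expect_equal(res_id$q, 1)
})

test_that("BH adjustment follows the step-up formula and orders q with p", {
  # hand-applied BH on (0.01, 0.02, 0.04): (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  vals <- c(1, 2, 3, 10, 11, 12, 5, 6, 7)
  res <- wilcoxon_bh(vals, rep(c("a", "b", "c"), each = 3))
  expect_equal(nrow(res), 3)
  expect_true(all(res$q >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("chi-squared presence test reproduces the hand-computed statistic", {
  tab <- rbind(c(8, 2), c(2, 8))
  res <- suppressWarnings(chi2_presence(tab))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 1)
  # identical proportions -> statistic 0, p = 1
  res0 <- suppressWarnings(chi2_presence(rbind(c(5, 5), c(5, 5))))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # degenerate tables are rejected
  expect_error(chi2_presence(cbind(c(8, 2))), "columns")
  expect_error(chi2_presence(rbind(c(0, 0), c(5, 5))), "margins")
  # data-frame interface tabulates presence by organ
  df <- tibble::tibble(organ = rep(c("liver", "lung"), each = 10),
                       present = c(rep(TRUE, 8), rep(FALSE, 2),
                                   rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(suppressWarnings(chi2_presence(df))$statistic, 7.2)
})
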