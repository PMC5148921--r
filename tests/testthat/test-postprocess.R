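# Post-MCMC summaries: LOD statistics, binned profiles, weighting,
# selection, heat map and variance components.

test_that("LOD conversion and inclusion weighting follow their formulas", {
  expect_equal(lod_from_wald(0), 0)
  expect_equal(lod_from_wald(2 * log(10)), 1)
  expect_equal(lod_from_wald(6 * log(10)), 3)
  expect_error(lod_from_wald(-1), ">= 0")
  expect_equal(weighted_lod(18000, 5, 18000), 5)
  expect_equal(weighted_lod(0, 5, 18000), 0)
  expect_equal(weighted_lod(400, 5, 18000), 400 * 5 / 18000)
  expect_equal(weighted_lod(400, 5, 18000), 0.1111, tolerance = 1e-3)
  expect_error(weighted_lod(1, 5, 0), "N must be")
  expect_error(weighted_lod(10, 5, 9), "inclusion count")
})

test_that("interval Wald statistic uses posterior moments of the chains", {
  map <- two_group_map()
  N <- 500
  set.seed(1)
  a <- matrix(rnorm(N * 10, 0, 0.1), N, 10)
  d <- matrix(rnorm(N * 10, 0, 0.1), N, 10)
  a[, 3] <- rnorm(N, 2, 0.5)           # one strong additive interval
  lam <- matrix(rep(seq(5, 95, by = 10) %% 50, each = N), N, 10)
  ch <- fake_chain(a, d, lam, map)
  il <- interval_lod(ch)
  W3 <- mean(a[, 3])^2 / var(a[, 3]) + mean(d[, 3])^2 / var(d[, 3])
  expect_equal(il$lod[3], W3 / (2 * log(10)))
  expect_equal(which.max(il$lod), 3L)
  # all-zero chains give a flat-zero profile
  ch0 <- fake_chain(a * 0, d * 0, lam, map)
  expect_true(all(interval_lod(ch0)$lod == 0))
  prof0 <- main_qtl_profile(ch0)
  expect_true(all(prof0$lod == 0))
  # LOD is invariant under phenotype rescaling (chains scale linearly)
  ch_scaled <- fake_chain(3 * a, 3 * d, lam, map)
  expect_equal(interval_lod(ch_scaled)$lod, il$lod)
})

test_that("profile bins tile each group and weight frequency by max LOD", {
  map <- two_group_map()             # two groups spanning 50 cM each
  N <- 200
  set.seed(2)
  a <- matrix(rnorm(N * 10, 1, 1), N, 10)
  d <- matrix(rnorm(N * 10), N, 10)
  lam <- matrix(runif(N * 10, 0.01, 9.99), N, 10) +
    matrix(rep(c(0, 10, 20, 30, 40), each = N), N, 10)
  ch <- fake_chain(a, d, lam, map)
  prof <- main_qtl_profile(ch, bin_cM = 3)
  for (g in 1:2) {
    pg <- prof[prof$group == g, ]
    expect_equal(pg$bin_start, seq(0, 48, by = 3))
    expect_equal(pg$bin_end, c(seq(3, 48, by = 3), 50))
    expect_equal(pg$bin_start[-1], pg$bin_end[-nrow(pg)])  # no overlap
  }
  # frequencies sum to 1 per group; lod = freq x max_lod
  expect_equal(sum(prof$freq[prof$group == 1]), 1)
  expect_equal(prof$lod, prof$freq * prof$max_lod)
  pm <- main_qtl_profile(ch, bin_cM = 3, weight = "max_lod")
  expect_equal(pm$lod, pm$max_lod)
})

test_that("epistatic LOD uses inclusion-conditional moments", {
  map <- two_group_map()
  N <- 1000
  set.seed(3)
  # pair (2,7) active in 600 samples with a strong dd effect
  idx <- sort(sample(N, 600))
  epi <- data.frame(sample = idx, k1 = 2L, k2 = 7L,
                    aa = rnorm(600, 0, 0.05), ad = rnorm(600, 0, 0.05),
                    da = rnorm(600, 0, 0.05), dd = rnorm(600, 1.5, 0.3))
  ch <- fake_chain(matrix(0, N, 10), matrix(0, N, 10),
                   matrix(5, N, 10), map, epi = epi)
  el <- epistasis_lod(ch, 2, 7)
  W <- sum(colMeans(epi[, 4:7])^2 / apply(epi[, 4:7], 2, var))
  expect_equal(el$lod, W / (2 * log(10)))
  expect_true(el$defined)
  expect_equal(el$n, 600L)
  # order-free pair lookup
  expect_equal(epistasis_lod(ch, 7, 2)$lod, el$lod)
  # unseen pair: undefined moments flagged, LOD 0
  e0 <- epistasis_lod(ch, 1, 2)
  expect_false(e0$defined)
  expect_equal(e0$lod, 0)
  # summary table carries n, N, LOD* and the selection flag
  sm <- summarize_epistasis(ch, chain_min = 400, lod_min = 3)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$n, 600L)
  expect_equal(sm$lod_star, weighted_lod(600, sm$lod, N))
  expect_true(all(sm$lod_star <= sm$lod))
})

test_that("selection applies strict chain-then-LOD thresholds monotonely", {
  base <- data.frame(k1 = 1:4, k2 = 2:5, n = c(401, 400, 18000, 5000),
                     N = 18000, lod = c(3.01, 10, 2.99, 8),
                     lod_star = c(0.07, 0.2, 2.99, 2.2),
                     aa = 0, ad = 0, da = 0, dd = 0)
  sel <- select_epistasis(base, 400, 3)
  expect_equal(sort(sel$k1), c(1L, 4L))   # strict: 400 and 2.99 both fail
  expect_equal(sel$k1[1], 4L)             # sorted by LOD* descending
  # monotone: raising either threshold never adds a pair
  sel2 <- select_epistasis(base, 1000, 3)
  expect_true(all(sel2$k1 %in% sel$k1))
  sel3 <- select_epistasis(base, 400, 5)
  expect_true(all(sel3$k1 %in% sel$k1))
})

test_that("heat-map matrix mirrors the inclusion counts", {
  map <- two_group_map()
  N <- 100
  epi <- data.frame(sample = c(1:30, 5:14), k1 = rep(c(2L, 3L), c(30, 10)),
                    k2 = rep(c(7L, 9L), c(30, 10)),
                    aa = 0, ad = 0, da = 0, dd = 0)
  ch <- fake_chain(matrix(0, N, 10), matrix(0, N, 10), matrix(5, N, 10),
                   map, epi = epi)
  hm <- heatmap_matrix(ch)
  expect_identical(hm, t(hm))
  expect_equal(hm[2, 7], 30L)
  expect_equal(hm[9, 3], 10L)
  expect_true(all(diag(hm) == 0))
  expect_equal(sum(hm[upper.tri(hm)]), sum(ch$samples$t))
})

test_that("variance components recover plug-in contributions", {
  map <- two_group_map()
  N <- 50; n <- 200
  set.seed(4)
  x0 <- sample(c(1, 0, -1), n, TRUE, c(0.25, 0.5, 0.25))
  xbar <- matrix(0, n, 10); xbar[, 1] <- x0
  a <- matrix(0, N, 10); a[, 1] <- 2      # constant additive effect 2
  ch <- fake_chain(a, matrix(0, N, 10), matrix(5, N, 10), map,
                   sigma2 = rep(1.7, N), xbar = xbar,
                   wbar = matrix(0, n, 10))
  vc <- variance_components(ch)
  expect_equal(vc$variance[vc$component == "additive"], 4 * var(x0))
  expect_equal(vc$variance[vc$component == "dominance"], 0)
  expect_equal(vc$variance[vc$component == "residual"], 1.7)
  expect_true(all(vc$variance[vc$component %in%
                                c("aa", "ad", "da", "dd")] == 0))
  expect_equal(vc$variance[vc$component == "total_genetic"], 4 * var(x0))
})
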