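# Sampler mechanics: engine agreement, determinism, bookkeeping identities,
# and distribution checks of the conditional draws on small fixtures.

small_cross <- function(n = 60, seed = 5) {
  sc <- recovery_scenario()
  simulate_cross(sc, n = n, seed = seed)
}

test_that("both engines realise the same chain from one seed", {
  # the engines share one RNG stream; floating-point summation round-off
  # (R accumulates in long double) amplifies slowly, so agreement is
  # asserted over a 60-iteration horizon
  b <- small_cross()
  cfg <- sampler_config(burn_in = 10, thin = 1, retained = 50, seed = 9)
  ch_r <- run_rjmcmc(b$pheno, b$geno, b$map, config = cfg, engine = "r")
  ch_c <- run_rjmcmc(b$pheno, b$geno, b$map, config = cfg, engine = "cpp")
  expect_identical(ch_r$t_trace, ch_c$t_trace)
  expect_equal(ch_r$samples$mu, ch_c$samples$mu, tolerance = 1e-6)
  expect_equal(ch_r$samples$sigma2, ch_c$samples$sigma2, tolerance = 1e-6)
  expect_equal(ch_r$a, ch_c$a, tolerance = 1e-6)
  expect_equal(ch_r$d, ch_c$d, tolerance = 1e-6)
  expect_equal(ch_r$lambda, ch_c$lambda, tolerance = 1e-6)
  expect_identical(ch_r$inclusion, ch_c$inclusion)
  expect_identical(ch_r$epi$k1, ch_c$epi$k1)
  expect_identical(ch_r$epi$k2, ch_c$epi$k2)
})

test_that("runs are reproducible from the seed and respect the schedule", {
  b <- small_cross(40)
  cfg <- sampler_config(burn_in = 30, thin = 3, retained = 50, seed = 77)
  ch1 <- run_rjmcmc(b$pheno, b$geno, b$map, config = cfg)
  ch2 <- run_rjmcmc(b$pheno, b$geno, b$map, config = cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$epi, ch2$epi)
  expect_equal(nrow(ch1$samples), 50L)
  expect_equal(ch1$samples$iteration, seq(33, 180, by = 3))
  expect_equal(length(ch1$t_trace), 180L)
})

test_that("chain bookkeeping identities hold", {
  b <- small_cross(80, seed = 2)
  ch <- run_rjmcmc(b$pheno, b$geno, b$map,
                   config = sampler_config(burn_in = 100, thin = 2,
                                           retained = 400, seed = 3))
  # dimension changes by at most one pair per move, two moves per iteration
  expect_true(all(abs(diff(ch$t_trace)) <= 2))
  # per retained sample, the long table rows equal the recorded t
  rows <- tabulate(ch$epi$sample, ch$N)
  expect_equal(rows, ch$samples$t)
  # inclusion counts sum to the number of long-table rows, and the
  # upper-triangle total equals the summed dimension trajectory
  expect_equal(sum(ch$inclusion) / 2, nrow(ch$epi))
  expect_equal(sum(ch$inclusion[upper.tri(ch$inclusion)]),
               sum(ch$samples$t))
  expect_identical(ch$inclusion, t(ch$inclusion))
  # positions stay strictly inside their interval bounds
  itab <- ch$intervals
  for (k in seq_len(nrow(itab))) {
    expect_true(all(ch$lambda[, k] > itab$lower[k]))
    expect_true(all(ch$lambda[, k] < itab$upper[k]))
  }
  # all recorded variances respect the floor, all states finite
  expect_true(all(ch$sa2 > 0) && all(ch$sd2 > 0))
  expect_true(all(is.finite(ch$samples$sigma2)) &&
                all(ch$samples$sigma2 > 0))
  expect_true(all(is.finite(ch$a)) && all(is.finite(ch$d)))
})

test_that("validation rejects malformed input", {
  b <- small_cross(20)
  expect_error(run_rjmcmc(rep(1, 20), b$geno, b$map), "constant")
  expect_error(run_rjmcmc(b$pheno[-1], b$geno, b$map), "rows must match")
  g2 <- b$geno; colnames(g2)[1] <- "zzz"
  expect_error(run_rjmcmc(b$pheno, g2, b$map), "lacks map marker")
  g3 <- b$geno; g3[1, 1] <- 7L
  expect_error(run_rjmcmc(b$pheno, g3, b$map), "codes must be")
})

test_that("missing marker genotypes are tolerated by the imputation", {
  b <- small_cross(50, seed = 8)
  g <- b$geno
  set.seed(1)
  g[sample(length(g), length(g) %/% 10)] <- NA_integer_
  ch <- run_rjmcmc(b$pheno, g, b$map,
                   config = sampler_config(burn_in = 20, thin = 1,
                                           retained = 60, seed = 4))
  expect_equal(nrow(ch$samples), 60L)
  expect_true(all(is.finite(ch$samples$sigma2)))
})

test_that("ridge conditional draws match the grid-evaluated density", {
  fx <- toy_fixture()
  # effect conditional: p(b) ~ exp(-0.5/s2 sum((r - c b)^2)) N(0, ev)
  logdens <- function(bb)
    -0.5 / fx$sigma2 * sum((fx$y - fx$cc * bb)^2) -
      bb^2 / (2 * fx$effect_var)
  cdf <- grid_cdf(logdens, -4, 4)
  set.seed(10)
  draws <- replicate(50000,
    epiqtl:::ridge_draw(fx$cc, fx$y, fx$sigma2, fx$effect_var))
  expect_lt(ks_stat(draws, cdf), 0.02)
  # dominance-type covariate, same form
  logdens_w <- function(bb)
    -0.5 / fx$sigma2 * sum((fx$y - fx$ww * bb)^2) -
      bb^2 / (2 * fx$effect_var)
  set.seed(11)
  draws_w <- replicate(50000,
    epiqtl:::ridge_draw(fx$ww, fx$y, fx$sigma2, fx$effect_var))
  expect_lt(ks_stat(draws_w, grid_cdf(logdens_w, -6, 6)), 0.02)
  # all-zero covariate recovers the prior
  set.seed(12)
  dz <- replicate(20000, epiqtl:::ridge_draw(rep(0, 5), fx$y, fx$sigma2,
                                             fx$effect_var))
  expect_equal(stats::var(dz), fx$effect_var, tolerance = 0.05)
  expect_equal(mean(dz), 0, tolerance = 0.02)
  # vanishing shrinkage tends to the least-squares coefficient
  set.seed(13)
  dls <- replicate(20000, epiqtl:::ridge_draw(fx$cc, fx$y, fx$sigma2, 1e8))
  expect_equal(mean(dls), sum(fx$cc * fx$y) / sum(fx$cc^2),
               tolerance = 0.02)
})

test_that("shrinkage-variance draws match the scaled inverse-chi-square", {
  set.seed(21)
  draws <- epiqtl:::draw_effect_variance(rep(1, 1e5), 0.95)
  # independent oracle: inverse-gamma(n_a/2, effect^2/2) via 1/rgamma
  set.seed(22)
  oracle <- 1 / stats::rgamma(1e5, shape = 0.475, rate = 0.5)
  D <- ks_stat(draws, stats::ecdf(oracle))
  expect_lt(D, 0.01)
  # scale family: draws at effect 2 are 4x draws at effect 1
  set.seed(23); d1 <- epiqtl:::draw_effect_variance(rep(1, 1e5), 0.95)
  set.seed(23); d2 <- epiqtl:::draw_effect_variance(rep(2, 1e5), 0.95)
  expect_equal(d2, 4 * d1)
  # zero effect degenerates to the floor
  expect_equal(epiqtl:::draw_effect_variance(0, 0.95, 1e-12), 1e-12)
})

test_that("residual-variance draws match the inverse-gamma oracle and
           concentrate at S/df for large df", {
  n <- 100; n_a <- 0.95; S <- 250
  set.seed(31)
  draws <- replicate(50000, epiqtl:::draw_residual_variance(S, n, n_a))
  set.seed(32)
  oracle <- 1 / stats::rgamma(50000, shape = (n_a + n - 1) / 2, rate = S / 2)
  expect_lt(ks_stat(draws, stats::ecdf(oracle)), 0.01)
  # chi-square concentration at large degrees of freedom
  set.seed(33)
  big <- replicate(2000, epiqtl:::draw_residual_variance(1e4, 1e4, n_a))
  expect_equal(mean(big), 1e4 / (1e4 + n_a - 1), tolerance = 0.01)
})

test_that("genotype conditional equals the flanking-marker enumeration", {
  # one interval, both flanking distances 10 cM; oracle built from the
  # enumeration transition matrices: prior(g) P(mL | g) P(mR | g) x lik
  r <- recomb_fraction(10)
  for (dsn in c("f2", "f2:3")) {
    Hor <- if (dsn == "f2") f2_transition_oracle(r) else
      f23_transition_oracle(r)
    pg <- unname(genotype_prior(dsn))
    pm <- c(0.25, 0.5, 0.25)
    Mor <- t(Hor * pm) / pg            # P(m | g) by Bayes inversion
    lg <- epiqtl:::log_mgq(r, dsn == "f2:3")
    for (mL in 1:3) for (mR in 1:3) {
      lw <- epiqtl:::geno_logweights(mL, mR, lg, lg, log(pg))
      got <- exp(lw[1, ]) / sum(exp(lw[1, ]))
      want <- pg * Mor[, mL] * Mor[, mR]
      expect_equal(got, want / sum(want), tolerance = 1e-10)
    }
  }
  # a missing flank drops its factor: prior x one transition only
  lg <- epiqtl:::log_mgq(r, FALSE)
  pg <- c(0.25, 0.5, 0.25)
  lw <- epiqtl:::geno_logweights(NA_integer_, 1L, lg, lg, log(pg))
  want <- pg * exp(lg[, 1])
  expect_equal(exp(lw[1, ]) / sum(exp(lw[1, ])), want / sum(want),
               tolerance = 1e-12)
})

test_that("fully informative flanks at r ~ 0 pin the imputed genotype", {
  # single 0.002-cM interval: the QTL genotype must copy the marker codes
  map <- linkage_map(c("a", "b"), c(1, 1), c(0, 0.002))
  n <- 30
  set.seed(2)
  g <- simulate_genotypes(map, n, "f2")
  expect_identical(g[, 1], g[, 2])
  y <- rnorm(n)
  ch <- run_rjmcmc(y, g, map,
                   config = sampler_config(burn_in = 5, thin = 1,
                                           retained = 40, seed = 6))
  # posterior-mean additive code equals the marker code for everyone
  expect_equal(drop(ch$xbar), as.numeric(g[, 1]), tolerance = 1e-12)
})

test_that("position samples follow the grid-evaluated marginal posterior", {
  # one 20-cM interval: with all effects irrelevant (flat dimension moves
  # never add pairs in a 1-interval map, and y is pure noise), the sampler's
  # lambda marginal is proportional to prod_i sum_g prior(g) P(mL|g) P(mR|g);
  # compare the retained lambda histogram to that grid profile
  map <- linkage_map(c("a", "b"), c(1, 1), c(0, 20))
  n <- 120
  set.seed(14)
  g <- simulate_genotypes(map, n, "f2")
  y <- rnorm(n)
  ch <- run_rjmcmc(y, g, map,
                   config = sampler_config(burn_in = 500, thin = 2,
                                           retained = 8000, seed = 15))
  iL <- 2 - g[, 1]; iR <- 2 - g[, 2]
  grid <- seq(0.25, 19.75, by = 0.5)
  logpost <- vapply(grid, function(lam) {
    lgL <- epiqtl:::log_mgq(recomb_fraction(lam), FALSE)
    lgR <- epiqtl:::log_mgq(recomb_fraction(20 - lam), FALSE)
    lw <- epiqtl:::geno_logweights(iL, iR, lgL, lgR,
                                   log(c(0.25, 0.5, 0.25)))
    sum(epiqtl:::row_logsumexp3(lw))
  }, numeric(1))
  want <- exp(logpost - max(logpost))
  want <- want / sum(want)
  got <- tabulate(findInterval(ch$lambda[, 1], seq(0, 20, by = 0.5)),
                  length(grid))
  got <- got / sum(got)
  # total-variation distance between histogram and grid posterior
  expect_lt(0.5 * sum(abs(got - want)), 0.1)
})

test_that("the flat-likelihood dimension chain visits pairs uniformly", {
  b <- small_cross(10, seed = 12)
  ch <- run_rjmcmc(b$pheno, b$geno, b$map,
                   config = sampler_config(burn_in = 0, thin = 1,
                                           retained = 20000, seed = 13),
                   dimension_likelihood = "flat", fix_phi = 2)
  inc <- ch$inclusion[upper.tri(ch$inclusion)]
  expect_true(all(inc > 0))          # exhaustive visiting of the pair space
  # no pair is favoured: counts within 3 sigma of uniform sharing
  expect_lt(max(abs(inc - mean(inc))) / sd(inc), 4.5)
})
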