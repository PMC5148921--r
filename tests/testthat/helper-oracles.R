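# Independent oracles and small fixtures used across the suite.

# --- exhaustive-enumeration oracles for the transition matrices -------------
# Gametes are (m, q) allele pairs, 1 = the capital allele.  An F1 meiosis
# emits coupling gametes with probability (1 - r) / 2 each and recombinants
# with r / 2 each.

f1_gamete_table <- function(r) {
  g <- expand.grid(m = c(1L, 0L), q = c(1L, 0L))
  g$p <- ifelse(g$m == g$q, (1 - r) / 2, r / 2)
  g
}

code_idx <- function(allele_count) 4L - (allele_count + 1L)  # 2,1,0 -> 1,2,3

# F2: conditional P(QTL genotype | marker genotype) by enumerating the two
# independent F1 gametes of an F2 individual.
f2_transition_oracle <- function(r) {
  gam <- f1_gamete_table(r)
  J <- matrix(0, 3, 3)
  for (i in seq_len(4)) for (j in seq_len(4)) {
    mi <- code_idx(gam$m[i] + gam$m[j])
    qi <- code_idx(gam$q[i] + gam$q[j])
    J[mi, qi] <- J[mi, qi] + gam$p[i] * gam$p[j]
  }
  J / rowSums(J)
}

# F2:3: enumerate the F2 parent (all F1 gamete pairs), self it with one
# independent recombinant meiosis per parental gamete, and tabulate the
# progeny QTL genotype against the parent's marker genotype.
f23_transition_oracle <- function(r) {
  gam <- f1_gamete_table(r)
  J <- matrix(0, 3, 3)
  for (i in seq_len(4)) for (j in seq_len(4)) {
    pp <- gam$p[i] * gam$p[j]
    h1 <- c(gam$m[i], gam$q[i]); h2 <- c(gam$m[j], gam$q[j])
    # gamete distribution of the selfed parent
    gd <- rbind(c(h1, (1 - r) / 2), c(h2, (1 - r) / 2),
                c(h1[1], h2[2], r / 2), c(h2[1], h1[2], r / 2))
    mi <- code_idx(h1[1] + h2[1])
    for (u in seq_len(4)) for (v in seq_len(4)) {
      qi <- code_idx(gd[u, 2] + gd[v, 2])
      J[mi, qi] <- J[mi, qi] + pp * gd[u, 3] * gd[v, 3]
    }
  }
  J / rowSums(J)
}

# --- grid-density CDF oracle for Kolmogorov-Smirnov checks ------------------

# Numerically integrate an unnormalised log-density over a grid and return
# an interpolating CDF.
grid_cdf <- function(logdens, lo, hi, m = 8001) {
  xs <- seq(lo, hi, length.out = m)
  ld <- vapply(xs, logdens, numeric(1))
  ld <- ld - max(ld)
  dens <- exp(ld)
  cum <- cumsum((dens[-1] + dens[-m]) / 2 * diff(xs))
  cum <- c(0, cum) / cum[m - 1]
  function(q) stats::approx(xs, cum, xout = q, yleft = 0, yright = 1)$y
}

# One-sample Kolmogorov-Smirnov statistic against an arbitrary CDF.
ks_stat <- function(draws, cdf) {
  x <- sort(draws)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# --- small fixtures ---------------------------------------------------------

# The n = 5 fixture used by the conditional-distribution oracles: a fixed
# tiny regression problem with known covariates and residuals.
toy_fixture <- function() {
  list(y = c(1.2, -0.7, 0.4, 2.1, -1.5),
       cc = c(1, 0, -1, 1, -1),          # an additive-type covariate
       ww = c(-0.5, 0.5, -0.5, -0.5, 0.5),
       sigma2 = 1.3, effect_var = 0.8)
}

# A two-group, six-markers-per-group map on a 10-cM grid.
two_group_map <- function() {
  linkage_map(sprintf("m%d_%d", rep(1:2, each = 6), rep(1:6, 2)),
              rep(1:2, each = 6), rep(10 * (0:5), 2))
}

# A map with the stated marker/group layout (sizes per group).
sized_map <- function(sizes, spacing = 10) {
  linkage_map(
    unlist(lapply(seq_along(sizes), function(g)
      sprintf("g%dm%d", g, seq_len(sizes[g])))),
    rep(seq_along(sizes), sizes),
    unlist(lapply(sizes, function(s) spacing * (seq_len(s) - 1))))
}

# A minimal synthetic chain record for the postprocess unit tests.
fake_chain <- function(a, d, lambda, map, epi = NULL, sigma2 = NULL,
                       xbar = NULL, wbar = NULL, N = nrow(a)) {
  itab <- epiqtl:::interval_table(map)
  p <- nrow(itab)
  if (is.null(epi))
    epi <- data.frame(sample = integer(), k1 = integer(), k2 = integer(),
                      aa = numeric(), ad = numeric(), da = numeric(),
                      dd = numeric())
  incl <- matrix(0L, p, p)
  if (nrow(epi)) {
    tb <- table(factor(epi$k1, levels = 1:p), factor(epi$k2, levels = 1:p))
    incl <- matrix(as.integer(tb), p, p)
    incl <- incl + t(incl)
  }
  if (is.null(sigma2)) sigma2 <- rep(1, N)
  n_ind <- if (is.null(xbar)) 2L else nrow(xbar)
  if (is.null(xbar)) xbar <- matrix(0, n_ind, p)
  if (is.null(wbar)) wbar <- matrix(0, n_ind, p)
  structure(list(
    samples = data.frame(sample = seq_len(N), iteration = seq_len(N),
                         mu = rep(0, N), sigma2 = sigma2,
                         phi = rep(1, N),
                         t = as.integer(tabulate(epi$sample, N))),
    a = a, d = d, lambda = lambda,
    sa2 = a * 0 + 1, sd2 = d * 0 + 1,
    epi = epi, inclusion = incl, N = N,
    t_trace = integer(0), xbar = xbar, wbar = wbar,
    map = map, intervals = itab, design = "f2",
    priors = prior_config(), config = sampler_config(0, 1, N),
    map_function = "kosambi"), class = "qtl_chain")
}
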