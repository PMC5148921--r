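# Reversible-jump Gibbs/Metropolis sampler over the epistatic QTL model.
#
# Fixed part: one latent QTL per marker interval with additive and dominance
# effects under the F2 metric, each with its own shrinkage variance.
# Trans-dimensional part: a variable-size set of interval pairs, each pair
# carrying the four epistatic effects (aa, ad, da, dd); pairs are proposed
# for addition and deletion every iteration, with a truncated Poisson prior
# on the pair count whose mean gets a conjugate Gamma update.
#
# Two engines implement the identical update schedule: a readable R
# reference and a compiled C++ port.  Both consume R's RNG stream in the
# same order, so for a given seed they realise the same chain; tiny
# floating-point summation differences (R accumulates in long double)
# eventually amplify, so cross-engine agreement is asserted over a short
# horizon in the test suite.

#' Prior and proposal configuration
#'
#' @param n_a degrees-of-freedom correction for the per-effect scaled
#'   inverse-chi-square hyperpriors; must lie in (0, 1) so the corrected
#'   exponent Delta = (1 - n_a) / 2 stays in (0, 1/2) and the joint posterior
#'   is proper.  Default 0.95.
#' @param p_add,p_delete,p_stay prior move probabilities for the dimension
#'   change (must sum to 1; default 1/3 each).  They enter the
#'   Hastings-corrected acceptance ratios of the add and delete moves.
#' @param tau,upsilon shape and rate of the Gamma hyperprior on the Poisson
#'   mean of the pair count (default 1 and 1, giving the conjugate
#'   Gamma(t + 1, 2) update).
#' @param position_tuning half-width d (cM) of the uniform random-walk
#'   proposal for QTL positions; usually 1-2 cM.
#' @param variance_floor lower bound applied to sampled variances.
#' @return list of class \code{"prior_config"}.
#' @export
prior_config <- function(n_a = 0.95, p_add = 1/3, p_delete = 1/3,
                         p_stay = 1/3, tau = 1, upsilon = 1,
                         position_tuning = 2, variance_floor = 1e-12) {
  if (n_a <= 0 || n_a >= 1) stop("n_a must lie in (0, 1)")
  if (abs(p_add + p_delete + p_stay - 1) > 1e-12)
    stop("move probabilities must sum to 1")
  if (position_tuning <= 0) stop("position_tuning must be > 0")
  structure(list(n_a = n_a, p_add = p_add, p_delete = p_delete,
                 p_stay = p_stay, tau = tau, upsilon = upsilon,
                 position_tuning = position_tuning,
                 variance_floor = variance_floor),
            class = "prior_config")
}

#' Chain-length configuration
#'
#' Default follows the study protocol: 10,000 burn-in iterations, then one
#' retained sample every 20 iterations until 18,000 samples are kept
#' (370,000 iterations in total).
#'
#' @param burn_in discarded initial iterations.
#' @param thin keep one sample every \code{thin} iterations after burn-in.
#' @param retained number of retained samples.
#' @param seed integer seed; the run is bit-reproducible from it.
#' @return list of class \code{"sampler_config"}.
#' @export
sampler_config <- function(burn_in = 10000, thin = 20, retained = 18000,
                           seed = 1) {
  stopifnot(burn_in >= 0, thin >= 1, retained >= 1)
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 retained = as.integer(retained), seed = as.integer(seed)),
            class = "sampler_config")
}

# ---- small full-conditional draws (the R engine's building blocks, also ----
# ---- exercised directly by the distribution-oracle tests)              ----

# Ridge-form Normal draw for one effect with covariate column cc against the
# partial residual (residual with this effect's contribution added back):
# precision weight S = sum(cc^2) + sigma2 / effect_var,
# mean = S^-1 sum(cc * resid_part), variance = S^-1 sigma2.
ridge_draw <- function(cc, resid_part, sigma2, effect_var) {
  S <- sum(cc * cc) + sigma2 / effect_var
  stats::rnorm(1, sum(cc * resid_part) / S, sqrt(sigma2 / S))
}

# Per-effect shrinkage variance: scaled inverse-chi-square with n_a degrees
# of freedom and scale effect^2, i.e. effect^2 / chisq(n_a); floored.
draw_effect_variance <- function(effect, n_a, floor = 1e-12) {
  v <- effect^2 / stats::rchisq(length(effect), n_a)
  v[!is.finite(v)] <- 1e12
  pmax(v, floor)
}

# Residual variance: ee / chisq(n_a + n - 1).
draw_residual_variance <- function(ee, n, n_a, floor = 1e-12) {
  max(ee / stats::rchisq(1, n_a + n - 1), floor)
}

# Log acceptance ratio of the add move (t -> t + 1):
# likelihood ratio x phi/(t+1) x p_d/((t+1) p_a).
add_logalpha <- function(loglik_ratio, t, phi, p_add, p_delete) {
  loglik_ratio + log(phi) - 2 * log(t + 1) + log(p_delete) - log(p_add)
}

# Log acceptance ratio of the delete move (t -> t - 1):
# likelihood ratio x t/phi x p_a t / p_d.
delete_logalpha <- function(loglik_ratio, t, phi, p_add, p_delete) {
  loglik_ratio + 2 * log(t) - log(phi) + log(p_add) - log(p_delete)
}

# One uniform draw over 1..m that consumes exactly one deviate (mirrors the
# compiled engine, keeping the two RNG streams aligned).
unif_index1 <- function(m) {
  1L + min(m - 1L, as.integer(floor(stats::runif(1) * m)))
}

# ---- fast transition matrices ---------------------------------------------

# log P(marker | QTL) as a 3x3 matrix [qtl, marker], codes ordered (1,0,-1).
# Closed forms from the two-locus F2 joint (and one selfing generation for
# F2:3); algebraically identical to marker_given_qtl() which builds them from
# first principles -- the closed forms avoid per-iteration enumeration.
log_mgq <- function(r, f23) {
  if (!f23) {
    # symmetric joint: P(m|g) matrix equals P(g|m)
    M <- matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
                  r * (1 - r), 1 - 2 * r + 2 * r^2, r * (1 - r),
                  r^2, 2 * r * (1 - r), (1 - r)^2),
                3, 3, byrow = TRUE)
  } else {
    # H = P(g_progeny | m_parent); invert with parent-marker marginal
    # (1/4, 1/2, 1/4) and progeny prior (3/8, 1/4, 3/8)
    h11 <- (1 - r) * (2 - r) / 2
    h12 <- r * (1 - r)
    h13 <- r * (1 + r) / 2
    h21 <- (1 + 2 * r - 2 * r^2) / 4
    h22 <- (1 - 2 * r + 2 * r^2) / 2
    H <- matrix(c(h11, h12, h13,
                  h21, h22, h21,
                  h13, h12, h11),
                3, 3, byrow = TRUE)
    pm <- c(0.25, 0.5, 0.25)
    pg <- c(0.375, 0.25, 0.375)
    M <- t(H * pm) / pg
  }
  log(M)
}

# ---- vectorised helpers over the 3 genotype codes -------------------------

X_CODES <- c(1, 0, -1)
W_CODES <- c(-0.5, 0.5, -0.5)

# n x 3 log prior-transition weights for one interval: log prior(g) +
# log P(mL | g) + log P(mR | g); a missing flank contributes nothing.
geno_logweights <- function(iL, iR, lgL, lgR, lprior) {
  n <- length(iL)
  lw <- matrix(rep(lprior, each = n), n, 3)
  naL <- is.na(iL); naR <- is.na(iR)
  if (any(naL)) iL[naL] <- 1L
  if (any(naR)) iR[naR] <- 1L
  for (j in 1:3) {
    tl <- lgL[j, iL]; tr <- lgR[j, iR]
    if (any(naL)) tl[naL] <- 0
    if (any(naR)) tr[naR] <- 0
    lw[, j] <- lw[, j] + tl + tr
  }
  lw
}

row_logsumexp3 <- function(lw) {
  m <- pmax(lw[, 1], lw[, 2], lw[, 3])
  m + log(exp(lw[, 1] - m) + exp(lw[, 2] - m) + exp(lw[, 3] - m))
}

sample_categorical3 <- function(lw) {
  m <- pmax(lw[, 1], lw[, 2], lw[, 3])
  p1 <- exp(lw[, 1] - m); p2 <- exp(lw[, 2] - m); p3 <- exp(lw[, 3] - m)
  u <- stats::runif(nrow(lw)) * (p1 + p2 + p3)
  1L + (u > p1) + (u > p1 + p2)
}

# ---- the sampler -----------------------------------------------------------

#' Run the reversible-jump sampler
#'
#' Per iteration the sampler executes, in order: the grand-mean draw, the
#' additive and dominance effect draws for every interval, the refresh of
#' every active pair's four epistatic effects, one add proposal and one
#' delete proposal for the epistatic pair set, the per-effect
#' shrinkage-variance draws, the residual-variance draw, the QTL-genotype
#' imputation per interval from the flanking markers, the
#' Metropolis-Hastings position update per interval, and the conjugate
#' Gamma update of the Poisson mean of the pair count.  All acceptance
#' ratios are computed in log space.
#'
#' @param y numeric phenotype vector.
#' @param geno marker genotype matrix (individuals x markers, codes 1/0/-1,
#'   NA = missing), columns named by the map's markers.
#' @param map a \code{\link{linkage_map}}.
#' @param design \code{"f2"} or \code{"f2:3"}.
#' @param priors a \code{\link{prior_config}}.
#' @param config a \code{\link{sampler_config}}.
#' @param map_function map function used for marker-QTL distances.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"} (reference
#'   implementation); both draw from the same RNG stream and realise the
#'   same chain for a given seed (agreement to near machine precision over
#'   hundreds of iterations, after which floating-point round-off decouples
#'   the trajectories).
#' @param dimension_likelihood \code{"data"} (default) uses the Gaussian
#'   likelihood ratio in the add/delete decisions; \code{"flat"} forces that
#'   ratio to 1, a validation mode that lets the dimension chain be compared
#'   against its exact prior-driven kernel.
#' @param fix_phi optional fixed value for the Poisson mean (suppresses its
#'   Gamma update); used with \code{dimension_likelihood = "flat"} for
#'   kernel validation.
#' @return object of class \code{"qtl_chain"}; see Details.
#' @details The returned chain record holds: \code{samples} (data frame with
#'   one row per retained sample: iteration, mu, sigma2, phi, t), matrices
#'   \code{a}, \code{d}, \code{lambda}, \code{sa2}, \code{sd2} (retained x
#'   intervals), \code{epi} (long data frame: sample, k1, k2, aa, ad, da,
#'   dd), \code{inclusion} (p x p symmetric matrix of per-pair inclusion
#'   counts), \code{N} (retained total), \code{t_trace} (pair count at every
#'   iteration), posterior-mean design codes \code{xbar}, \code{wbar}, and
#'   the inputs needed to interpret them (\code{map}, \code{intervals},
#'   \code{design}, \code{priors}, \code{config}).
#' @export
run_rjmcmc <- function(y, geno, map, design = c("f2", "f2:3"),
                       priors = prior_config(), config = sampler_config(),
                       map_function = c("kosambi", "haldane"),
                       engine = c("cpp", "r"),
                       dimension_likelihood = c("data", "flat"),
                       fix_phi = NULL) {
  design <- match_design(design)
  map_function <- match.arg(map_function)
  engine <- match.arg(engine)
  dimension_likelihood <- match.arg(dimension_likelihood)
  f23 <- design == "f2:3"
  stopifnot(inherits(map, "linkage_map"), is.numeric(y), !anyNA(y))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(geno) != n) stop("genotype rows must match phenotype length")
  if (!all(map$marker %in% colnames(geno)))
    stop("genotype matrix lacks map marker(s): ",
         paste(setdiff(map$marker, colnames(geno)), collapse = ", "))
  geno <- geno[, map$marker, drop = FALSE]
  if (!all(geno[!is.na(geno)] %in% c(1, 0, -1)))
    stop("genotype codes must be 1, 0, -1 or NA")
  vy <- stats::var(y)
  if (vy == 0) stop("phenotype is constant: var(y) = 0")

  itab <- interval_table(map)
  p <- nrow(itab)
  np <- p * (p - 1L) %/% 2L
  pair_idx <- which(upper.tri(diag(p)), arr.ind = TRUE)   # k1 < k2
  ord <- order(pair_idx[, 1], pair_idx[, 2])
  pair_k1 <- pair_idx[ord, 1]; pair_k2 <- pair_idx[ord, 2]

  # flanking-marker index matrices (code 1,0,-1 -> index 1,2,3; NA where
  # the flank is missing)
  iL <- 2L - geno[, itab$left, drop = FALSE]
  iR <- 2L - geno[, itab$right, drop = FALSE]

  set.seed(config$seed)
  args <- list(y = y, iL = iL, iR = iR, low = itab$lower, upp = itab$upper,
               pair_k1 = pair_k1, pair_k2 = pair_k2, f23 = f23,
               kosambi = map_function == "kosambi",
               lprior = log(unname(genotype_prior(design))),
               n_a = priors$n_a, eps = priors$variance_floor,
               p_a = priors$p_add, p_d = priors$p_delete,
               dtune = priors$position_tuning, vy = vy,
               phi0 = if (is.null(fix_phi)) choose(p, 2) * 0.01 else fix_phi,
               update_phi = is.null(fix_phi),
               use_lik = dimension_likelihood == "data",
               burn_in = config$burn_in, thin = config$thin,
               retained = config$retained)
  res <- if (engine == "cpp") do.call(rjmcmc_engine_cpp, args)
         else do.call(rjmcmc_engine_r, args)

  R <- config$retained
  epi <- if (length(res$epi)) {
    m <- matrix(res$epi, ncol = 7, byrow = TRUE)
    data.frame(sample = as.integer(m[, 1]), k1 = as.integer(m[, 2]),
               k2 = as.integer(m[, 3]), aa = m[, 4], ad = m[, 5],
               da = m[, 6], dd = m[, 7])
  } else {
    data.frame(sample = integer(), k1 = integer(), k2 = integer(),
               aa = numeric(), ad = numeric(), da = numeric(),
               dd = numeric())
  }
  incl <- res$incl + t(res$incl)

  structure(list(
    samples = data.frame(sample = seq_len(R), iteration = res$s_it,
                         mu = res$s_mu, sigma2 = res$s_sig,
                         phi = res$s_phi, t = res$s_t),
    a = res$s_a, d = res$s_d, lambda = res$s_lam,
    sa2 = res$s_sa2, sd2 = res$s_sd2,
    epi = epi, inclusion = incl, N = R, t_trace = res$t_trace,
    xbar = res$xsum / R, wbar = res$wsum / R,
    map = map, intervals = itab, design = design,
    priors = priors, config = config, map_function = map_function),
    class = "qtl_chain")
}

# The R reference engine.  The compiled engine in src/rjmcmc.cpp mirrors
# this function statement by statement, drawing from the same RNG stream.
rjmcmc_engine_r <- function(y, iL, iR, low, upp, pair_k1, pair_k2, f23,
                            kosambi, lprior, n_a, eps, p_a, p_d, dtune, vy,
                            phi0, update_phi, use_lik, burn_in, thin,
                            retained) {
  n <- length(y); p <- length(low); np <- length(pair_k1)
  total <- burn_in + retained * thin
  rf <- if (kosambi) function(dd) 0.5 * tanh(0.02 * dd)
        else function(dd) 0.5 * (1 - exp(-0.02 * dd))
  lp1 <- lprior[1]; lp2 <- lprior[2]; lp3 <- lprior[3]
  iL_list <- lapply(seq_len(p), function(k) iL[, k])
  iR_list <- lapply(seq_len(p), function(k) iR[, k])
  naL <- lapply(iL_list, is.na); naR <- lapply(iR_list, is.na)
  has_na <- vapply(seq_len(p), function(k) any(naL[[k]]) || any(naR[[k]]),
                   logical(1))
  for (k in seq_len(p)) {
    iL_list[[k]][naL[[k]]] <- 1L
    iR_list[[k]][naR[[k]]] <- 1L
  }
  prior_lw3 <- function(k, lam) {
    gL <- log_mgq(rf(lam - low[k]), f23)
    gR <- log_mgq(rf(upp[k] - lam), f23)
    tl1 <- gL[1L, iL_list[[k]]]; tl2 <- gL[2L, iL_list[[k]]]
    tl3 <- gL[3L, iL_list[[k]]]
    tr1 <- gR[1L, iR_list[[k]]]; tr2 <- gR[2L, iR_list[[k]]]
    tr3 <- gR[3L, iR_list[[k]]]
    if (has_na[k]) {
      z <- naL[[k]]
      tl1[z] <- 0; tl2[z] <- 0; tl3[z] <- 0
      z <- naR[[k]]
      tr1[z] <- 0; tr2[z] <- 0; tr3[z] <- 0
    }
    list(lp1 + tl1 + tr1, lp2 + tl2 + tr2, lp3 + tl3 + tr3)
  }
  sample_lw3 <- function(lw) {
    m <- pmax.int(pmax.int(lw[[1]], lw[[2]]), lw[[3]])
    q1 <- exp(lw[[1]] - m); q2 <- exp(lw[[2]] - m); q3 <- exp(lw[[3]] - m)
    u <- stats::runif(n) * (q1 + q2 + q3)
    1L + (u > q1) + (u > q1 + q2)
  }
  lw3_loglik <- function(lw, gqk) {
    m <- pmax.int(pmax.int(lw[[1]], lw[[2]]), lw[[3]])
    lse <- m + log(exp(lw[[1]] - m) + exp(lw[[2]] - m) + exp(lw[[3]] - m))
    val <- lw[[1]]
    i2 <- gqk == 2L; val[i2] <- lw[[2]][i2]
    i3 <- gqk == 3L; val[i3] <- lw[[3]][i3]
    sum(val) - sum(lse)
  }

  # --- initialization: additive-dominant model only, t = 0; genotypes from
  #     prior x transitions at the interval midpoints (likelihood ignored)
  mu <- mean(y)
  a <- numeric(p); d <- numeric(p)
  sa2 <- rep(vy * 1e-5 / p, p); sd2 <- rep(vy * 1e-5 / p, p)
  sigma2 <- vy
  phi <- phi0
  lambda <- (low + upp) / 2
  gq <- matrix(1L, n, p)
  for (k in seq_len(p)) gq[, k] <- sample_lw3(prior_lw3(k, lambda[k]))
  x <- matrix(X_CODES[gq], n, p)
  w <- matrix(W_CODES[gq], n, p)

  act <- logical(np)
  act_id <- integer(0)
  theta <- matrix(0, 0, 4)
  evar <- matrix(0, 0, 4)
  t_cur <- 0L

  pair_contrib <- function(j) {
    k1 <- pair_k1[act_id[j]]; k2 <- pair_k2[act_id[j]]
    x[, k1] * x[, k2] * theta[j, 1] + x[, k1] * w[, k2] * theta[j, 2] +
      w[, k1] * x[, k2] * theta[j, 3] + w[, k1] * w[, k2] * theta[j, 4]
  }

  R <- retained
  s_mu <- numeric(R); s_sig <- numeric(R); s_phi <- numeric(R)
  s_t <- integer(R); s_it <- integer(R)
  s_a <- matrix(0, R, p); s_d <- matrix(0, R, p); s_lam <- matrix(0, R, p)
  s_sa2 <- matrix(0, R, p); s_sd2 <- matrix(0, R, p)
  epi_rec <- list()
  incl <- matrix(0L, p, p)
  xsum <- matrix(0, n, p); wsum <- matrix(0, n, p)
  t_trace <- integer(total)
  kept <- 0L

  for (iter in seq_len(total)) {
    # full-model residual, rebuilt exactly once per iteration
    e <- y - mu - drop(x %*% a) - drop(w %*% d)
    if (t_cur > 0L) for (j in seq_len(t_cur)) e <- e - pair_contrib(j)

    # 1. grand mean
    gm <- mean(e) + mu
    mu_new <- stats::rnorm(1, gm, sqrt(sigma2 / n))
    e <- e + (mu - mu_new); mu <- mu_new

    # 2. main effects, additive then dominance per interval
    for (k in seq_len(p)) {
      cc <- x[, k]; rp <- e + cc * a[k]
      anew <- ridge_draw(cc, rp, sigma2, sa2[k])
      e <- rp - cc * anew; a[k] <- anew
      cc <- w[, k]; rp <- e + cc * d[k]
      dnew <- ridge_draw(cc, rp, sigma2, sd2[k])
      e <- rp - cc * dnew; d[k] <- dnew
    }

    # 3. refresh the four epistatic effects of every active pair from
    #    their ridge-form conditionals (sequential within a pair)
    if (t_cur > 0L) for (j in seq_len(t_cur)) {
      k1 <- pair_k1[act_id[j]]; k2 <- pair_k2[act_id[j]]
      covs <- list(x[, k1] * x[, k2], x[, k1] * w[, k2],
                   w[, k1] * x[, k2], w[, k1] * w[, k2])
      for (m in 1:4) {
        cc <- covs[[m]]; rp <- e + cc * theta[j, m]
        tnew <- ridge_draw(cc, rp, sigma2, evar[j, m])
        e <- rp - cc * tnew; theta[j, m] <- tnew
      }
    }

    # 4. add proposal: uniform draw among inactive pairs, fresh effects
    if (t_cur < np) {
      id <- if (t_cur == 0L) unif_index1(np) else {
        inact <- which(!act)
        inact[unif_index1(length(inact))]
      }
      k1 <- pair_k1[id]; k2 <- pair_k2[id]
      covs <- list(x[, k1] * x[, k2], x[, k1] * w[, k2],
                   w[, k1] * x[, k2], w[, k1] * w[, k2])
      # birth variances at var(y): the proposed effects are drawn nearly
      # unshrunken, so a pair that genuinely improves the fit is caught the
      # first time it is proposed (see the methods vignette)
      v0 <- vy
      th <- numeric(4); enew <- e
      for (j in 1:4) {
        th[j] <- ridge_draw(covs[[j]], enew, sigma2, v0)
        enew <- enew - covs[[j]] * th[j]
      }
      llr <- if (use_lik) -0.5 / sigma2 * (sum(enew^2) - sum(e^2)) else 0
      la <- add_logalpha(llr, t_cur, phi, p_a, p_d)
      if (log(stats::runif(1)) < la) {
        act[id] <- TRUE
        act_id <- c(act_id, id)
        theta <- rbind(theta, th, deparse.level = 0)
        evar <- rbind(evar, rep(v0, 4), deparse.level = 0)
        t_cur <- t_cur + 1L
        e <- enew
      }
    }

    # 5. delete proposal: uniform victim among active pairs
    if (t_cur >= 1L) {
      j <- unif_index1(t_cur)
      ewo <- e + pair_contrib(j)
      # likelihood ratio of the proposed (t - 1) model over the current
      # one, the direction required for reversibility against the add move
      llr <- if (use_lik) -0.5 / sigma2 * (sum(ewo^2) - sum(e^2)) else 0
      la <- delete_logalpha(llr, t_cur, phi, p_a, p_d)
      if (log(stats::runif(1)) < la) {
        act[act_id[j]] <- FALSE
        act_id <- act_id[-j]
        theta <- theta[-j, , drop = FALSE]
        evar <- evar[-j, , drop = FALSE]
        t_cur <- t_cur - 1L
        e <- ewo
      }
    }

    # 6. shrinkage variances for every term in the model
    sa2 <- draw_effect_variance(a, n_a, eps)
    sd2 <- draw_effect_variance(d, n_a, eps)
    if (t_cur > 0L)
      evar <- matrix(draw_effect_variance(as.vector(theta), n_a, eps),
                     t_cur, 4)

    # 7. residual variance
    sigma2 <- draw_residual_variance(sum(e * e), n, n_a, eps)

    # 8. genotype imputation per interval; the prior-transition weights are
    #    kept to price the position move afterwards
    ll_keep <- numeric(p)
    half_prec <- 0.5 / sigma2
    for (k in seq_len(p)) {
      lw <- prior_lw3(k, lambda[k])
      # per-individual slopes of the interval's contribution in x and w
      A <- rep.int(a[k], n); D <- rep.int(d[k], n)
      if (t_cur > 0L) for (j in seq_len(t_cur)) {
        pk1 <- pair_k1[act_id[j]]; pk2 <- pair_k2[act_id[j]]
        if (pk1 == k) {
          A <- A + x[, pk2] * theta[j, 1] + w[, pk2] * theta[j, 2]
          D <- D + x[, pk2] * theta[j, 3] + w[, pk2] * theta[j, 4]
        } else if (pk2 == k) {
          A <- A + x[, pk1] * theta[j, 1] + w[, pk1] * theta[j, 3]
          D <- D + x[, pk1] * theta[j, 2] + w[, pk1] * theta[j, 4]
        }
      }
      base <- e + x[, k] * A + w[, k] * D
      r1 <- base - A + 0.5 * D          # candidate residuals per code
      r2 <- base - 0.5 * D
      r3 <- base + A + 0.5 * D
      lw_lik <- list(lw[[1]] - half_prec * r1 * r1,
                     lw[[2]] - half_prec * r2 * r2,
                     lw[[3]] - half_prec * r3 * r3)
      idx <- sample_lw3(lw_lik)
      gq[, k] <- idx
      x[, k] <- X_CODES[idx]
      w[, k] <- W_CODES[idx]
      e <- base - x[, k] * A - w[, k] * D
      ll_keep[k] <- lw3_loglik(lw, idx)
    }

    # 9. M-H position update per interval (reflected uniform window with
    #    explicit Hastings length correction); uses the prior-transition
    #    weights only, since the likelihood does not involve lambda given
    #    the imputed genotypes
    for (k in seq_len(p)) {
      L <- low[k]; U <- upp[k]
      lo <- max(L, lambda[k] - dtune); hi <- min(U, lambda[k] + dtune)
      lam_star <- lo + (hi - lo) * stats::runif(1)
      lam_star <- min(max(lam_star, L + 1e-9), U - 1e-9)
      lo2 <- max(L, lam_star - dtune); hi2 <- min(U, lam_star + dtune)
      ll_new <- lw3_loglik(prior_lw3(k, lam_star), gq[, k])
      la <- ll_new - ll_keep[k] + log(hi - lo) - log(hi2 - lo2)
      if (log(stats::runif(1)) < la) lambda[k] <- lam_star
    }

    # 10. Poisson mean: conjugate Gamma-Poisson update
    if (update_phi) phi <- stats::rgamma(1, shape = t_cur + 1, rate = 2)

    t_trace[iter] <- t_cur

    if (iter > burn_in && (iter - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      s_it[kept] <- iter
      s_mu[kept] <- mu; s_sig[kept] <- sigma2
      s_phi[kept] <- phi; s_t[kept] <- t_cur
      s_a[kept, ] <- a; s_d[kept, ] <- d; s_lam[kept, ] <- lambda
      s_sa2[kept, ] <- sa2; s_sd2[kept, ] <- sd2
      if (t_cur > 0L) {
        kk1 <- pair_k1[act_id]; kk2 <- pair_k2[act_id]
        incl[cbind(kk1, kk2)] <- incl[cbind(kk1, kk2)] + 1L
        epi_rec[[length(epi_rec) + 1L]] <-
          as.vector(t(cbind(kept, kk1, kk2, theta)))
      }
      xsum <- xsum + x; wsum <- wsum + w
    }
  }

  list(s_mu = s_mu, s_sig = s_sig, s_phi = s_phi, s_t = s_t, s_it = s_it,
       s_a = s_a, s_d = s_d, s_lam = s_lam, s_sa2 = s_sa2, s_sd2 = s_sd2,
       epi = unlist(epi_rec), incl = incl, t_trace = t_trace,
       xsum = xsum, wsum = wsum)
}

#' @export
print.qtl_chain <- function(x, ...) {
  cat("RJMCMC chain:", x$N, "retained samples,", nrow(x$intervals),
      "intervals;", "mean pair count", round(mean(x$samples$t), 2), "\n")
  invisible(x)
}
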