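# Post-MCMC decision surfaces: Wald/LOD statistics per interval and per
# epistatic pair, 3-cM binned genome profiles weighted by posterior position
# visits, inclusion-count weighting of pair LODs, selection, heat-map and
# variance-component summaries.

#' LOD from a Wald statistic
#'
#' LOD = W / (2 ln 10).
#'
#' @param W non-negative Wald statistic (vectorised).
#' @return LOD score(s).
#' @export
lod_from_wald <- function(W) {
  if (any(W < 0)) stop("Wald statistic must be >= 0")
  W / (2 * log(10))
}

#' Inclusion-count weighted LOD
#'
#' LOD* = n LOD / N down-weights pairs that were rarely present in the model:
#' LOD* = LOD only when the pair was active in every retained sample.
#'
#' @param n inclusion count (0 <= n <= N).
#' @param LOD raw LOD.
#' @param N retained chain length.
#' @export
weighted_lod <- function(n, LOD, N) {
  if (N <= 0) stop("N must be > 0")
  if (any(n < 0 | n > N)) stop("inclusion count must lie in [0, N]")
  n * LOD / N
}

# Interval-wise Wald statistic from the posterior moments of the main-effect
# chains: W_k = abar_k^2 / var(a_k) + dbar_k^2 / var(d_k).
interval_wald <- function(chain) {
  am <- colMeans(chain$a); av <- apply(chain$a, 2, stats::var)
  dm <- colMeans(chain$d); dv <- apply(chain$d, 2, stats::var)
  W <- ifelse(av > 0, am^2 / av, 0) + ifelse(dv > 0, dm^2 / dv, 0)
  W
}

#' Interval LOD scores for main effects
#'
#' Per interval, the Wald statistic is built from the posterior means of the
#' additive and dominance chains against their posterior sample variances,
#' and converted to LOD.
#'
#' @param chain a \code{qtl_chain}.
#' @return data frame with columns \code{interval}, \code{group},
#'   \code{lod}.
#' @export
interval_lod <- function(chain) {
  stopifnot(inherits(chain, "qtl_chain"))
  data.frame(interval = seq_len(nrow(chain$intervals)),
             group = chain$intervals$group,
             lod = lod_from_wald(interval_wald(chain)))
}

#' Binned genome profile for main-effect QTL
#'
#' Each linkage group is tiled by 3-cM bins from its origin (last bin
#' truncated).  For each bin, f is the fraction of retained position samples
#' of the group's intervals that fall in the bin, and the profile value is f
#' weighted by the maximum interval LOD attained among those samples
#' (\code{weight = "frequency"}), or that maximum LOD alone
#' (\code{weight = "max_lod"}).
#'
#' @param chain a \code{qtl_chain}.
#' @param bin_cM bin width in cM (default 3).
#' @param weight combination rule, see above.
#' @return data frame of class \code{"lod_profile"}: \code{group},
#'   \code{bin_start}, \code{bin_end}, \code{position} (bin midpoint),
#'   \code{freq}, \code{max_lod}, \code{lod}.
#' @export
main_qtl_profile <- function(chain, bin_cM = 3,
                             weight = c("frequency", "max_lod")) {
  stopifnot(inherits(chain, "qtl_chain"))
  weight <- match.arg(weight)
  if (chain$N < 1) stop("empty chain")
  ilod <- lod_from_wald(interval_wald(chain))
  map <- chain$map; itab <- chain$intervals
  out <- list()
  for (g in unique(itab$group)) {
    pos <- map$position_cM[as.integer(map$group) == g]
    origin <- min(pos); span <- max(pos)
    starts <- seq(origin, span, by = bin_cM)
    starts <- starts[starts < span]
    ends <- pmin(starts + bin_cM, span)
    ks <- which(itab$group == g)
    lam <- chain$lambda[, ks, drop = FALSE]             # N x p_g
    lodm <- matrix(ilod[ks], nrow(lam), length(ks), byrow = TRUE)
    tot <- length(lam)
    fq <- ml <- numeric(length(starts))
    for (b in seq_along(starts)) {
      inb <- lam >= starts[b] & (lam < ends[b] | b == length(starts))
      fq[b] <- sum(inb) / tot
      ml[b] <- if (any(inb)) max(lodm[inb]) else 0
    }
    out[[length(out) + 1]] <-
      data.frame(group = g, bin_start = starts, bin_end = ends,
                 position = (starts + ends) / 2, freq = fq, max_lod = ml,
                 lod = if (weight == "frequency") fq * ml else ml)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("lod_profile", "data.frame")
  res
}

# Inclusion-conditional moments of the four epistatic effects of one pair.
pair_moments <- function(chain, k1, k2) {
  sub <- chain$epi[chain$epi$k1 == k1 & chain$epi$k2 == k2, , drop = FALSE]
  list(n = nrow(sub),
       mean = if (nrow(sub)) colMeans(sub[, c("aa", "ad", "da", "dd")])
              else rep(0, 4),
       var = if (nrow(sub) >= 2)
               apply(sub[, c("aa", "ad", "da", "dd")], 2, stats::var)
             else rep(NA_real_, 4))
}

#' Epistatic LOD for one pair
#'
#' Wald statistic over the pair's four effects using inclusion-conditional
#' sample moments (samples in which the pair was active), with a diagonal
#' variance matrix; LOD = W / (2 ln 10).  Pairs visited fewer than twice
#' have undefined moments and report LOD 0 with \code{defined = FALSE}.
#'
#' @param chain a \code{qtl_chain}.
#' @param k1,k2 interval indices of the pair (order-free).
#' @return list with \code{lod}, \code{n}, \code{defined}.
#' @export
epistasis_lod <- function(chain, k1, k2) {
  stopifnot(inherits(chain, "qtl_chain"))
  kk <- sort(c(k1, k2))
  m <- pair_moments(chain, kk[1], kk[2])
  if (m$n < 2)
    return(list(lod = 0, n = m$n, defined = FALSE))
  ok <- m$var > 0 & is.finite(m$var)
  W <- sum(m$mean[ok]^2 / m$var[ok])
  list(lod = lod_from_wald(W), n = m$n, defined = TRUE)
}

#' Summary table of all visited epistatic pairs
#'
#' One row per pair with positive inclusion count: inclusion count n,
#' reference chain length N, raw LOD, weighted LOD* = n LOD / N, posterior
#' (inclusion-conditional) effect means, and the selection flag from
#' \code{\link{select_epistasis}} thresholds.
#'
#' @param chain a \code{qtl_chain}.
#' @param chain_min,lod_min selection thresholds (strict inequalities);
#'   defaults 400 and 3.
#' @return data frame of class \code{"epistasis_summary"} sorted by
#'   \code{lod_star} descending.
#' @export
summarize_epistasis <- function(chain, chain_min = 400, lod_min = 3) {
  stopifnot(inherits(chain, "qtl_chain"))
  idx <- which(chain$inclusion > 0 & upper.tri(chain$inclusion),
               arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    k1 <- idx[i, 1]; k2 <- idx[i, 2]
    m <- pair_moments(chain, k1, k2)
    el <- epistasis_lod(chain, k1, k2)
    data.frame(k1 = k1, k2 = k2, n = chain$inclusion[k1, k2], N = chain$N,
               lod = el$lod, lod_star = weighted_lod(
                 chain$inclusion[k1, k2], el$lod, chain$N),
               aa = m$mean[1], ad = m$mean[2], da = m$mean[3],
               dd = m$mean[4])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(k1 = integer(), k2 = integer(), n = integer(), N = integer(),
               lod = numeric(), lod_star = numeric(), aa = numeric(),
               ad = numeric(), da = numeric(), dd = numeric())
  out$selected <- out$n > chain_min & out$lod > lod_min
  out <- out[order(-out$lod_star), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epistasis_summary", "data.frame")
  out
}

#' Select epistatic pairs by chain length, then LOD
#'
#' Two-stage rule: keep pairs whose inclusion count exceeds
#' \code{chain_min}, then among those the pairs with LOD above
#' \code{lod_min} (both strict), sorted by weighted LOD* descending.
#'
#' @param summaries an \code{epistasis_summary}.
#' @param chain_min,lod_min thresholds (defaults 400 and 3).
#' @export
select_epistasis <- function(summaries, chain_min = 400, lod_min = 3) {
  keep <- summaries[summaries$n > chain_min & summaries$lod > lod_min, ,
                    drop = FALSE]
  keep[order(-keep$lod_star), , drop = FALSE]
}

#' Heat-map matrix of inclusion counts
#'
#' @param chain a \code{qtl_chain}.
#' @return p x p symmetric matrix; entry (k1, k2) is the number of retained
#'   samples in which the pair was active, diagonal 0.
#' @export
heatmap_matrix <- function(chain) {
  stopifnot(inherits(chain, "qtl_chain"))
  chain$inclusion
}

#' Variance components at posterior-mean effects
#'
#' For each model component the fitted contribution per individual is built
#' from the posterior-mean effects and the posterior-mean design codes
#' (xbar, wbar, and their element-wise products for active pairs); the
#' component variance is the sample variance of that contribution across
#' individuals.  The residual component is the posterior mean of the sampled
#' residual variance.
#'
#' @param chain a \code{qtl_chain}.
#' @return data frame with columns \code{component}, \code{variance}.
#' @export
variance_components <- function(chain) {
  stopifnot(inherits(chain, "qtl_chain"))
  abar <- colMeans(chain$a); dbar <- colMeans(chain$d)
  g_add <- drop(chain$xbar %*% abar)
  g_dom <- drop(chain$wbar %*% dbar)
  g_epi <- matrix(0, length(g_add), 4)
  idx <- which(chain$inclusion > 0 & upper.tri(chain$inclusion),
               arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    k1 <- idx[i, 1]; k2 <- idx[i, 2]
    m <- pair_moments(chain, k1, k2)
    wgt <- chain$inclusion[k1, k2] / chain$N  # model-averaged contribution
    cv <- epistatic_covariates(chain$xbar[, k1], chain$wbar[, k1],
                               chain$xbar[, k2], chain$wbar[, k2])
    g_epi[, 1] <- g_epi[, 1] + wgt * cv$eta * m$mean[1]
    g_epi[, 2] <- g_epi[, 2] + wgt * cv$gamma * m$mean[2]
    g_epi[, 3] <- g_epi[, 3] + wgt * cv$varpi * m$mean[3]
    g_epi[, 4] <- g_epi[, 4] + wgt * cv$phi * m$mean[4]
  }
  g_tot <- g_add + g_dom + rowSums(g_epi)
  data.frame(
    component = c("additive", "dominance", "aa", "ad", "da", "dd",
                  "total_genetic", "residual"),
    variance = c(stats::var(g_add), stats::var(g_dom),
                 apply(g_epi, 2, stats::var), stats::var(g_tot),
                 mean(chain$samples$sigma2)))
}
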