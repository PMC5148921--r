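#' F2-metric design codes
#'
#' Maps genotype codes to the orthogonal-contrast (F2 metric) additive and
#' dominance codes: QQ (1) -> (x = 1, w = -1/2), Qq (0) -> (0, 1/2),
#' qq (-1) -> (-1, -1/2).  Under exact F2 frequencies (1/4, 1/2, 1/4) the
#' codes satisfy E[x] = E[w] = E[xw] = 0, so additive and dominance effects
#' are uncorrelated.
#'
#' @param genotype vector (or matrix) of codes in \{1, 0, -1\}; missing
#'   values are not allowed here -- genotypes are imputed upstream.
#' @return list with components \code{x} and \code{w}, same shape as input.
#' @examples
#' f2_metric(c(1, 0, -1))
#' @export
f2_metric <- function(genotype) {
  if (anyNA(genotype))
    stop("missing genotype codes: impute before coding")
  if (!all(genotype %in% c(1, 0, -1)))
    stop("genotype codes must be 1, 0 or -1")
  w <- ifelse(genotype == 0, 0.5, -0.5)
  if (is.matrix(genotype)) {
    x <- genotype
    storage.mode(x) <- "double"
    dim(w) <- dim(genotype)
    dimnames(w) <- dimnames(genotype)
  } else {
    x <- as.numeric(genotype)
  }
  list(x = x, w = w)
}

#' Epistatic covariates for a locus pair
#'
#' The four first-order epistatic covariates are element-wise products of the
#' additive and dominance codes of the two loci:
#' eta = x * x' (additive-additive), gamma = x * w' (additive-dominant),
#' varpi = w * x' (dominant-additive), phi = w * w' (dominant-dominant).
#'
#' @param x_k,w_k additive and dominance code vectors at the first locus.
#' @param x_k2,w_k2 codes at the second locus; all four must share a length.
#' @return list with components \code{eta}, \code{gamma}, \code{varpi},
#'   \code{phi}.
#' @export
epistatic_covariates <- function(x_k, w_k, x_k2, w_k2) {
  n <- length(x_k)
  if (length(w_k) != n || length(x_k2) != n || length(w_k2) != n)
    stop("covariate vectors must have equal length")
  list(eta = x_k * x_k2, gamma = x_k * w_k2,
       varpi = w_k * x_k2, phi = w_k * w_k2)
}
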