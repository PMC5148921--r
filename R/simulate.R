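# Cross simulator: F2 marker chains, optional selfing to F2:3, phenotypes
# assembled from the genetic model, and the two built-in study scenarios.

# One meiosis from an F1 (heterozygous everywhere): n haplotypes over the loci
# of one linkage group, Markov with switch probability r[j] between adjacent
# loci.  Alleles coded 1/0.
sim_f1_gametes <- function(n, rvec) {
  m <- length(rvec) + 1L
  h <- matrix(0L, n, m)
  h[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (j in seq_along(rvec)) {
    sw <- stats::rbinom(n, 1L, rvec[j])
    h[, j + 1L] <- ifelse(sw == 1L, 1L - h[, j], h[, j])
  }
  h
}

# One gamete from each of n selfed parents with haplotype pair (H1, H2):
# a recombinant walk choosing the source haplotype at each locus.
sim_selfing_gametes <- function(H1, H2, rvec) {
  n <- nrow(H1); m <- ncol(H1)
  src <- matrix(0L, n, m)
  src[, 1L] <- stats::rbinom(n, 1L, 0.5)
  for (j in seq_along(rvec)) {
    sw <- stats::rbinom(n, 1L, rvec[j])
    src[, j + 1L] <- ifelse(sw == 1L, 1L - src[, j], src[, j])
  }
  H1 * (1L - src) + H2 * src
}

#' Simulate marker genotypes for an intercross
#'
#' Genotypes follow the Markov chain over gametes implied by adjacent-marker
#' recombination fractions.  For an F2 each individual is the union of two
#' independent F1 gametes.  For F2:3 progenies, an F2 plant is simulated per
#' row and then selfed once (independent recombinant meioses per gamete);
#' each row is one F2:3 genotype draw.
#'
#' @param map a \code{\link{linkage_map}}.
#' @param n number of individuals.
#' @param design \code{"f2"} (default) or \code{"f2:3"}.
#' @param map_function map function for distance-to-recombination conversion.
#' @param missing_rate optional missing-at-random rate applied to the output
#'   (default 0; the study designs have complete marker data).
#' @return integer matrix n x markers with codes 1/0/-1 (and NA where
#'   missing), columns named by marker.
#' @export
simulate_genotypes <- function(map, n, design = c("f2", "f2:3"),
                               map_function = c("kosambi", "haldane"),
                               missing_rate = 0) {
  stopifnot(inherits(map, "linkage_map"), n >= 1)
  design <- match_design(design)
  map_function <- match.arg(map_function)
  gi <- as.integer(map$group)
  geno <- matrix(NA_integer_, n, nrow(map),
                 dimnames = list(NULL, map$marker))
  for (g in unique(gi)) {
    cols <- which(gi == g)
    rvec <- recomb_fraction(diff(map$position_cM[cols]), map_function)
    H1 <- sim_f1_gametes(n, rvec)
    H2 <- sim_f1_gametes(n, rvec)
    if (design == "f2:3") {
      G1 <- sim_selfing_gametes(H1, H2, rvec)
      G2 <- sim_selfing_gametes(H1, H2, rvec)
      geno[, cols] <- G1 + G2 - 1L
    } else {
      geno[, cols] <- H1 + H2 - 1L
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < missing_rate, n)
    geno[drop] <- NA_integer_
  }
  geno
}

#' Simulation truth: QTL placement and effects
#'
#' Bundles the QTL architecture used by \code{\link{simulate_phenotype}}.
#' QTL sit exactly at marker positions, so every effect is tied to a named
#' marker column of the genotype matrix.
#'
#' @param main data frame with columns \code{marker}, \code{a}, \code{d}.
#' @param epistasis data frame with columns \code{marker1}, \code{marker2},
#'   \code{aa}, \code{ad}, \code{da}, \code{dd} (zero rows allowed).
#' @param h2 narrow-sense-of-the-model heritability in (0, 1]: the ratio of
#'   genetic to total phenotypic variance used to scale the residual.
#' @return object of class \code{"sim_truth"}.
#' @export
sim_truth <- function(main, epistasis = NULL, h2 = 0.5) {
  if (is.null(epistasis))
    epistasis <- data.frame(marker1 = character(), marker2 = character(),
                            aa = numeric(), ad = numeric(),
                            da = numeric(), dd = numeric())
  stopifnot(all(c("marker", "a", "d") %in% names(main)),
            all(c("marker1", "marker2", "aa", "ad", "da", "dd") %in%
                  names(epistasis)))
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  structure(list(main = main, epistasis = epistasis, h2 = h2),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", nrow(x$main), "main-effect QTL,",
      nrow(x$epistasis), "epistatic pair(s), h2 =", x$h2, "\n")
  invisible(x)
}

# Genetic value per individual from marker-coded genotypes and a truth object.
genetic_value <- function(truth, geno) {
  n <- nrow(geno)
  g <- numeric(n)
  for (i in seq_len(nrow(truth$main))) {
    mk <- truth$main$marker[i]
    if (!mk %in% colnames(geno)) stop("truth marker not in genotypes: ", mk)
    cd <- f2_metric(geno[, mk])
    g <- g + cd$x * truth$main$a[i] + cd$w * truth$main$d[i]
  }
  for (i in seq_len(nrow(truth$epistasis))) {
    e <- truth$epistasis[i, ]
    c1 <- f2_metric(geno[, e$marker1]); c2 <- f2_metric(geno[, e$marker2])
    cov <- epistatic_covariates(c1$x, c1$w, c2$x, c2$w)
    g <- g + cov$eta * e$aa + cov$gamma * e$ad +
      cov$varpi * e$da + cov$phi * e$dd
  }
  g
}

#' Simulate a phenotype from a truth object
#'
#' The genetic value is assembled from the F2-metric codes at the truth
#' markers; Gaussian residuals are calibrated against the realized genetic
#' variance of the cohort: sigma^2 = var(g) (1 - h2) / h2, and the drawn
#' residual vector is centred, decorrelated from g and rescaled so its
#' sample variance equals sigma^2 exactly.  The realized sample-level
#' heritability var(g) / var(y) therefore equals \code{truth$h2}.
#'
#' @param truth a \code{\link{sim_truth}}.
#' @param geno genotype matrix from \code{\link{simulate_genotypes}} (no
#'   missing cells at truth markers).
#' @return numeric phenotype vector with attributes \code{sigma2} (residual
#'   variance used) and \code{genetic_value}.
#' @export
simulate_phenotype <- function(truth, geno) {
  stopifnot(inherits(truth, "sim_truth"))
  g <- genetic_value(truth, geno)
  vg <- stats::var(g)
  if (truth$h2 == 1) return(structure(g, sigma2 = 0, genetic_value = g))
  s2 <- vg * (1 - truth$h2) / truth$h2
  eres <- stats::rnorm(length(g), 0, sqrt(s2))
  if (vg > 0) eres <- stats::residuals(stats::lm(eres ~ g))
  eres <- eres - mean(eres)
  eres <- eres * sqrt(s2 / stats::var(eres))
  structure(g + eres, sigma2 = s2, genetic_value = g)
}

#' The default simulated study scenario
#'
#' Emits the map and truth of the built-in simulation design: 104 bi-allelic
#' markers in 7 linkage groups on a uniform 7.8-cM grid (15 markers in groups
#' 1-6, 14 in group 7, hence 97 intervals), six main-effect QTL with a = d = 2
#' placed at a random interior marker of each of the first six groups, and
#' seven epistatic QTL arranged in four interval pairs (19 x 25, 54 x 72,
#' 59 x 91, 59 x 94) whose four epistatic effects are each drawn from
#' Uniform(-2, 2); heritability 0.5.  Epistatic QTL carry no main effect.
#'
#' @param seed integer seed controlling the random main-QTL markers and
#'   epistatic effect values.
#' @return list with components \code{map} (a \code{linkage_map}) and
#'   \code{truth} (a \code{sim_truth}; attribute \code{intervals} records the
#'   interval index of every QTL).
#' @export
default_scenario <- function(seed = 1) {
  sizes <- c(15L, 15L, 15L, 15L, 15L, 15L, 14L)
  marker <- character(0); group <- integer(0); pos <- numeric(0)
  for (g in seq_along(sizes)) {
    marker <- c(marker, sprintf("m%d_%02d", g, seq_len(sizes[g])))
    group <- c(group, rep(g, sizes[g]))
    pos <- c(pos, 7.8 * (seq_len(sizes[g]) - 1L))
  }
  map <- linkage_map(marker, group, pos)
  iv <- interval_table(map)
  pair_iv <- rbind(c(19L, 25L), c(54L, 72L), c(59L, 91L), c(59L, 94L))
  epi_marker <- map$marker[iv$left]          # interval k hosts its left marker
  withr_seed(seed, {
    epi <- data.frame(marker1 = epi_marker[pair_iv[, 1]],
                      marker2 = epi_marker[pair_iv[, 2]],
                      aa = stats::runif(4, -2, 2), ad = stats::runif(4, -2, 2),
                      da = stats::runif(4, -2, 2), dd = stats::runif(4, -2, 2))
    used <- unique(c(pair_iv))
    main_iv <- integer(6)
    for (g in 1:6) {
      cand <- setdiff(which(iv$group == g)[-1], used)  # interior, unused
      main_iv[g] <- cand[sample.int(length(cand), 1)]
    }
    main <- data.frame(marker = epi_marker[main_iv], a = 2, d = 2)
  })
  truth <- sim_truth(main, epi, h2 = 0.5)
  attr(truth, "intervals") <- list(main = main_iv, pairs = pair_iv)
  list(map = map, truth = truth)
}

#' A compact parameter-recovery scenario
#'
#' Two linkage groups of six markers each on a 10-cM grid (10 intervals).
#' One main-effect QTL (a = 2, d = 1) sits at the first marker of group 1
#' (interval 1) and one purely dominant-by-dominant pair (dd = 2) joins the
#' last marker of group 1 with the first marker of group 2 (interval pair
#' 5 x 6); heritability 0.5.  The QTL are placed at group-terminal markers so
#' that each is flanked by a single candidate interval, making the recovery
#' target unambiguous.
#'
#' @return list with \code{map} and \code{truth}; attribute
#'   \code{intervals} of the truth gives \code{main = 1} and
#'   \code{pair = c(5, 6)}.
#' @export
recovery_scenario <- function() {
  map <- linkage_map(sprintf("m%d_%d", rep(1:2, each = 6), rep(1:6, 2)),
                     rep(1:2, each = 6), rep(10 * (0:5), 2))
  main <- data.frame(marker = "m1_1", a = 2, d = 1)
  epi <- data.frame(marker1 = "m1_6", marker2 = "m2_1",
                    aa = 0, ad = 0, da = 0, dd = 2)
  truth <- sim_truth(main, epi, h2 = 0.5)
  attr(truth, "intervals") <- list(main = 1L, pair = c(5L, 6L))
  list(map = map, truth = truth)
}

#' Simulate a full cross (genotypes plus phenotype)
#'
#' @param scenario list with \code{map} and \code{truth}, e.g. from
#'   \code{\link{default_scenario}}.
#' @param n number of individuals (the default study uses 300).
#' @param design cross design for the marker chains.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return object of class \code{"cross_bundle"}: list with \code{map},
#'   \code{geno}, \code{pheno}, \code{design}, \code{truth}, \code{ids}.
#' @export
simulate_cross <- function(scenario, n = 300, design = "f2", seed = 1) {
  design <- match_design(design)
  withr_seed(seed, {
    geno <- simulate_genotypes(scenario$map, n, design)
    pheno <- simulate_phenotype(scenario$truth, geno)
  })
  structure(list(map = scenario$map, geno = geno,
                 pheno = as.numeric(pheno), design = design,
                 truth = scenario$truth,
                 sigma2 = attr(pheno, "sigma2"),
                 genetic_value = attr(pheno, "genetic_value"),
                 ids = sprintf("ind%03d", seq_len(n))),
            class = "cross_bundle")
}

#' @export
print.cross_bundle <- function(x, ...) {
  cat("Cross bundle (", x$design, "): ", length(x$pheno), " individuals x ",
      ncol(x$geno), " markers\n", sep = "")
  invisible(x)
}

#' Realized heritability of a simulated cross
#'
#' Var(g) / Var(y) from the stored genetic values; a law-of-large-numbers
#' check that the residual calibration hit the requested heritability.
#'
#' @param bundle a \code{cross_bundle} carrying \code{genetic_value}.
#' @return numeric scalar.
#' @export
realized_h2 <- function(bundle) {
  stopifnot(inherits(bundle, "cross_bundle"),
            !is.null(bundle$genetic_value))
  stats::var(bundle$genetic_value) / stats::var(bundle$pheno)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}
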