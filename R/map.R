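#' Construct a linkage map
#'
#' A linkage map is an ordered set of markers grouped into linkage groups,
#' with positions in centiMorgans.  Positions must be strictly increasing
#' within each group, every group must contain at least two markers (a group
#' with a single marker defines no interval and therefore no candidate QTL),
#' and marker names must be unique genome-wide.
#'
#' @param marker character vector of marker names.
#' @param group linkage-group labels (coerced to factor in order of first
#'   appearance).
#' @param position_cM numeric positions in cM, non-negative.
#' @return An object of class \code{"linkage_map"}: a data frame with columns
#'   \code{marker}, \code{group}, \code{position_cM}, sorted by group and
#'   position.
#' @examples
#' m <- linkage_map(paste0("m", 1:4), c(1, 1, 2, 2), c(0, 10, 0, 20))
#' count_intervals(m)
#' @export
linkage_map <- function(marker, group, position_cM) {
  marker <- as.character(marker)
  position_cM <- as.numeric(position_cM)
  if (length(marker) != length(group) || length(marker) != length(position_cM))
    stop("marker, group and position_cM must have equal length")
  if (anyNA(marker) || anyNA(group) || anyNA(position_cM))
    stop("linkage map fields must not contain missing values")
  if (any(position_cM < 0)) stop("marker positions must be >= 0")
  if (anyDuplicated(marker))
    stop("duplicated marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  group <- factor(as.character(group), levels = unique(as.character(group)))
  map <- data.frame(marker = marker, group = group,
                    position_cM = position_cM, stringsAsFactors = FALSE)
  ord <- order(as.integer(map$group), map$position_cM)
  if (any(ord != seq_along(ord))) {
    warning("markers reordered by group and position")
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
  }
  for (g in levels(map$group)) {
    pos <- map$position_cM[map$group == g]
    if (length(pos) < 2)
      stop("linkage group '", g, "' has fewer than 2 markers")
    if (any(diff(pos) <= 0))
      stop("positions not strictly increasing in group '", g, "'")
  }
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' @export
print.linkage_map <- function(x, ...) {
  cat("Linkage map:", nrow(x), "markers in", nlevels(x$group),
      "linkage groups,", count_intervals(x), "intervals\n")
  invisible(x)
}

#' Read or write a linkage map as CSV
#'
#' The file has a header \code{marker,group,position_cM}.  Groups may appear
#' in any order; markers are sorted by position within group on load (with a
#' warning if the file was unsorted).
#'
#' @param path file path.
#' @return \code{read_map} returns a \code{linkage_map};
#'   \code{write_map} returns \code{path} invisibly.
#' @export
read_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "group", "position_cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  linkage_map(df$marker, df$group, df$position_cM)
}

#' @rdname read_map
#' @param map a \code{linkage_map}.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  out <- data.frame(marker = map$marker, group = as.character(map$group),
                    position_cM = map$position_cM)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of marker intervals in a map
#'
#' Each linkage group with m markers hosts m - 1 intervals, and one candidate
#' QTL is entertained per interval.
#'
#' @param map a \code{linkage_map}.
#' @return integer, the total interval count p.
#' @export
count_intervals <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  sum(table(map$group) - 1L)
}

#' Number of candidate epistatic terms
#'
#' With p candidate QTL there are p(p-1)/2 unordered locus pairs; each pair
#' carries \code{types} epistatic effects (4 when additive-additive,
#' additive-dominant, dominant-additive and dominant-dominant are all
#' modelled).
#'
#' @param p integer, number of candidate QTL (intervals); must be >= 2.
#' @param types number of epistasis types per pair (default 4).
#' @return integer count \code{types * p * (p - 1) / 2}.
#' @export
count_epistasis_candidates <- function(p, types = 4L) {
  p <- as.integer(p)
  if (is.na(p) || p < 2L) stop("p must be an integer >= 2")
  as.integer(types) * (p * (p - 1L)) %/% 2L
}

#' Model dimension for a given number of active epistatic pairs
#'
#' The fixed part of the model holds 2p main effects (additive and dominance
#' per interval); each active epistatic pair adds its four effects.
#'
#' @param p number of intervals.
#' @param t number of active epistatic pairs.
#' @return integer \code{2 p + 4 t}.
#' @export
model_dimension <- function(p, t = 0L) 2L * as.integer(p) + 4L * as.integer(t)

#' Map distance to recombination fraction
#'
#' Kosambi: r = tanh(2 d) / 2; Haldane: r = (1 - exp(-2 d)) / 2, with d the
#' distance in Morgans.  Both are strictly increasing in d and bounded by 1/2.
#'
#' @param d map distance in cM (>= 0); vectorised.
#' @param map_function \code{"kosambi"} (default) or \code{"haldane"}.
#' @return recombination fraction(s) in [0, 0.5).
#' @examples
#' recomb_fraction(10)              # Kosambi, 0.0987
#' recomb_fraction(10, "haldane")   # 0.0906
#' @export
recomb_fraction <- function(d, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (any(d < 0)) stop("map distance must be >= 0")
  dM <- d / 100
  switch(map_function,
         kosambi = 0.5 * tanh(2 * dM),
         haldane = 0.5 * (1 - exp(-2 * dM)))
}

#' Genotype prior for a cross design
#'
#' Marginal probabilities of the genotype codes (1 = QQ, 0 = Qq, -1 = qq).
#' F2: (1/4, 1/2, 1/4).  F2:3 (one selfing generation past F2): heterozygosity
#' halves, giving (3/8, 1/4, 3/8).
#'
#' @param design \code{"f2"} or \code{"f2:3"}.
#' @return named numeric triple over codes \code{c("1", "0", "-1")}.
#' @export
genotype_prior <- function(design = c("f2", "f2:3")) {
  design <- match_design(design)
  pr <- if (design == "f2") c(0.25, 0.5, 0.25) else c(0.375, 0.25, 0.375)
  names(pr) <- c("1", "0", "-1")
  pr
}

match_design <- function(design) {
  d <- tolower(as.character(design)[1])
  d <- sub("_", ":", d, fixed = TRUE)
  if (!d %in% c("f2", "f2:3"))
    stop("unknown cross design: ", design, " (use \"f2\" or \"f2:3\")")
  d
}

# Two-locus F2 joint distribution over (genotype at locus A, genotype at
# locus B), codes ordered (1, 0, -1).  Built from F1 gamete frequencies:
# coupling gametes (1-r)/2, recombinants r/2, two independent gametes per
# individual.
f2_joint <- function(r) {
  gam <- expand.grid(m = c(1L, 0L), q = c(1L, 0L))
  gp <- ifelse(gam$m == gam$q, (1 - r) / 2, r / 2)
  J <- matrix(0, 3, 3, dimnames = list(c("1", "0", "-1"), c("1", "0", "-1")))
  code <- function(n) c("1" = 3L, "0" = 2L)[as.character(n)]  # allele count -> row
  idx <- function(n) 4L - (n + 1L)  # allele count 2,1,0 -> index 1,2,3
  for (i in seq_len(4)) for (j in seq_len(4)) {
    mi <- gam$m[i] + gam$m[j]
    qi <- gam$q[i] + gam$q[j]
    J[idx(mi), idx(qi)] <- J[idx(mi), idx(qi)] + gp[i] * gp[j]
  }
  J
}

# Genotype transition under one generation of selfing: row = parent genotype
# code (1, 0, -1) at a single locus, column = offspring code.
selfing_kernel <- matrix(c(1, 0, 0,
                           0.25, 0.5, 0.25,
                           0, 0, 1),
                         3, 3, byrow = TRUE,
                         dimnames = list(c("1", "0", "-1"), c("1", "0", "-1")))

#' QTL-genotype transition matrix given a flanking marker
#'
#' Returns the 3 x 3 matrix H with rows indexed by the observed marker
#' genotype code (1, 0, -1) and columns by the QTL genotype code, each row a
#' conditional distribution P(QTL genotype | marker genotype).
#'
#' For an F2 the matrix derives from the two-locus F2 joint distribution at
#' recombination fraction r.  For F2:3 progenies the observed marker code is
#' that of the F2 parent plant and the latent QTL genotype is the progeny's
#' after one selfing generation: the parent's marker-QTL joint is propagated
#' through the selfing kernel, which reproduces the classical entry
#' P(QQ | MM) = (1 - r)^2 + 0.5 r (1 - r).  At r = 0 the F2 matrix is the
#' identity and the F2:3 matrix is the within-line selfing segregation of the
#' marker genotype itself.
#'
#' @param r recombination fraction in [0, 0.5].
#' @param design \code{"f2"} or \code{"f2:3"}.
#' @return 3 x 3 row-stochastic matrix with dimnames
#'   \code{list(marker = c("1","0","-1"), qtl = c("1","0","-1"))}.
#' @export
qtl_given_marker <- function(r, design = c("f2", "f2:3")) {
  design <- match_design(design)
  if (length(r) != 1 || is.na(r) || r < 0 || r > 0.5)
    stop("r must be a single value in [0, 0.5]")
  J <- f2_joint(r)           # rows marker, cols QTL, both on the F2 parent
  if (design == "f2:3") {
    # one selfing acts on the QTL locus conditionally on the parent QTL
    # genotype; the offspring QTL given parent (marker, QTL) depends only on
    # the parent QTL genotype
    J <- J %*% selfing_kernel
  }
  H <- J / rowSums(J)
  dimnames(H) <- list(marker = c("1", "0", "-1"), qtl = c("1", "0", "-1"))
  H
}

# P(marker | QTL genotype), rows = QTL code, cols = marker code; Bayes
# inversion of qtl_given_marker using the design's marginals.  Used by the
# genotype imputation step, where the flanking-marker conditional is
# prior(g) * P(m_L | g) * P(m_R | g).
marker_given_qtl <- function(r, design) {
  design <- match_design(design)
  H <- qtl_given_marker(r, design)
  pm <- c(0.25, 0.5, 0.25)              # marker marginal: F2 plant in both designs
  pg <- genotype_prior(design)
  M <- t(H * pm) / as.vector(pg)
  dimnames(M) <- list(qtl = c("1", "0", "-1"), marker = c("1", "0", "-1"))
  M
}

# Interval table used throughout the sampler: one row per candidate QTL.
# Columns: group index, left/right marker row index in the map, interval
# bounds in cM.
interval_table <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  gi <- as.integer(map$group)
  out <- do.call(rbind, lapply(unique(gi), function(g) {
    rows <- which(gi == g)
    k <- length(rows) - 1L
    data.frame(group = g,
               left = rows[seq_len(k)],
               right = rows[seq_len(k) + 1L],
               lower = map$position_cM[rows[seq_len(k)]],
               upper = map$position_cM[rows[seq_len(k) + 1L]])
  }))
  rownames(out) <- NULL
  out
}
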