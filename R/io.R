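# File formats and drivers: cross bundles on disk, chain/summary CSV output,
# run manifests, k-fold splitting and the cross-validation driver.
#
# Schemas (all plain CSV):
#   map        marker,group,position_cM
#   genotypes  id, then one column per marker; codes 1/0/-1, empty = missing
#   phenotype  id,y
#   chain      sample,iteration,mu,sigma2,phi,t
#   pairs      sample,k1,k2,aa,ad,da,dd
#   intervals  sample,k,a,d,lambda

#' Read a cross from map, genotype and phenotype CSV files
#'
#' Rows are harmonised by individual id (genotypes reordered to match the
#' phenotype file); every genotype column must be a map marker and vice
#' versa.  Missing genotype cells (empty or NA) are preserved as NA.  An
#' AA/AB/BB letter dialect is accepted and normalised to 1/0/-1.
#'
#' @param map_path,geno_path,pheno_path file paths.
#' @param design \code{"f2"} or \code{"f2:3"}.
#' @return a \code{cross_bundle}.
#' @export
read_cross <- function(map_path, geno_path, pheno_path, design = "f2") {
  design <- match_design(design)
  map <- read_map(map_path)
  gdf <- utils::read.csv(geno_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (names(gdf)[1] != "id") stop("genotype file must start with an 'id' column")
  pdf <- utils::read.csv(pheno_path, stringsAsFactors = FALSE)
  if (!all(c("id", "y") %in% names(pdf)))
    stop("phenotype file must have columns id,y")
  if (anyDuplicated(gdf$id))
    stop("duplicate individual id(s) in genotypes: ",
         paste(unique(gdf$id[duplicated(gdf$id)]), collapse = ", "))
  if (anyDuplicated(pdf$id))
    stop("duplicate individual id(s) in phenotypes: ",
         paste(unique(pdf$id[duplicated(pdf$id)]), collapse = ", "))
  if (!is.numeric(pdf$y))
    stop("non-numeric phenotype value(s), e.g. row ",
         which(is.na(suppressWarnings(as.numeric(pdf$y))))[1])
  extra_g <- setdiff(gdf$id, pdf$id); extra_p <- setdiff(pdf$id, gdf$id)
  if (length(extra_g) || length(extra_p))
    stop("individuals not shared by genotype and phenotype tables: ",
         paste(c(extra_g, extra_p), collapse = ", "))
  mk <- setdiff(names(gdf), "id")
  orphan <- setdiff(mk, map$marker)
  if (length(orphan))
    stop("genotype marker(s) absent from map: ",
         paste(orphan, collapse = ", "))
  lost <- setdiff(map$marker, mk)
  if (length(lost))
    stop("map marker(s) absent from genotypes: ",
         paste(lost, collapse = ", "))
  gdf <- gdf[match(pdf$id, gdf$id), , drop = FALSE]
  geno <- as.matrix(gdf[, map$marker, drop = FALSE])
  if (is.character(geno)) {
    letter <- c(AA = 1, AB = 0, BA = 0, BB = -1)
    conv <- ifelse(geno %in% names(letter), letter[geno],
                   suppressWarnings(as.numeric(geno)))
    geno <- matrix(as.numeric(conv), nrow(gdf),
                   dimnames = list(NULL, map$marker))
  }
  geno[geno == ""] <- NA
  storage.mode(geno) <- "integer"
  bad <- !is.na(geno) & !geno %in% c(1L, 0L, -1L)
  if (any(bad)) {
    hit <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype code at row ", hit[1], ", marker ",
         map$marker[hit[2]])
  }
  structure(list(map = map, geno = geno, pheno = pdf$y, design = design,
                 truth = NULL, ids = as.character(pdf$id)),
            class = "cross_bundle")
}

#' Write a cross bundle to a directory
#'
#' Emits \code{map.csv}, \code{genotypes.csv}, \code{phenotype.csv} and,
#' when the bundle carries a simulation truth, \code{truth.json}.
#'
#' @param bundle a \code{cross_bundle}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cross <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cross_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_map(bundle$map, file.path(dir, "map.csv"))
  gdf <- data.frame(id = bundle$ids, bundle$geno, check.names = FALSE)
  utils::write.csv(gdf, file.path(dir, "genotypes.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(data.frame(id = bundle$ids, y = bundle$pheno),
                   file.path(dir, "phenotype.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(
      list(main = tr$main, epistasis = tr$epistasis, h2 = tr$h2,
           sigma2 = bundle$sigma2, intervals = attr(tr, "intervals")),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(dir)
}

#' Write chain record CSV files and a run manifest
#'
#' @param chain a \code{qtl_chain}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "qtl_chain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(chain$samples, file.path(dir, "chain.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(chain$epi, file.path(dir, "pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  p <- nrow(chain$intervals)
  long <- data.frame(
    sample = rep(seq_len(chain$N), p),
    k = rep(seq_len(p), each = chain$N),
    a = as.vector(chain$a), d = as.vector(chain$d),
    lambda = as.vector(chain$lambda))
  utils::write.csv(long, file.path(dir, "intervals.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(design = chain$design, map_function = chain$map_function,
         intervals = p, retained = chain$N,
         burn_in = chain$config$burn_in, thin = chain$config$thin,
         seed = chain$config$seed,
         priors = unclass(chain$priors),
         package_version = as.character(utils::packageVersion("epiqtl")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Write post-MCMC summary CSV files
#'
#' Emits \code{lod_profile.csv}, \code{epistasis_summary.csv},
#' \code{heatmap.csv} and \code{variance_components.csv}.
#'
#' @param chain a \code{qtl_chain}.
#' @param dir output directory.
#' @param chain_min,lod_min,bin_cM summary thresholds.
#' @return \code{dir}, invisibly.
#' @export
write_summaries <- function(chain, dir, chain_min = 400, lod_min = 3,
                            bin_cM = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- main_qtl_profile(chain, bin_cM = bin_cM)
  utils::write.csv(as.data.frame(prof), file.path(dir, "lod_profile.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- summarize_epistasis(chain, chain_min, lod_min)
  utils::write.csv(as.data.frame(summ),
                   file.path(dir, "epistasis_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(heatmap_matrix(chain), file.path(dir, "heatmap.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(variance_components(chain),
                   file.path(dir, "variance_components.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Random k-fold partition
#'
#' Seeded random partition of n individuals into k disjoint folds.  Fold
#' sizes mimic the grouping used in the mapping study: the first k - 1
#' folds take floor(n/k) rounded down to the nearest multiple of 10 when
#' floor(n/k) >= 10 (round-sized groups of entries), otherwise floor(n/k);
#' the final fold takes the remainder.  With 256 individuals and k = 5 this
#' yields folds of 50, 50, 50, 50 and 56.
#'
#' @param n number of individuals.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of length n with fold labels 1..k.
#' @export
kfold_split <- function(n, k, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must not exceed n")
  base <- n %/% k
  if (base >= 10) base <- 10L * (base %/% 10L)
  sizes <- c(rep(base, k - 1L), n - base * (k - 1L))
  withr_seed(seed, {
    perm <- sample.int(n)
  })
  folds <- integer(n)
  folds[perm] <- rep.int(seq_len(k), sizes)
  folds
}

#' k-fold cross-validation of the epistasis scan
#'
#' For each fold the sampler runs on the remaining individuals; the report
#' counts, per epistatic pair and per interval, the folds in which it was
#' selected (pair: inclusion count and LOD thresholds; interval: LOD
#' threshold).
#'
#' @param bundle a \code{cross_bundle}.
#' @param priors,config sampler settings (the fold chain length is the
#'   configured one; \code{chain_min} should be scaled to \code{retained}
#'   accordingly).
#' @param k number of folds; \code{k = 1} degenerates to a single run on the
#'   full data.
#' @param chain_min,lod_min selection thresholds per fold.
#' @param seed seed for the fold assignment (fold chains use
#'   \code{config$seed} + fold index).
#' @return list with per-fold \code{summaries}, per-fold selected pairs,
#'   \code{pair_stability} (data frame k1, k2, folds_selected) and
#'   \code{interval_stability}.
#' @export
run_cv <- function(bundle, priors = prior_config(),
                   config = sampler_config(), k = 5, chain_min = 400,
                   lod_min = 3, seed = 1) {
  stopifnot(inherits(bundle, "cross_bundle"))
  n <- length(bundle$pheno)
  folds <- if (k == 1) rep(0L, n) else kfold_split(n, k, seed)
  p <- count_intervals(bundle$map)
  pair_count <- matrix(0L, p, p)
  int_count <- integer(p)
  summaries <- vector("list", k)
  for (f in seq_len(k)) {
    keep <- folds != f
    cfg <- config; cfg$seed <- config$seed + f
    ch <- run_rjmcmc(bundle$pheno[keep], bundle$geno[keep, , drop = FALSE],
                     bundle$map, bundle$design, priors, cfg)
    sm <- summarize_epistasis(ch, chain_min, lod_min)
    summaries[[f]] <- sm
    sel <- sm[sm$selected, , drop = FALSE]
    if (nrow(sel))
      pair_count[cbind(sel$k1, sel$k2)] <-
        pair_count[cbind(sel$k1, sel$k2)] + 1L
    il <- interval_lod(ch)
    hit <- il$interval[il$lod > lod_min]
    int_count[hit] <- int_count[hit] + 1L
  }
  pair_count <- pair_count + t(pair_count)
  ij <- which(pair_count > 0 & upper.tri(pair_count), arr.ind = TRUE)
  list(summaries = summaries,
       pair_stability = data.frame(k1 = ij[, 1], k2 = ij[, 2],
                                   folds_selected = pair_count[ij]),
       interval_stability = data.frame(interval = seq_len(p),
                                       folds_selected = int_count),
       folds = folds)
}
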