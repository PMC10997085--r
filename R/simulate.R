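# Synthetic all-sites-VCF cohorts with known sexes.
#
# Generative model: individual i has mean autosomal depth d_i; locus l has
# a capture-probability scaling ("recoverability") rho_l in [0, 1]; the
# expected read count of locus l in individual i is
#   d_i * copy(sex_i, class_l) * rho_l
# with copy factor 1 on autosomes; on the X, 1 for the homogametic sex and
# xCopyRatio (default 0.5, one copy versus two) for the heterogametic; on
# the Y, yPresence (default 0) for the homogametic sex and 1 for the
# heterogametic. Realised counts are Poisson (optionally negative
# binomial); a locus is missing in an individual exactly when its realised
# count is 0, and all member sites of a locus share its depth and
# missingness. Y loci draw recoverability from a higher distribution than
# autosomal/X loci by default, mirroring how a locus-sharing filter
# enriches robust Y loci; this is what makes heterogametic Index Y go
# negative at low coverage.

SIM_CONTIGS <- c(AUTOSOME = "chrA", X_LIKE = "chrX", Y_LIKE = "chrY")
.SIM_GAP <- 200L  # bp between simulated loci, > any sensible maxGap

#' Construct simulation parameters for a synthetic RAD cohort
#'
#' Defaults emulate the published fur-seal cohort: 11.5X mean depth,
#' 150 bp loci, and per-cohort locus counts of 31775 autosomal / 19574 X /
#' 551 Y. Smaller locus counts and lengths give statistically equivalent
#' cohorts at a fraction of the size (depth and missingness are locus
#' level quantities), so tests and examples scale these down.
#'
#' @param nIndividuals cohort size.
#' @param sexRatio proportion of homogametic individuals.
#' @param lociAutosome,lociX,lociY locus counts per chromosome class.
#' @param locusLength sites per locus.
#' @param meanDepth per-individual mean autosomal depth; length 1 or
#'   `nIndividuals`.
#' @param xCopyRatio X copy factor in the heterogametic sex.
#' @param yPresence Y capture factor in the homogametic sex.
#' @param recoverability named list of Beta shape pairs for per-locus
#'   capture scaling (`autosome`, `x`, `y`); `list()` disables the
#'   heterogeneity (all loci fully recoverable).
#' @param overdispersion negative-binomial size for read counts; NA =
#'   Poisson.
#' @param seed integer seed.
#' @return a validated [SimCohortParams-class].
#' @export
simParams <- function(nIndividuals = 60L, sexRatio = 0.5,
                      lociAutosome = 31775L, lociX = 19574L, lociY = 551L,
                      locusLength = 150L, meanDepth = 11.5,
                      xCopyRatio = 0.5, yPresence = 0,
                      recoverability = list(autosome = c(2, 2),
                                            x = c(2, 2), y = c(8, 2)),
                      overdispersion = NA_real_, seed = 1L) {
  new("SimCohortParams",
      nIndividuals = as.integer(nIndividuals),
      sexRatio = as.numeric(sexRatio),
      lociAutosome = as.integer(lociAutosome),
      lociX = as.integer(lociX), lociY = as.integer(lociY),
      locusLength = as.integer(locusLength),
      meanDepth = as.numeric(meanDepth),
      xCopyRatio = as.numeric(xCopyRatio),
      yPresence = as.numeric(yPresence),
      recoverability = recoverability,
      overdispersion = as.numeric(overdispersion),
      seed = as.integer(seed))
}

# loci layout + per-locus recoverability; consumes RNG (rho draws)
.simLoci <- function(params) {
  counts <- c(AUTOSOME = params@lociAutosome, X_LIKE = params@lociX,
              Y_LIKE = params@lociY)
  cls <- rep(names(counts), times = counts)
  j <- sequence(counts)
  rec <- params@recoverability
  rho <- if (!length(rec)) rep(1, length(cls)) else {
    shapes <- rbind(AUTOSOME = rec$autosome, X_LIKE = rec$x,
                    Y_LIKE = rec$y)
    stats::rbeta(length(cls), shapes[cls, 1], shapes[cls, 2])
  }
  data.frame(
    class = cls,
    contig = unname(SIM_CONTIGS[cls]),
    id = paste0(substr(cls, 1, 1), sprintf("%06d", j)),
    start = (j - 1L) * (params@locusLength + .SIM_GAP) + 1L,
    rho = rho)
}

# per-individual copy factors by class; homo = logical vector
.simCopyFactors <- function(params, homo) {
  cbind(AUTOSOME = rep(1, length(homo)),
        X_LIKE = ifelse(homo, 1, params@xCopyRatio),
        Y_LIKE = ifelse(homo, params@yPresence, 1))
}

# realised per-locus read counts (loci x individuals); consumes RNG
.simCounts <- function(loci, depths, cf, overdispersion) {
  cfm <- t(cf[, loci$class, drop = FALSE])      # loci x individuals
  lam <- sweep(cfm, 2, depths, "*") * loci$rho
  d <- if (is.na(overdispersion)) stats::rpois(length(lam), lam)
       else stats::rnbinom(length(lam), size = overdispersion, mu = lam)
  matrix(d, nrow = nrow(loci))
}

.simWriteVcf <- function(loci, counts, samples, locusLength, path) {
  geno <- matrix(ifelse(counts == 0, "./.:0",
                        paste0("0/0:", counts)), nrow = nrow(loci))
  repIdx <- rep(seq_len(nrow(loci)), each = locusLength)
  pos <- rep(loci$start, each = locusLength) +
    rep(seq_len(locusLength) - 1L, times = nrow(loci))
  contigLen <- tapply(loci$start + locusLength + .SIM_GAP, loci$contig, max)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sexRAD simulateCohort",
    sprintf("##contig=<ID=%s,length=%d>", names(contigLen),
            as.integer(contigLen)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- do.call(paste, c(
    list(rep(loci$contig, each = locusLength), pos,
         rep(loci$id, each = locusLength),
         "A", ".", ".", "PASS", ".", "GT:DP"),
    lapply(seq_along(samples), function(i) geno[repIdx, i]),
    list(sep = "\t")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' The chromosome-class map matching simulated cohorts
#'
#' Simulated VCFs place loci on contigs `chrA` (autosomal), `chrX`
#' (X-like) and `chrY` (Y-like).
#'
#' @return a [ChromClassMap-class].
#' @export
simChromMap <- function() {
  ChromClassMap(c(chrA = "AUTOSOME", chrX = "X_LIKE", chrY = "Y_LIKE"))
}

#' Simulate an all-sites VCF cohort with known sexes
#'
#' Writes a self-contained fixture triplet: the all-sites VCF (GT and DP
#' per genotype, locus IDs in the ID column), a truth table CSV
#' (individual, true sex, true mean depth) and the matching
#' chromosome-class configuration. The first `round(sexRatio * n)`
#' individuals are homogametic. The run is byte-identical given the seed.
#'
#' @param params a [SimCohortParams-class].
#' @param dir output directory (created if needed).
#' @param prefix basename prefix for the three files.
#' @param gzip write the VCF gzip-compressed.
#' @return list with `vcf`, `truth`, `chromMap` (paths), `truthTable`
#'   (data.frame with `individual`, `true_sex`, `mean_depth`) and `map`.
#' @examples
#' \donttest{
#' p <- simParams(nIndividuals = 6, lociAutosome = 200, lociX = 50,
#'                lociY = 10, locusLength = 3, meanDepth = 15, seed = 7)
#' sim <- simulateCohort(p, tempdir())
#' head(sim$truthTable)
#' }
#' @export
simulateCohort <- function(params, dir, prefix = "sim", gzip = FALSE) {
  stopifnot(is(params, "SimCohortParams"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- params@nIndividuals
  samples <- sprintf("ind%03d", seq_len(n))
  homo <- seq_len(n) <= round(params@sexRatio * n)
  depths <- rep_len(params@meanDepth, n)
  map <- simChromMap()
  set.seed(params@seed)
  loci <- .simLoci(params)
  counts <- .simCounts(loci, depths, .simCopyFactors(params, homo),
                       params@overdispersion)
  vcf <- file.path(dir, paste0(prefix, ".all.vcf", if (gzip) ".gz"))
  .simWriteVcf(loci, counts, samples, params@locusLength, vcf)
  truthTable <- data.frame(
    individual = samples,
    true_sex = ifelse(homo, map@homogameticLabel, map@heterogameticLabel),
    mean_depth = depths)
  truth <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truthTable, truth, row.names = FALSE, quote = FALSE)
  chromMap <- file.path(dir, paste0(prefix, "_chrom_map.yaml"))
  writeChromMap(map, chromMap)
  list(vcf = vcf, truth = truth, chromMap = chromMap,
       truthTable = truthTable, map = map)
}

#' Simulate a cohort spanning a coverage-depth gradient
#'
#' One sub-cohort of `params@nIndividuals` per scheduled depth, all
#' sharing the same loci and per-locus recoverability, written as a single
#' cohort (one VCF, one truth table). Each sub-cohort's read counts are
#' drawn from a freshly re-seeded stream, so two sub-cohorts at the same
#' scheduled depth are identical apart from individual identifiers. Used
#' to probe the low-coverage regime (down to the 1.4X end of the observed
#' range) in which Index X degrades and heterogametic Index Y goes
#' negative.
#'
#' @param params a [SimCohortParams-class]; `meanDepth` must be scalar and
#'   is overridden per sub-cohort.
#' @param depthSchedule positive depths (X-fold), one sub-cohort each.
#' @param dir,prefix,gzip as in [simulateCohort()].
#' @return as [simulateCohort()]; the truth table gains a
#'   `scheduled_depth` column.
#' @export
degradeCohort <- function(params, depthSchedule, dir, prefix = "degrade",
                          gzip = FALSE) {
  stopifnot(is(params, "SimCohortParams"))
  if (!length(depthSchedule))
    stop("depthSchedule must be non-empty", call. = FALSE)
  if (any(is.na(depthSchedule)) || any(depthSchedule <= 0))
    stop("depthSchedule must contain positive depths", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- params@nIndividuals
  homo <- seq_len(n) <= round(params@sexRatio * n)
  cf <- .simCopyFactors(params, homo)
  map <- simChromMap()
  set.seed(params@seed)
  loci <- .simLoci(params)
  counts <- vector("list", length(depthSchedule))
  samples <- character(0)
  truthTable <- NULL
  for (k in seq_along(depthSchedule)) {
    d <- depthSchedule[k]
    ids <- sprintf("s%02d_ind%03d", k, seq_len(n))
    set.seed(params@seed + 1L)  # shared stream: equal depths, equal draws
    counts[[k]] <- .simCounts(loci, rep(d, n), cf, params@overdispersion)
    samples <- c(samples, ids)
    truthTable <- rbind(truthTable, data.frame(
      individual = ids,
      true_sex = ifelse(homo, map@homogameticLabel,
                        map@heterogameticLabel),
      mean_depth = d, scheduled_depth = d))
  }
  counts <- do.call(cbind, counts)
  vcf <- file.path(dir, paste0(prefix, ".all.vcf", if (gzip) ".gz"))
  .simWriteVcf(loci, counts, samples, params@locusLength, vcf)
  truth <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(truthTable, truth, row.names = FALSE, quote = FALSE)
  chromMap <- file.path(dir, paste0(prefix, "_chrom_map.yaml"))
  writeChromMap(map, chromMap)
  list(vcf = vcf, truth = truth, chromMap = chromMap,
       truthTable = truthTable, map = map)
}

#' @describeIn SimCohortParams compact display.
#' @param object a `SimCohortParams`.
#' @export
setMethod("show", "SimCohortParams", function(object) {
  cat("SimCohortParams:", object@nIndividuals, "individual(s),",
      sprintf("%.0f%% homogametic\n", 100 * object@sexRatio))
  cat(sprintf("  loci: %d autosomal, %d X, %d Y; %d site(s) each\n",
              object@lociAutosome, object@lociX, object@lociY,
              object@locusLength))
  cat(sprintf("  depth: %s X | xCopyRatio %.2f | yPresence %.2f | seed %d\n",
              paste(format(range(object@meanDepth)), collapse = "-"),
              object@xCopyRatio, object@yPresence, object@seed))
})
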