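#' @import methods
NULL

#' Chromosome classes recognised by the sexing framework
#'
#' Every reference contig is assigned to one of these classes. `X_LIKE`
#' contigs are present in two copies in the homogametic sex and one in the
#' heterogametic sex (the X in XY systems, the Z in ZW systems); `Y_LIKE`
#' contigs are carried only by the heterogametic sex (Y, or W); `AUTOSOME`
#' contigs are diploid in both sexes; `EXCLUDED` contigs are ignored
#' entirely (unplaced scaffolds, mitochondrion, ...).
#'
#' @export
CHROM_CLASSES <- c("X_LIKE", "Y_LIKE", "AUTOSOME", "EXCLUDED")

# classes counted towards per-individual statistics
STAT_CLASSES <- c("AUTOSOME", "X_LIKE", "Y_LIKE")

#' ChromClassMap: contig-to-chromosome-class assignment
#'
#' Maps reference contig identifiers (as spelled in the VCF) to chromosome
#' classes. Contigs not listed receive `defaultClass`. The sex labels
#' attached to calls downstream are configurable strings so that ZW systems
#' can be handled by relabelling (Z contigs as `X_LIKE`, W as `Y_LIKE`,
#' homogametic label "male", heterogametic "female").
#'
#' @slot classes named character vector; names are contig identifiers,
#'   values are drawn from [CHROM_CLASSES].
#' @slot defaultClass class given to contigs not listed, `"AUTOSOME"` or
#'   `"EXCLUDED"`.
#' @slot homogameticLabel,heterogameticLabel sex labels used in reports
#'   (defaults `"female"` / `"male"`, the XY convention).
#'
#' @seealso [ChromClassMap()], [readChromMap()], [contigClass()]
#' @export
setClass("ChromClassMap",
  representation(
    classes = "character",
    defaultClass = "character",
    homogameticLabel = "character",
    heterogameticLabel = "character"
  )
)

setValidity("ChromClassMap", function(object) {
  cl <- object@classes
  if (length(cl) == 0L)
    return("no contigs classified: no sex chromosomes defined")
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    return("every contig entry must be named by its identifier")
  dup <- unique(names(cl)[duplicated(names(cl))])
  if (length(dup))
    return(sprintf("contig assigned to more than one class: %s",
                   paste(dup, collapse = ", ")))
  bad <- setdiff(unique(cl), CHROM_CLASSES)
  if (length(bad))
    return(sprintf("unknown chromosome class: %s (allowed: %s)",
                   paste(bad, collapse = ", "),
                   paste(CHROM_CLASSES, collapse = ", ")))
  if (!sum(cl == "X_LIKE"))
    return("at least one X_LIKE contig is required for sexing")
  if (!sum(cl == "Y_LIKE"))
    return("at least one Y_LIKE contig is required for sexing")
  if (length(object@defaultClass) != 1L ||
      !object@defaultClass %in% c("AUTOSOME", "EXCLUDED"))
    return("defaultClass must be \"AUTOSOME\" or \"EXCLUDED\"")
  if (length(object@homogameticLabel) != 1L ||
      length(object@heterogameticLabel) != 1L)
    return("sex labels must be single strings")
  if (identical(object@homogameticLabel, object@heterogameticLabel))
    return("homogametic and heterogametic labels must differ")
  TRUE
})

#' RunConfig: run-level parameters
#'
#' Holds every tunable parameter of the pipeline. All fields have defaults
#' matching the published workflow; see [runConfig()].
#'
#' @slot minLocusShareR minimum proportion of individuals in which a locus
#'   must be present to be retained (the `-R` filter), in \[0, 1\].
#' @slot maxObsHet maximum per-site observed heterozygosity tolerated
#'   within a retained locus, in \[0, 1\].
#' @slot indexYFemaleThreshold Index Y at or above which the homogametic
#'   sex is called.
#' @slot lowDepthWarning overall mean depth (X-fold) below which calls are
#'   flagged low-depth and the advisory Index X call is suppressed.
#' @slot outputPrecision decimal places used when writing report CSVs.
#' @slot depthField FORMAT key carrying per-genotype depth (default "DP").
#' @slot seed integer seed, or NA for none.
#'
#' @export
setClass("RunConfig",
  representation(
    minLocusShareR = "numeric",
    maxObsHet = "numeric",
    indexYFemaleThreshold = "numeric",
    lowDepthWarning = "numeric",
    outputPrecision = "integer",
    depthField = "character",
    seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  chk1 <- function(x) length(x) == 1L && !is.na(x)
  if (!chk1(object@minLocusShareR) ||
      object@minLocusShareR < 0 || object@minLocusShareR > 1)
    return("minLocusShareR must be a single value in [0, 1]")
  if (!chk1(object@maxObsHet) ||
      object@maxObsHet < 0 || object@maxObsHet > 1)
    return("maxObsHet must be a single value in [0, 1]")
  if (!chk1(object@indexYFemaleThreshold))
    return("indexYFemaleThreshold must be a single value")
  if (!chk1(object@lowDepthWarning) || object@lowDepthWarning <= 0)
    return("lowDepthWarning must be a single positive value (X-fold)")
  if (!chk1(object@outputPrecision) || object@outputPrecision < 0)
    return("outputPrecision must be a single non-negative integer")
  if (!chk1(object@depthField) || !nzchar(object@depthField))
    return("depthField must be a non-empty FORMAT key")
  if (length(object@seed) != 1L)
    return("seed must be a single integer or NA")
  TRUE
})

#' SexingStats: per-individual, per-chromosome-class statistics
#'
#' The accumulated missingness and coverage-depth statistics that feed the
#' two sexing indexes. One row of `perClass` per individual and chromosome
#' class (AUTOSOME, X_LIKE, Y_LIKE); `overall` holds the per-individual
#' totals pooled across those classes.
#'
#' Definitions (per individual and class): `missingness` is the fraction of
#' sites retained in the VCF for that class whose genotype is missing in
#' the individual — the denominator is the population-wide site count, not
#' a per-individual one. `completeness = 1 - missingness`. `mean_depth`
#' averages per-genotype depth over non-missing sites only, and is NA when
#' an individual has no non-missing site in the class.
#'
#' @slot perClass data.frame with columns `individual`, `class`, `n_sites`,
#'   `n_missing`, `n_nonmissing`, `depth_sum`, `missingness`,
#'   `completeness`, `mean_depth`.
#' @slot overall data.frame with columns `individual`, `n_sites`,
#'   `n_nonmissing`, `depth_sum`, `mean_depth` pooled over all counted
#'   classes.
#' @slot samples character vector of sample identifiers, in VCF order.
#'
#' @seealso [accumulateStats()], [classStats()], [indexX()], [indexY()]
#' @export
setClass("SexingStats",
  representation(
    perClass = "data.frame",
    overall = "data.frame",
    samples = "character"
  )
)

setValidity("SexingStats", function(object) {
  pc <- object@perClass
  need <- c("individual", "class", "n_sites", "n_missing", "n_nonmissing",
            "depth_sum", "missingness", "completeness", "mean_depth")
  if (!all(need %in% names(pc)))
    return(sprintf("perClass lacks columns: %s",
                   paste(setdiff(need, names(pc)), collapse = ", ")))
  if (nrow(pc)) {
    if (any(!pc$class %in% STAT_CLASSES))
      return("perClass$class must be AUTOSOME, X_LIKE or Y_LIKE")
    if (any(pc$n_missing + pc$n_nonmissing != pc$n_sites))
      return("n_missing + n_nonmissing must equal n_sites")
    has <- pc$n_sites > 0
    if (any(abs(pc$missingness[has] + pc$completeness[has] - 1) > 0))
      return("completeness must equal 1 - missingness exactly")
    if (any(pc$depth_sum < 0))
      return("depth_sum must be non-negative")
    bad <- pc$n_nonmissing == 0 & !is.na(pc$mean_depth)
    if (any(bad))
      return("mean_depth must be NA when no site is non-missing")
  }
  if (!all(unique(pc$individual) %in% object@samples))
    return("perClass individuals must appear in samples")
  TRUE
})

#' LocusTable: grouping of VCF sites into RAD loci
#'
#' Produced by [groupLoci()]; consumed by [filterLoci()] and
#' [writeFilteredVcf()]. A locus is present in an individual when at least
#' one member site carries a non-missing genotype; per-site observed
#' heterozygosity is the fraction of non-missing genotypes that are
#' heterozygous.
#'
#' @slot loci data.frame with columns `locus_id`, `contig`, `start`, `end`,
#'   `n_sites`, `max_obs_het`.
#' @slot presence logical matrix, loci x samples.
#' @slot sites data.frame with columns `contig`, `pos`, `id`, `locus`
#'   (row index into `loci`) and `obs_het`.
#' @slot samples character vector of sample identifiers.
#'
#' @export
setClass("LocusTable",
  representation(
    loci = "data.frame",
    presence = "matrix",
    sites = "data.frame",
    samples = "character"
  )
)

setValidity("LocusTable", function(object) {
  if (nrow(object@loci) != nrow(object@presence))
    return("presence must have one row per locus")
  if (ncol(object@presence) != length(object@samples))
    return("presence must have one column per sample")
  if (nrow(object@sites) &&
      (min(object@sites$locus) < 1L ||
       max(object@sites$locus) > nrow(object@loci)))
    return("every site must point at an existing locus")
  TRUE
})

#' SexCalls: per-individual sex assignments
#'
#' One row per individual with both indexes, the depth/completeness
#' quantities they were computed from, the Index Y call (the assignment the
#' method trusts), the advisory Index X call, and confidence flags.
#'
#' @slot calls data.frame with columns `individual`, `depth_a`, `depth_x`,
#'   `depth_y`, `com_x`, `com_y`, `index_x`, `index_y`,
#'   `overall_mean_depth`, `sex_by_y`, `sex_by_x`, `sex`, `low_depth_flag`,
#'   `agreement_flag`, `reason`.
#' @slot labels named character vector mapping `homogametic` and
#'   `heterogametic` to the report labels.
#' @slot threshold the Index Y threshold the calls used.
#'
#' @seealso [classifyCohort()], [assignSex()]
#' @export
setClass("SexCalls",
  representation(
    calls = "data.frame",
    labels = "character",
    threshold = "numeric"
  )
)

setValidity("SexCalls", function(object) {
  if (!all(c("homogametic", "heterogametic") %in% names(object@labels)))
    return("labels must name homogametic and heterogametic")
  ok <- c("homogametic", "heterogametic", "unassigned")
  if (nrow(object@calls) && any(!object@calls$sex_by_y %in% ok))
    return("sex_by_y must be homogametic, heterogametic or unassigned")
  TRUE
})

#' SimCohortParams: generative parameters for a synthetic RAD cohort
#'
#' Defaults reproduce the statistical structure of the published fur-seal
#' dataset: 150 bp loci, 11.5X mean depth, and locus counts of 31775
#' autosomal / 19574 X / 551 Y per cohort. Depth and missingness are
#' locus-level quantities shared by a locus's member sites, so small
#' `locusLength` values give the same statistics at a fraction of the VCF
#' size. See [simParams()].
#'
#' @slot nIndividuals cohort size.
#' @slot sexRatio proportion of homogametic individuals.
#' @slot lociAutosome,lociX,lociY locus counts per chromosome class.
#' @slot locusLength sites per locus.
#' @slot meanDepth per-individual mean autosomal depth (X-fold); length 1
#'   or `nIndividuals`.
#' @slot xCopyRatio X-chromosome copy factor in the heterogametic sex
#'   (0.5: one X copy versus two).
#' @slot yPresence Y-chromosome capture factor in the homogametic sex
#'   (0: no Y).
#' @slot recoverability named list of Beta shape pairs (`autosome`, `x`,
#'   `y`) for the per-locus capture-probability scaling, or NULL-like empty
#'   list to disable (all loci fully recoverable).
#' @slot overdispersion negative-binomial size parameter for read counts;
#'   NA draws Poisson counts.
#' @slot seed integer seed; the simulation is reproducible given the seed.
#'
#' @export
setClass("SimCohortParams",
  representation(
    nIndividuals = "integer",
    sexRatio = "numeric",
    lociAutosome = "integer",
    lociX = "integer",
    lociY = "integer",
    locusLength = "integer",
    meanDepth = "numeric",
    xCopyRatio = "numeric",
    yPresence = "numeric",
    recoverability = "list",
    overdispersion = "numeric",
    seed = "integer"
  )
)

setValidity("SimCohortParams", function(object) {
  pos1 <- function(x) length(x) == 1L && !is.na(x) && x > 0
  if (!pos1(object@nIndividuals)) return("nIndividuals must be positive")
  if (length(object@sexRatio) != 1L || object@sexRatio < 0 ||
      object@sexRatio > 1)
    return("sexRatio must be in [0, 1]")
  for (s in c("lociAutosome", "lociX", "lociY"))
    if (!pos1(slot(object, s))) return(sprintf("%s must be positive", s))
  if (!pos1(object@locusLength)) return("locusLength must be positive")
  md <- object@meanDepth
  if (!length(md) %in% c(1L, object@nIndividuals))
    return("meanDepth must have length 1 or nIndividuals")
  if (any(is.na(md)) || any(md <= 0))
    return("meanDepth must be positive")
  if (length(object@xCopyRatio) != 1L || object@xCopyRatio < 0)
    return("xCopyRatio must be non-negative")
  if (length(object@yPresence) != 1L || object@yPresence < 0 ||
      object@yPresence > 1)
    return("yPresence must be in [0, 1]")
  if (length(object@recoverability) &&
      !all(c("autosome", "x", "y") %in% names(object@recoverability)))
    return("recoverability must name autosome, x and y Beta shapes")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' SexingReport: bundled result of a full pipeline run
#'
#' @slot calls the [SexCalls-class] object.
#' @slot stats the [SexingStats-class] the calls were computed from.
#' @slot files named list of output file paths (`csv`, `plots`, `stats`,
#'   and `filtered_vcf` when the locus filter ran).
#' @slot counts named list of stage counts (sites read, loci retained,
#'   individuals called, unassigned).
#'
#' @export
setClass("SexingReport",
  representation(
    calls = "SexCalls",
    stats = "SexingStats",
    files = "list",
    counts = "list"
  )
)
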