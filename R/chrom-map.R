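#' Construct a chromosome-class map
#'
#' Assigns reference contigs to chromosome classes. At least one `X_LIKE`
#' and one `Y_LIKE` contig are required; contigs not listed fall back to
#' `default`. The default of `AUTOSOME` matches a chromosome-level assembly
#' where every unlisted contig is an autosome; choose `EXCLUDED` when the
#' reference carries unplaced scaffolds that would otherwise dilute the
#' autosomal depth.
#'
#' For ZW systems, assign the Z to `X_LIKE`, the W to `Y_LIKE`, and swap
#' the sex labels (`homogameticLabel = "male"`, `heterogameticLabel =
#' "female"`): the index arithmetic is identical, only the meaning of the
#' homogametic sex changes.
#'
#' @param contigs named character vector or named list mapping contig
#'   identifiers (as spelled in the VCF) to classes in [CHROM_CLASSES].
#' @param default class for unlisted contigs, `"AUTOSOME"` (default) or
#'   `"EXCLUDED"`.
#' @param homogameticLabel,heterogameticLabel report labels for the two
#'   sexes.
#' @return a validated [ChromClassMap-class].
#' @examples
#' m <- ChromClassMap(c(NC_045612.1 = "X_LIKE", NC_045613.1 = "Y_LIKE"))
#' contigClass(m, c("NC_045612.1", "NC_000001.1"))
#' @export
ChromClassMap <- function(contigs, default = c("AUTOSOME", "EXCLUDED"),
                          homogameticLabel = "female",
                          heterogameticLabel = "male") {
  default <- match.arg(default)
  if (is.list(contigs)) contigs <- unlist(contigs)
  contigs <- vapply(contigs, as.character, character(1))
  new("ChromClassMap", classes = contigs, defaultClass = default,
      homogameticLabel = homogameticLabel,
      heterogameticLabel = heterogameticLabel)
}

#' Read a chromosome-class configuration file
#'
#' The configuration is a small YAML document:
#' ```yaml
#' contigs:
#'   NC_045612.1: X_LIKE
#'   NC_045613.1: Y_LIKE
#' default: AUTOSOME          # optional; AUTOSOME or EXCLUDED
#' labels:                    # optional
#'   homogametic: female
#'   heterogametic: male
#' ```
#' Duplicate contig keys and unknown class labels are configuration
#' errors; a document defining no `X_LIKE` or no `Y_LIKE` contig is
#' rejected because sexing cannot proceed without both.
#'
#' @param path path to the YAML configuration.
#' @return a validated [ChromClassMap-class].
#' @seealso [writeChromMap()] for the inverse.
#' @export
readChromMap <- function(path) {
  if (!file.exists(path))
    stop("chromosome-class configuration not found: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("configuration error in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(doc) || is.null(doc$contigs) || !length(doc$contigs))
    stop("configuration error in ", path,
         ": no contigs classified (no sex chromosomes defined)",
         call. = FALSE)
  lab <- doc$labels
  ChromClassMap(
    contigs = doc$contigs,
    default = if (is.null(doc$default)) "AUTOSOME" else doc$default,
    homogameticLabel =
      if (is.null(lab$homogametic)) "female" else lab$homogametic,
    heterogameticLabel =
      if (is.null(lab$heterogametic)) "male" else lab$heterogametic
  )
}

#' Write a chromosome-class map to its YAML file format
#'
#' `readChromMap(writeChromMap(m, f))` reproduces `m` exactly.
#'
#' @param map a [ChromClassMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChromMap <- function(map, path) {
  stopifnot(is(map, "ChromClassMap"))
  yaml::write_yaml(list(
    contigs = as.list(map@classes),
    default = map@defaultClass,
    labels = list(homogametic = map@homogameticLabel,
                  heterogametic = map@heterogameticLabel)
  ), path)
  invisible(path)
}

#' Look up the chromosome class of contigs
#'
#' @param x a [ChromClassMap-class].
#' @param contigs character vector of contig identifiers.
#' @return character vector of classes, one per contig; unlisted contigs
#'   get the map's default class.
#' @rdname contigClass
#' @export
setMethod("contigClass", "ChromClassMap", function(x, contigs) {
  cls <- unname(x@classes[contigs])
  cls[is.na(cls)] <- x@defaultClass
  cls
})

#' @describeIn ChromClassMap compact display.
#' @param object a `ChromClassMap`.
#' @export
setMethod("show", "ChromClassMap", function(object) {
  tab <- table(factor(object@classes, levels = CHROM_CLASSES))
  cat("ChromClassMap with", length(object@classes), "classified contig(s)\n")
  cat(sprintf("  %s: %d contig(s)\n", names(tab), as.integer(tab)), sep = "")
  cat("  unlisted contigs ->", object@defaultClass, "\n")
  cat(sprintf("  labels: homogametic=%s, heterogametic=%s\n",
              object@homogameticLabel, object@heterogameticLabel))
})

#' Construct run-level parameters
#'
#' Defaults follow the published workflow: locus-sharing proportion 0.3,
#' maximum observed heterozygosity 0.7, Index Y threshold 0.5 (midpoint of
#' the expected homogametic and heterogametic values 1 and 0), low-depth
#' warning at 10X (below which Index X is unreliable and its advisory call
#' is suppressed), 4 decimal places in report CSVs.
#'
#' @param minLocusShareR minimum proportion of individuals sharing a locus.
#' @param maxObsHet maximum per-site observed heterozygosity.
#' @param indexYFemaleThreshold Index Y at or above which the homogametic
#'   sex is called (inclusive).
#' @param lowDepthWarning overall mean depth (X-fold) below which calls are
#'   flagged.
#' @param outputPrecision decimal places for report CSVs.
#' @param depthField FORMAT key carrying per-genotype depth.
#' @param seed optional integer seed recorded with the run.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(minLocusShareR = 0.3, maxObsHet = 0.7,
                      indexYFemaleThreshold = 0.5, lowDepthWarning = 10,
                      outputPrecision = 4L, depthField = "DP",
                      seed = NA_integer_) {
  new("RunConfig",
      minLocusShareR = as.numeric(minLocusShareR),
      maxObsHet = as.numeric(maxObsHet),
      indexYFemaleThreshold = as.numeric(indexYFemaleThreshold),
      lowDepthWarning = as.numeric(lowDepthWarning),
      outputPrecision = as.integer(outputPrecision),
      depthField = as.character(depthField),
      seed = as.integer(seed))
}

#' @describeIn RunConfig compact display.
#' @param object a `RunConfig`.
#' @export
setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  locus-sharing r:", object@minLocusShareR,
      "| max obs het:", object@maxObsHet, "\n")
  cat("  Index Y threshold:", object@indexYFemaleThreshold,
      "| low-depth warning:", object@lowDepthWarning, "X\n")
  cat("  depth field:", object@depthField,
      "| precision:", object@outputPrecision,
      "| seed:", object@seed, "\n")
})
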