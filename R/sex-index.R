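# The two sexing indexes and the calling rule.
#
# Index X = DepthX / DepthA: mean X-chromosome depth over mean autosomal
# depth. The heterogametic sex carries one X copy against two autosomal
# copies, so it is expected at 0.5; the homogametic sex at 1.
#
# Index Y = (ComX - ComY) / ComX, with Com = 1 - missingness: the relative
# completeness deficit of the Y versus the X. The homogametic sex carries
# no Y (ComY = 0, index 1); the heterogametic sex carries one copy of each
# (ComY ~ ComX, index 0). The index can go negative when Y loci are
# recovered more reliably than X loci, as happens at low coverage.
#
# Only Index Y assigns sex; Index X is advisory because it degrades below
# about 10X overall depth.

.pickClass <- function(pc, column) {
  out <- matrix(NA_real_, nrow = length(unique(pc$individual)), ncol = 3,
                dimnames = list(unique(pc$individual), STAT_CLASSES))
  idx <- cbind(match(pc$individual, rownames(out)),
               match(pc$class, STAT_CLASSES))
  ok <- !is.na(idx[, 2])
  out[idx[ok, , drop = FALSE]] <- pc[[column]][ok]
  out
}

#' Index X: ratio of X-chromosome to autosomal mean depth
#'
#' Expected at 1 in the homogametic sex (two X copies, like the
#' autosomes) and 0.5 in the heterogametic sex (one copy). Undefined (NA)
#' for an individual whose autosomal or X mean depth is undefined, or
#' whose autosomal mean depth is 0.
#'
#' @param x a [SexingStats-class].
#' @param ... unused.
#' @return named numeric vector, one value per individual, NA where
#'   undefined.
#' @rdname indexX
#' @export
setMethod("indexX", "SexingStats", function(x, ...) {
  md <- .pickClass(x@perClass, "mean_depth")
  dx <- md[, "X_LIKE"]
  da <- md[, "AUTOSOME"]
  out <- ifelse(is.na(da) | is.na(dx) | da == 0, NA_real_, dx / da)
  stats::setNames(out, rownames(md))
})

#' Index Y: relative completeness deficit of the Y versus the X
#'
#' `(ComX - ComY) / ComX` with completeness = 1 - missingness. Expected at
#' 1 in the homogametic sex (no Y chromosome, Y missingness 1) and 0 in
#' the heterogametic sex (one copy of each sex chromosome). Values below 0
#' occur in heterogametic individuals at low coverage, when the retained Y
#' loci are recovered more reliably than X loci; the negative sign only
#' reinforces the heterogametic call. Undefined (NA) when ComX = 0.
#' Depends only on completeness, never on depth. A cohort whose VCF holds
#' no Y-like sites at all is treated as total Y absence (ComY = 0), so
#' every individual with X data gets Index Y = 1.
#'
#' @param x a [SexingStats-class].
#' @param ... unused.
#' @return named numeric vector, one value per individual, NA where
#'   undefined.
#' @rdname indexY
#' @export
setMethod("indexY", "SexingStats", function(x, ...) {
  com <- .pickClass(x@perClass, "completeness")
  cx <- com[, "X_LIKE"]
  cy <- com[, "Y_LIKE"]
  # a VCF with no Y_LIKE sites at all is total Y absence: ComY = 0
  cy[is.na(cy)] <- 0
  out <- ifelse(is.na(cx) | cx == 0, NA_real_, (cx - cy) / cx)
  stats::setNames(out, rownames(com))
})

#' Assign sex from the two indexes
#'
#' Only Index Y determines the assignment: at or above
#' `indexYFemaleThreshold` (inclusive) the individual is called
#' homogametic, below it heterogametic, and with Index Y undefined it is
#' unassigned with a reason. Index X yields an advisory call by nearest
#' expected value (1 for homogametic, 0.5 for heterogametic, so the
#' midpoint 0.75 separates them); the advisory call is suppressed
#' (unassigned) when the individual's overall depth is below
#' `lowDepthWarning`, the regime in which Index X is known to fail.
#'
#' @param indexX,indexY numeric vectors of equal length (NA = undefined).
#' @param overallDepth overall mean depth per individual (X-fold).
#' @param config a [RunConfig-class]; supplies the threshold and the
#'   low-depth limit.
#' @return data.frame with columns `sex_by_y`, `sex_by_x` (values
#'   `homogametic` / `heterogametic` / `unassigned`), `low_depth_flag`,
#'   `agreement_flag` and `reason`.
#' @export
assignSex <- function(indexX, indexY, overallDepth, config = runConfig()) {
  stopifnot(is(config, "RunConfig"))
  n <- max(length(indexX), length(indexY), length(overallDepth))
  indexX <- rep_len(indexX, n)
  indexY <- rep_len(indexY, n)
  overallDepth <- rep_len(overallDepth, n)
  lowDepth <- !is.na(overallDepth) & overallDepth < config@lowDepthWarning
  sexByY <- ifelse(is.na(indexY), "unassigned",
                   ifelse(indexY >= config@indexYFemaleThreshold,
                          "homogametic", "heterogametic"))
  sexByX <- ifelse(is.na(indexX) | lowDepth, "unassigned",
                   ifelse(abs(indexX - 1) <= abs(indexX - 0.5),
                          "homogametic", "heterogametic"))
  agree <- sexByY != "unassigned" & sexByX != "unassigned" &
    sexByY == sexByX
  reason <- character(n)
  reason[is.na(indexY)] <- "Index Y undefined (X completeness is zero)"
  reason[is.na(indexY) & is.na(indexX)] <-
    "both indexes undefined (no usable X-chromosome data)"
  data.frame(sex_by_y = sexByY, sex_by_x = sexByX,
             low_depth_flag = lowDepth, agreement_flag = agree,
             reason = reason)
}

#' Classify a whole cohort
#'
#' Computes both indexes from accumulated statistics, applies the calling
#' rule to every individual, and attaches the depth and completeness
#' quantities the indexes were computed from.
#'
#' @param stats a [SexingStats-class] (non-empty).
#' @param config a [RunConfig-class].
#' @param map optional [ChromClassMap-class]; supplies the sex labels
#'   attached to calls (defaults "female" homogametic / "male"
#'   heterogametic).
#' @return a [SexCalls-class].
#' @export
classifyCohort <- function(stats, config = runConfig(), map = NULL) {
  stopifnot(is(stats, "SexingStats"))
  if (!length(stats@samples) || !nrow(stats@perClass))
    stop("empty statistics: no individuals to classify", call. = FALSE)
  labels <- if (is.null(map)) c(homogametic = "female",
                                heterogametic = "male")
            else c(homogametic = map@homogameticLabel,
                   heterogametic = map@heterogameticLabel)
  md <- .pickClass(stats@perClass, "mean_depth")
  com <- .pickClass(stats@perClass, "completeness")
  ids <- rownames(md)
  ix <- indexX(stats)[ids]
  iy <- indexY(stats)[ids]
  ov <- stats@overall$mean_depth[match(ids, stats@overall$individual)]
  asg <- assignSex(ix, iy, ov, config)
  sex <- ifelse(asg$sex_by_y == "unassigned", "unassigned",
                unname(labels[asg$sex_by_y]))
  calls <- data.frame(
    individual = ids,
    depth_a = md[, "AUTOSOME"], depth_x = md[, "X_LIKE"],
    depth_y = md[, "Y_LIKE"],
    com_x = com[, "X_LIKE"], com_y = com[, "Y_LIKE"],
    index_x = unname(ix), index_y = unname(iy),
    overall_mean_depth = ov,
    sex_by_y = asg$sex_by_y, sex_by_x = asg$sex_by_x, sex = sex,
    low_depth_flag = asg$low_depth_flag,
    agreement_flag = asg$agreement_flag,
    reason = asg$reason,
    row.names = NULL)
  new("SexCalls", calls = calls, labels = labels,
      threshold = config@indexYFemaleThreshold)
}

#' Access sex-call results
#'
#' `sexCalls()` returns the per-individual call table; `cohortSummary()`
#' tallies calls per sex plus unassigned and flagged counts.
#'
#' @param x a [SexCalls-class].
#' @param ... unused.
#' @rdname sexCalls
#' @export
setMethod("sexCalls", "SexCalls", function(x, ...) x@calls)

#' @rdname sexCalls
#' @export
setMethod("cohortSummary", "SexCalls", function(x, ...) {
  cl <- x@calls
  out <- list(n = nrow(cl))
  for (lab in unname(x@labels)) out[[lab]] <- sum(cl$sex == lab)
  out$unassigned <- sum(cl$sex == "unassigned")
  out$low_depth <- sum(cl$low_depth_flag)
  out$index_disagreement <- sum(!cl$agreement_flag &
                                  cl$sex_by_x != "unassigned" &
                                  cl$sex_by_y != "unassigned")
  out
})

#' @describeIn SexCalls compact display.
#' @param object a `SexCalls`.
#' @export
setMethod("show", "SexCalls", function(object) {
  s <- cohortSummary(object)
  cat("SexCalls:", s$n, "individual(s)\n")
  for (lab in c(unname(object@labels), "unassigned"))
    cat(sprintf("  %s: %d\n", lab, s[[lab]]))
  cat("  low-depth flagged:", s$low_depth,
      "| index disagreement:", s$index_disagreement, "\n")
  cat("  Index Y threshold:", object@threshold, "\n")
})
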