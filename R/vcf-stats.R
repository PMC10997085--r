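# All-sites VCF streaming: per-individual, per-chromosome-class
# missingness and mean-depth accumulation. The accumulator is the
# quantitative core of the method: both sexing indexes are pure functions
# of what it computes.

.vcfOpen <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt")
  else file(path, open = "rt")
}

# k-th colon-separated FORMAT field, vectorised; k = 1 is the common case
.fmtField <- function(x, k) {
  if (k == 1L) sub(":.*$", "", x)
  else sub(sprintf("^(?:[^:]*:){%d}([^:]*).*$", k - 1L), "\\1", x,
           perl = TRUE)
}

# read header lines off an open connection; stops at the #CHROM line
.vcfReadHeader <- function(con, path) {
  meta <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln))
      stop("not a VCF: no #CHROM header line in ", path, call. = FALSE)
    if (startsWith(ln, "##")) { meta <- c(meta, ln); next }
    if (startsWith(ln, "#CHROM")) break
    stop("not a VCF: unexpected line before #CHROM in ", path, call. = FALSE)
  }
  cols <- strsplit(ln, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("VCF has no sample columns: ", path, call. = FALSE)
  fileformat <- grep("^##fileformat=", meta, value = TRUE)
  contigs <- sub('^##contig=<ID=([^,>]+).*$', "\\1",
                 grep("^##contig=", meta, value = TRUE))
  fmt <- sub('^##FORMAT=<ID=([^,>]+).*$', "\\1",
             grep("^##FORMAT=", meta, value = TRUE))
  list(samples = cols[-(1:9)], contigs = contigs, formatIds = fmt,
       fileformat = sub("^##fileformat=", "", fileformat[1]))
}

#' Validate an all-sites VCF before accumulation
#'
#' Checks that the file parses as VCF 4.x, carries sample columns, and
#' declares a per-genotype depth field (all-sites VCFs without depth cannot
#' support Index X). When a [ChromClassMap-class] is supplied and the VCF
#' header lists its contigs, a missing overlap with the map's `X_LIKE` or
#' `Y_LIKE` contigs is surfaced as a warning in the summary.
#'
#' @param path path to a plain or gzip-compressed VCF.
#' @param map optional [ChromClassMap-class] for contig-overlap checks.
#' @param depthField FORMAT key expected to carry per-genotype depth.
#' @return a list with elements `samples`, `contigs`, `formatIds`,
#'   `fileformat` and `warnings` (character, possibly empty).
#' @export
validateVcf <- function(path, map = NULL, depthField = "DP") {
  if (!file.exists(path))
    stop("VCF not found: ", path, call. = FALSE)
  con <- .vcfOpen(path)
  on.exit(close(con))
  hdr <- .vcfReadHeader(con, path)
  if (!is.na(hdr$fileformat) && !grepl("^VCFv4", hdr$fileformat))
    stop("unsupported VCF version '", hdr$fileformat, "' in ", path,
         call. = FALSE)
  fmt <- hdr$formatIds
  if (!length(fmt)) {
    # headerless minimal VCF: fall back to the first record's FORMAT column
    rec <- readLines(con, n = 1L)
    if (length(rec)) {
      fields <- strsplit(rec, "\t", fixed = TRUE)[[1]]
      if (length(fields) >= 9L)
        fmt <- strsplit(fields[9], ":", fixed = TRUE)[[1]]
    }
  }
  if (!depthField %in% fmt)
    stop("no per-genotype depth field '", depthField, "' in ", path,
         ": sexing requires a depth-bearing all-sites VCF ",
         "(e.g. STACKS populations --vcf-all output)", call. = FALSE)
  warnings <- character()
  if (!is.null(map) && length(hdr$contigs)) {
    cls <- contigClass(map, hdr$contigs)
    if (!any(cls == "X_LIKE"))
      warnings <- c(warnings,
        "no VCF contig is classified X_LIKE by the chromosome map")
    if (!any(cls == "Y_LIKE"))
      warnings <- c(warnings,
        "no VCF contig is classified Y_LIKE by the chromosome map")
  }
  c(hdr, list(warnings = warnings))
}

#' Construct a SexingStats object from per-class counts
#'
#' Derived columns (`n_nonmissing`, `missingness`, `completeness`,
#' `mean_depth`) and the pooled per-individual `overall` table are computed
#' here so that every construction route enforces the same identities.
#' Mostly useful for constructing analytic fixtures; [accumulateStats()]
#' builds these objects from a VCF.
#'
#' @param perClass data.frame with columns `individual`, `class`,
#'   `n_sites`, `n_missing`, `depth_sum` (and optionally `n_nonmissing`).
#' @param samples sample identifiers; defaults to the individuals present.
#' @return a validated [SexingStats-class].
#' @examples
#' # female-pattern fixture: X depth = autosomal depth, no Y sites present
#' SexingStats(data.frame(
#'   individual = "f1",
#'   class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
#'   n_sites = c(100, 100, 50),
#'   n_missing = c(0, 10, 50),
#'   depth_sum = c(2000, 1800, 0)))
#' @export
SexingStats <- function(perClass, samples = NULL) {
  pc <- as.data.frame(perClass)
  need <- c("individual", "class", "n_sites", "n_missing", "depth_sum")
  if (!all(need %in% names(pc)))
    stop("perClass needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  pc$individual <- as.character(pc$individual)
  pc$n_sites <- as.numeric(pc$n_sites)
  pc$n_missing <- as.numeric(pc$n_missing)
  pc$depth_sum <- as.numeric(pc$depth_sum)
  if (is.null(pc$n_nonmissing))
    pc$n_nonmissing <- pc$n_sites - pc$n_missing
  pc$missingness <- ifelse(pc$n_sites > 0, pc$n_missing / pc$n_sites, NA)
  pc$completeness <- ifelse(pc$n_sites > 0, 1 - pc$n_missing / pc$n_sites, NA)
  pc$mean_depth <- ifelse(pc$n_nonmissing > 0,
                          pc$depth_sum / pc$n_nonmissing, NA)
  if (is.null(samples)) samples <- unique(pc$individual)
  if (!nrow(pc))
    return(new("SexingStats", perClass = pc,
               overall = data.frame(individual = character(),
                                    n_sites = numeric(),
                                    n_nonmissing = numeric(),
                                    depth_sum = numeric(),
                                    mean_depth = numeric()),
               samples = as.character(samples)))
  ov <- do.call(rbind, lapply(split(pc, pc$individual), function(d)
    data.frame(individual = d$individual[1],
               n_sites = sum(d$n_sites),
               n_nonmissing = sum(d$n_nonmissing),
               depth_sum = sum(d$depth_sum))))
  ov <- ov[match(intersect(samples, ov$individual), ov$individual), ,
           drop = FALSE]
  ov$mean_depth <- ifelse(ov$n_nonmissing > 0,
                          ov$depth_sum / ov$n_nonmissing, NA)
  rownames(pc) <- NULL
  rownames(ov) <- NULL
  new("SexingStats", perClass = pc, overall = ov,
      samples = as.character(samples))
}

#' Accumulate per-individual, per-class statistics from an all-sites VCF
#'
#' Streams the VCF record by record (chunked, so memory use is independent
#' of file size) and accumulates, for every sample and chromosome class,
#' the number of sites, missing genotypes, and the depth sum over
#' non-missing sites. Sites on `EXCLUDED` contigs are skipped; every other
#' site counts towards exactly one class.
#'
#' A genotype is missing when any GT allele is the missing symbol `.`
#' (half-missing diploid calls count as missing). Depth is read from the
#' configured FORMAT key over non-missing genotypes only; a missing
#' genotype's depth value, if present, is ignored, and a non-missing
#' genotype without a numeric depth value contributes depth 0. The
#' statistics depend only on genotype missingness and depth, never on the
#' alleles, so invariant and multi-allelic records are handled identically.
#'
#' @param path path to a plain or gzip-compressed all-sites VCF.
#' @param map a [ChromClassMap-class] classifying the VCF's contigs.
#' @param depthField FORMAT key carrying per-genotype depth.
#' @param chunkSize records read per chunk.
#' @return a [SexingStats-class] with one per-class row per sample and
#'   class in `AUTOSOME`, `X_LIKE`, `Y_LIKE`.
#' @export
accumulateStats <- function(path, map, depthField = "DP",
                            chunkSize = 5000L) {
  stopifnot(is(map, "ChromClassMap"))
  con <- .vcfOpen(path)
  on.exit(close(con))
  hdr <- .vcfReadHeader(con, path)
  samples <- hdr$samples
  n <- length(samples)
  nSites <- stats::setNames(numeric(3), STAT_CLASSES)
  zero <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(STAT_CLASSES, samples))
  nMiss <- zero; nNon <- zero; dSum <- zero
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    lines <- lines[nzchar(lines)]
    if (!length(lines)) next
    parts <- strsplit(lines, "\t", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 9L + n)) {
      bad <- parts[[which(len != 9L + n)[1]]]
      stop(sprintf(
        "truncated or corrupt VCF record at %s:%s (%d of %d fields)",
        if (length(bad)) bad[1] else "?", if (length(bad) > 1) bad[2] else "?",
        length(bad), 9L + n), call. = FALSE)
    }
    m <- matrix(unlist(parts, use.names = FALSE), ncol = 9L + n,
                byrow = TRUE)
    cls <- contigClass(map, m[, 1])
    keep <- cls != "EXCLUDED"
    if (!any(keep)) next
    m <- m[keep, , drop = FALSE]
    cls <- cls[keep]
    fmt <- m[, 9]
    for (f in unique(fmt)) {
      rows <- which(fmt == f)
      keys <- strsplit(f, ":", fixed = TRUE)[[1]]
      gtIdx <- match("GT", keys)
      dpIdx <- match(depthField, keys)
      if (is.na(gtIdx) || is.na(dpIdx))
        stop(sprintf("record at %s:%s lacks %s in FORMAT '%s'",
                     m[rows[1], 1], m[rows[1], 2],
                     if (is.na(gtIdx)) "GT" else depthField, f),
             call. = FALSE)
      cells <- m[rows, 10:(9L + n), drop = FALSE]
      gt <- .fmtField(cells, gtIdx)
      miss <- grepl(".", gt, fixed = TRUE)
      dp <- suppressWarnings(as.numeric(.fmtField(cells, dpIdx)))
      dp[is.na(dp) | miss] <- 0
      dim(miss) <- dim(cells); dim(dp) <- dim(cells)
      for (cc in unique(cls[rows])) {
        rr <- rows[cls[rows] == cc]
        sel <- match(rr, rows)
        nSites[cc] <- nSites[cc] + length(rr)
        nMiss[cc, ] <- nMiss[cc, ] + colSums(miss[sel, , drop = FALSE])
        nNon[cc, ] <- nNon[cc, ] + colSums(!miss[sel, , drop = FALSE])
        dSum[cc, ] <- dSum[cc, ] + colSums(dp[sel, , drop = FALSE])
      }
    }
  }
  perClass <- data.frame(
    individual = rep(samples, each = 3),
    class = rep(STAT_CLASSES, times = n),
    n_sites = rep(nSites, times = n),
    n_missing = as.vector(nMiss[, seq_len(n), drop = FALSE]),
    n_nonmissing = as.vector(nNon[, seq_len(n), drop = FALSE]),
    depth_sum = as.vector(dSum[, seq_len(n), drop = FALSE]))
  SexingStats(perClass, samples = samples)
}

#' Access the statistics tables of a SexingStats object
#'
#' `classStats()` returns the per-individual, per-class table;
#' `overallStats()` the per-individual totals pooled across classes.
#'
#' @param x a [SexingStats-class].
#' @param ... unused.
#' @return a data.frame.
#' @rdname classStats
#' @export
setMethod("classStats", "SexingStats", function(x, ...) x@perClass)

#' @rdname classStats
#' @export
setMethod("overallStats", "SexingStats", function(x, ...) x@overall)

#' Tidy audit table of per-individual per-class statistics
#'
#' The audit layout written by the pipeline: one row per individual and
#' class with site counts, missingness and mean depth.
#'
#' @param stats a [SexingStats-class].
#' @return data.frame with columns `individual`, `class`, `n_sites`,
#'   `n_missing`, `missingness`, `mean_depth`.
#' @export
statsTable <- function(stats) {
  stopifnot(is(stats, "SexingStats"))
  pc <- stats@perClass
  pc[, c("individual", "class", "n_sites", "n_missing", "missingness",
         "mean_depth")]
}

#' @describeIn SexingStats compact display.
#' @param object a `SexingStats`.
#' @export
setMethod("show", "SexingStats", function(object) {
  ns <- tapply(object@perClass$n_sites, object@perClass$class, max)
  cat("SexingStats:", length(object@samples), "individual(s)\n")
  for (cc in STAT_CLASSES)
    cat(sprintf("  %s: %s site(s)\n", cc,
                format(if (cc %in% names(ns)) ns[[cc]] else 0)))
  md <- object@overall$mean_depth
  if (length(md))
    cat(sprintf("  overall mean depth: %.2f-%.2fX\n",
                min(md, na.rm = TRUE), max(md, na.rm = TRUE)))
})
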