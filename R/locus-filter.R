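# Locus-level retention filters applied upstream of index computation:
# minimum locus-sharing proportion across individuals (the STACKS -R
# filter, single-population semantics) and maximum per-site observed
# heterozygosity (purges paralog-collapsed loci). This stage is optional:
# cohorts arriving as already-filtered populations output skip it.

.requireVcfR <- function() {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the locus-filter module needs the vcfR package", call. = FALSE)
}

# GT missingness and heterozygosity without relying on ploidy:
# an allele equal to '.' makes the genotype missing; a genotype whose two
# sides of / or | differ is heterozygous (haploid calls are never het)
.gtMissing <- function(gt) is.na(gt) | grepl(".", gt, fixed = TRUE)

.gtHet <- function(gt, miss) {
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  !miss & a1 != a2
}

#' Group the sites of an all-sites VCF into RAD loci
#'
#' When every record carries a locus identifier in the VCF ID column (as
#' STACKS all-sites output does), grouping uses those identifiers verbatim
#' (scoped within contig). Otherwise, consecutive sites on one contig with
#' an inter-site gap of at most `maxGap` form one locus — with the default
#' `maxGap = 1`, a locus is a run of strictly consecutive positions, the
#' shape single-end RAD loci take in an all-sites VCF.
#'
#' @param path path to a plain or gzip-compressed all-sites VCF, sorted by
#'   contig then position (unsorted input is an error).
#' @param maxGap largest inter-site gap joined into one locus when no IDs
#'   are available.
#' @return a [LocusTable-class].
#' @export
groupLoci <- function(path, maxGap = 1L) {
  .requireVcfR()
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L)
    stop("VCF has no records: ", path, call. = FALSE)
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  # sorted check: positions non-decreasing within contig, contigs in blocks
  newContig <- c(TRUE, contig[-1] != contig[-length(contig)])
  if (length(pos) > 1L) {
    same <- !newContig[-1]
    if (any(same & diff(pos) < 0L))
      stop("VCF is not sorted by position within contig", call. = FALSE)
  }
  if (anyDuplicated(rle(contig)$values))
    stop("VCF is not sorted: contig appears in non-contiguous blocks",
         call. = FALSE)
  haveIds <- all(!is.na(id) & nzchar(id) & id != ".")
  if (haveIds) {
    key <- paste(contig, id, sep = "\r")
    newLocus <- c(TRUE, key[-1] != key[-length(key)])
    locus <- cumsum(newLocus)
    locusId <- id[newLocus]
  } else {
    gap <- c(0L, diff(pos))
    newLocus <- newContig | gap > maxGap
    locus <- cumsum(newLocus)
    locusId <- sprintf("locus_%05d", seq_len(sum(newLocus)))
  }
  gtMat <- v@gt[, -1, drop = FALSE]   # column 1 is FORMAT
  samples <- colnames(gtMat)
  gt <- .fmtField(gtMat, 1L)          # GT is the first FORMAT field per spec 4.x
  miss <- .gtMissing(gt)
  het <- .gtHet(gt, miss)
  dim(miss) <- dim(gtMat); dim(het) <- dim(gtMat)
  nonMiss <- rowSums(!miss)
  obsHet <- ifelse(nonMiss > 0, rowSums(het) / nonMiss, NA)
  presence <- rowsum((!miss) * 1L, locus) > 0L
  colnames(presence) <- samples
  loci <- data.frame(
    locus_id = locusId,
    contig = contig[newLocus],
    start = tapply(pos, locus, min),
    end = tapply(pos, locus, max),
    n_sites = as.integer(table(locus)),
    max_obs_het = as.numeric(tapply(obsHet, locus, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))),
    row.names = NULL)
  sites <- data.frame(contig = contig, pos = pos, id = id,
                      locus = locus, obs_het = obsHet)
  rownames(presence) <- NULL
  new("LocusTable", loci = loci, presence = presence,
      sites = sites, samples = samples)
}

#' Apply the locus-sharing and heterozygosity retention filters
#'
#' A locus is retained iff (a) it is present (at least one non-missing
#' genotype among its member sites) in at least `ceiling(r * N)` of the N
#' samples — "at least a proportion r" is an inclusive lower bound, hence
#' the ceiling — and (b) no member site has observed heterozygosity
#' exceeding `maxObsHet`. A single offending site vetoes its whole locus.
#' With `r = 0` and `maxObsHet = 1` the filter is the identity.
#'
#' @param table a [LocusTable-class] from [groupLoci()].
#' @param r minimum locus-sharing proportion in \[0, 1\].
#' @param maxObsHet maximum tolerated per-site observed heterozygosity.
#' @return a list with elements `table` (the retained [LocusTable-class])
#'   and `report` (named list: `n_input`, `n_retained`,
#'   `dropped_presence`, `dropped_het`; loci failing both rules count in
#'   both drop tallies).
#' @export
filterLoci <- function(table, r = 0.3, maxObsHet = 0.7) {
  stopifnot(is(table, "LocusTable"), r >= 0, r <= 1,
            maxObsHet >= 0, maxObsHet <= 1)
  nLoci <- nrow(table@loci)
  if (nLoci == 0L) {
    warning("empty locus table: nothing to filter")
    return(list(table = table,
                report = list(n_input = 0L, n_retained = 0L,
                              dropped_presence = 0L, dropped_het = 0L)))
  }
  nSamples <- length(table@samples)
  needed <- ceiling(r * nSamples)
  presCount <- rowSums(table@presence)
  okPres <- presCount >= needed
  mh <- table@loci$max_obs_het
  okHet <- is.na(mh) | mh <= maxObsHet
  keep <- okPres & okHet
  keepIdx <- which(keep)
  sites <- table@sites[table@sites$locus %in% keepIdx, , drop = FALSE]
  sites$locus <- match(sites$locus, keepIdx)
  out <- new("LocusTable",
             loci = table@loci[keep, , drop = FALSE],
             presence = table@presence[keep, , drop = FALSE],
             sites = sites, samples = table@samples)
  rownames(out@loci) <- NULL
  rownames(out@sites) <- NULL
  list(table = out,
       report = list(n_input = nLoci, n_retained = sum(keep),
                     dropped_presence = sum(!okPres),
                     dropped_het = sum(okPres & !okHet)))
}

#' Write the subset VCF containing only retained loci
#'
#' Streams the original VCF, preserving its header verbatim and keeping
#' exactly the records whose (contig, position) belongs to a retained
#' locus.
#'
#' @param path input VCF (plain or gzip).
#' @param table the retained [LocusTable-class] from [filterLoci()].
#' @param out output path; a `.gz` suffix selects gzip compression.
#' @return `out`, invisibly.
#' @export
writeFilteredVcf <- function(path, table, out) {
  stopifnot(is(table, "LocusTable"))
  keepKey <- paste(table@sites$contig, table@sites$pos, sep = "\r")
  con <- .vcfOpen(path)
  on.exit(close(con), add = TRUE)
  ocon <- if (grepl("\\.gz$", out)) gzfile(out, "wt") else file(out, "wt")
  on.exit(close(ocon), add = TRUE)
  repeat {
    lines <- readLines(con, n = 5000L)
    if (!length(lines)) break
    isHdr <- startsWith(lines, "#")
    keep <- isHdr
    idx <- which(!isHdr)
    if (length(idx)) {
      recs <- lines[idx]
      contig <- sub("\t.*$", "", recs)
      pos <- sub("^[^\t]*\t([^\t]*)\t.*$", "\\1", recs)
      keep[idx] <- paste(contig, as.integer(pos), sep = "\r") %in% keepKey
    }
    writeLines(lines[keep], ocon)
  }
  invisible(out)
}

#' @describeIn LocusTable compact display.
#' @param object a `LocusTable`.
#' @export
setMethod("show", "LocusTable", function(object) {
  cat("LocusTable:", nrow(object@loci), "locus/loci,",
      nrow(object@sites), "site(s),", length(object@samples),
      "sample(s)\n")
  if (nrow(object@loci)) {
    tab <- table(object@loci$contig)
    cat(sprintf("  %s: %d locus/loci\n", names(tab), as.integer(tab)),
        sep = "")
  }
})
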