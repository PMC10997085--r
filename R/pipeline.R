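# End-to-end orchestration: validate -> (optional locus filter) ->
# accumulate -> classify -> final_sexing.csv + sexing_plots.pdf + audit
# stats CSV. Logging goes to standard error via message().

.roundCols <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write the per-individual sexing report CSV
#'
#' Numeric columns are rounded to the configured precision; the layout is
#' a superset of everything the indexes and dispersion plots need.
#' Re-running on identical inputs yields a byte-identical file.
#'
#' @param calls a [SexCalls-class].
#' @param path output path.
#' @param precision decimal places.
#' @return `path`, invisibly.
#' @export
writeSexingCsv <- function(calls, path, precision = 4L) {
  stopifnot(is(calls, "SexCalls"))
  utils::write.csv(.roundCols(sexCalls(calls), precision), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw the three dispersion plots
#'
#' One page each: Index X vs Index Y, Index X vs overall coverage depth,
#' and Index Y vs overall coverage depth. Points are coloured by assigned
#' sex; panels with an Index Y axis carry a blue horizontal reference line
#' at the calling threshold (the line that separates the sexes). Points
#' with an undefined index are omitted from the panels needing it, with
#' the omission counted in the caption; if every index is undefined a
#' placeholder page is drawn and a warning raised.
#'
#' @param calls a [SexCalls-class] with at least one row.
#' @param file output PDF path.
#' @param width,height page size in inches.
#' @return `file`, invisibly.
#' @export
makeSexingPlots <- function(calls, file, width = 6, height = 5) {
  stopifnot(is(calls, "SexCalls"))
  df <- sexCalls(calls)
  if (!nrow(df)) stop("no individuals to plot", call. = FALSE)
  thr <- calls@threshold
  sexes <- c(unname(calls@labels), "unassigned")
  cols <- stats::setNames(c("black", "red", "grey50"), sexes)
  df$sex <- factor(df$sex, levels = sexes)
  panel <- function(d, xvar, yvar, xlab, ylab, hline) {
    omitted <- nrow(df) - nrow(d)
    cap <- if (omitted > 0)
      sprintf("%d individual(s) with undefined index omitted", omitted)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]],
                                         y = .data[[yvar]],
                                         colour = .data$sex)) +
      ggplot2::geom_point(size = 2, alpha = 0.8) +
      ggplot2::scale_colour_manual(values = cols, drop = FALSE) +
      ggplot2::labs(x = xlab, y = ylab, colour = "sex", caption = cap) +
      ggplot2::theme_bw()
    if (!is.null(hline))
      p <- p + ggplot2::geom_hline(yintercept = hline, colour = "blue")
    p
  }
  placeholder <- function(label) {
    ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = label) +
      ggplot2::theme_void()
  }
  dxy <- df[!is.na(df$index_x) & !is.na(df$index_y), ]
  dx <- df[!is.na(df$index_x) & !is.na(df$overall_mean_depth), ]
  dy <- df[!is.na(df$index_y) & !is.na(df$overall_mean_depth), ]
  if (!nrow(dxy) && !nrow(dx) && !nrow(dy))
    warning("all indexes undefined: plots contain placeholders only")
  grDevices::pdf(file, width = width, height = height, onefile = TRUE)
  on.exit(grDevices::dev.off())
  print(if (nrow(dxy)) panel(dxy, "index_x", "index_y",
                             "Index X", "Index Y", thr)
        else placeholder("Index X vs Index Y: no defined values"))
  print(if (nrow(dx)) panel(dx, "overall_mean_depth", "index_x",
                            "Overall coverage depth (X)", "Index X", NULL)
        else placeholder("Index X vs coverage depth: no defined values"))
  print(if (nrow(dy)) panel(dy, "overall_mean_depth", "index_y",
                            "Overall coverage depth (X)", "Index Y", thr)
        else placeholder("Index Y vs coverage depth: no defined values"))
  invisible(file)
}

#' Run the sexing pipeline end to end
#'
#' Validates the VCF, optionally applies the locus retention filters
#' (writing the subset VCF that downstream statistics are computed from),
#' accumulates per-individual per-class statistics, classifies the cohort,
#' and writes `final_sexing.csv`, `sexing_plots.pdf` and the audit
#' statistics table `class_stats.csv` into `outDir`. On any stage error,
#' partial outputs are removed before the error propagates with its stage
#' name.
#'
#' @param vcf path to the all-sites VCF (plain or gzip).
#' @param chromMap a [ChromClassMap-class], or the path of its YAML file.
#' @param config a [RunConfig-class].
#' @param outDir output directory (created if needed).
#' @param locusFilter apply the locus-sharing/heterozygosity filters
#'   before accumulation (off by default: cohorts arriving as filtered
#'   populations output have had them applied upstream).
#' @param maxGap locus-grouping gap passed to [groupLoci()] when
#'   filtering.
#' @param plots draw `sexing_plots.pdf`.
#' @param verbose log stage counts to standard error.
#' @return a [SexingReport-class], invisibly.
#' @export
runSexingPipeline <- function(vcf, chromMap, config = runConfig(),
                              outDir = ".", locusFilter = FALSE,
                              maxGap = 1L, plots = TRUE, verbose = TRUE) {
  stopifnot(is(config, "RunConfig"))
  map <- if (is(chromMap, "ChromClassMap")) chromMap
         else readChromMap(chromMap)
  log <- function(...) if (verbose) message("[sexRAD] ", ...)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "validate"
  tryCatch({
    hdr <- validateVcf(vcf, map = map, depthField = config@depthField)
    for (w in hdr$warnings) warning(w, call. = FALSE)
    log(sprintf("validated %s: %d sample(s)", vcf, length(hdr$samples)))
    files <- list()
    counts <- list(n_samples = length(hdr$samples))
    statsInput <- vcf
    if (locusFilter) {
      stage <- "locus filter"
      tab <- groupLoci(vcf, maxGap = maxGap)
      flt <- filterLoci(tab, r = config@minLocusShareR,
                        maxObsHet = config@maxObsHet)
      counts$loci_input <- flt$report$n_input
      counts$loci_retained <- flt$report$n_retained
      log(sprintf(paste0("locus filter: %d of %d loci retained ",
                         "(%d failed sharing, %d failed heterozygosity)"),
                  flt$report$n_retained, flt$report$n_input,
                  flt$report$dropped_presence, flt$report$dropped_het))
      statsInput <- file.path(outDir, "filtered.all.vcf")
      written <- c(written, statsInput)
      writeFilteredVcf(vcf, flt$table, statsInput)
      files$filtered_vcf <- statsInput
    }
    stage <- "statistics accumulation"
    stats <- accumulateStats(statsInput, map,
                             depthField = config@depthField)
    nSites <- sum(tapply(stats@perClass$n_sites, stats@perClass$class,
                         max))
    counts$sites_counted <- as.integer(nSites)
    log(sprintf("accumulated %d site(s) across %d class(es)",
                as.integer(nSites),
                length(unique(stats@perClass$class))))
    if (all(stats@perClass$n_sites[stats@perClass$class == "Y_LIKE"] == 0))
      warning("no Y_LIKE sites in the VCF: Index Y is 1 for every ",
              "individual with X data", call. = FALSE)
    stage <- "classification"
    calls <- classifyCohort(stats, config = config, map = map)
    s <- cohortSummary(calls)
    counts$individuals_called <- s$n - s$unassigned
    counts$unassigned <- s$unassigned
    log(sprintf("called %d individual(s): %s; %d unassigned",
                s$n,
                paste(sprintf("%d %s", unlist(s[unname(calls@labels)]),
                              unname(calls@labels)), collapse = ", "),
                s$unassigned))
    stage <- "report writing"
    files$csv <- file.path(outDir, "final_sexing.csv")
    written <- c(written, files$csv)
    writeSexingCsv(calls, files$csv, precision = config@outputPrecision)
    files$stats <- file.path(outDir, "class_stats.csv")
    written <- c(written, files$stats)
    utils::write.csv(.roundCols(statsTable(stats),
                                config@outputPrecision),
                     files$stats, row.names = FALSE, quote = FALSE)
    if (plots) {
      stage <- "plotting"
      files$plots <- file.path(outDir, "sexing_plots.pdf")
      written <- c(written, files$plots)
      makeSexingPlots(calls, files$plots)
    }
    log("wrote ", paste(unlist(files), collapse = ", "))
    invisible(new("SexingReport", calls = calls, stats = stats,
                  files = files, counts = counts))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @describeIn SexingReport compact display.
#' @param object a `SexingReport`.
#' @export
setMethod("show", "SexingReport", function(object) {
  cat("SexingReport\n")
  for (nm in names(object@counts))
    cat(sprintf("  %s: %s\n", nm, format(object@counts[[nm]])))
  cat("  files:", paste(unlist(object@files), collapse = ", "), "\n")
  show(object@calls)
})
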