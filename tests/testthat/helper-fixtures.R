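# Fixture builders and the independent (vcfR-based, naive) recount oracle.
# All fixtures are generated in code at test time.

# write a small VCF from genotype/depth matrices (sites x samples)
makeVcf <- function(path, contig, pos, gt, dp = NULL, id = ".",
                    format = "GT:DP",
                    samples = paste0("s", seq_len(ncol(as.matrix(gt)))),
                    declareDp = TRUE) {
  gt <- as.matrix(gt)
  if (!is.null(dp)) dp <- as.matrix(dp)
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  cells <- Reduce(function(acc, k) {
    f <- switch(k, GT = gt, DP = dp,
                matrix("7,3", nrow(gt), ncol(gt)))  # filler for other keys
    if (is.null(acc)) f else matrix(paste(acc, f, sep = ":"), nrow(gt))
  }, keys, accumulate = FALSE, init = NULL)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(contig)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (declareDp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if ("AD" %in% keys)
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- do.call(paste, c(
    list(contig, pos, id, "A", ".", ".", "PASS", ".", format),
    lapply(seq_len(ncol(cells)), function(j) cells[, j]),
    list(sep = "\t")))
  writeLines(c(header, body), path)
  path
}

testChromMap <- function()
  ChromClassMap(c(chrX = "X_LIKE", chrY = "Y_LIKE", scaf = "EXCLUDED"),
                default = "AUTOSOME")

# random all-sites fixture exercising missing genotypes, "." depth values,
# excluded contigs, and multi-key FORMAT layouts
randomFixture <- function(path, seed, nSites = NULL, nSamples = NULL) {
  set.seed(seed)
  if (is.null(nSites)) nSites <- sample(20:300, 1)
  if (is.null(nSamples)) nSamples <- sample(2:10, 1)
  contigs <- sort(factor(
    sample(c("chrA", "chrB", "chrX", "chrY", "scaf"), nSites,
           replace = TRUE, prob = c(0.35, 0.2, 0.25, 0.1, 0.1)),
    levels = c("chrA", "chrB", "chrX", "chrY", "scaf")))
  pos <- unlist(lapply(table(contigs), function(k) sort(sample(1e6, k))),
                use.names = FALSE)
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./.", ".", "1/."),
                      nSites * nSamples, replace = TRUE,
                      prob = c(0.4, 0.15, 0.15, 0.2, 0.05, 0.05)),
               nrow = nSites)
  dp <- matrix(as.character(sample(0:40, nSites * nSamples,
                                   replace = TRUE)), nrow = nSites)
  dp[sample(length(dp), ceiling(length(dp) / 20))] <- "."
  format <- sample(c("GT:DP", "GT:AD:DP"), 1)
  makeVcf(path, as.character(contigs), pos, gt, dp, format = format)
  list(path = path, map = testChromMap(), nSites = nSites,
       nSamples = nSamples)
}

# naive site-by-site recount, written against vcfR's parser; independent
# of the package's streaming accumulator
oracleStats <- function(path, map, depthField = "DP") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  cls <- contigClass(map, v@fix[, "CHROM"])
  gt <- vcfR::extract.gt(v, "GT", convertNA = FALSE, IDtoRowNames = FALSE)
  dpv <- vcfR::extract.gt(v, depthField, convertNA = FALSE,
                          IDtoRowNames = FALSE)
  samples <- colnames(gt)
  rows <- list()
  for (s in samples) {
    for (cc in c("AUTOSOME", "X_LIKE", "Y_LIKE")) {
      sel <- which(cls == cc)
      nMiss <- 0L; nNon <- 0L; dSum <- 0
      for (i in sel) {
        g <- gt[i, s]
        if (is.na(g) || grepl(".", g, fixed = TRUE)) {
          nMiss <- nMiss + 1L
        } else {
          nNon <- nNon + 1L
          d <- suppressWarnings(as.numeric(dpv[i, s]))
          dSum <- dSum + if (is.na(d)) 0 else d
        }
      }
      n <- length(sel)
      rows[[paste(s, cc)]] <- data.frame(
        individual = s, class = cc, n_sites = as.numeric(n),
        n_missing = as.numeric(nMiss), n_nonmissing = as.numeric(nNon),
        depth_sum = dSum,
        missingness = if (n > 0) nMiss / n else NA_real_,
        completeness = if (n > 0) 1 - nMiss / n else NA_real_,
        mean_depth = if (nNon > 0) dSum / nNon else NA_real_)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

orderStats <- function(df) {
  df <- df[order(df$individual, df$class), ]
  rownames(df) <- NULL
  df
}

# constructed per-class stats fixture from the analytic quantities
statsFixture <- function(individual = "i1", depthA = 20, depthX = 20,
                         depthY = 0, comX = 0.9, comY = 0,
                         nSites = 1000) {
  nmX <- round((1 - comX) * nSites)
  nmY <- round((1 - comY) * nSites)
  SexingStats(data.frame(
    individual = individual,
    class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = nSites,
    n_missing = c(0, nmX, nmY),
    depth_sum = c(depthA * nSites, depthX * (nSites - nmX),
                  depthY * (nSites - nmY))))
}

# a table of 10 single-site loci with presence counts 0..9 of 10 samples
presenceToy <- function(path) {
  gt <- t(vapply(0:9, function(k)
    c(rep("0/0", k), rep("./.", 10 - k)), character(10)))
  makeVcf(path, rep("chrA", 10), seq(1, by = 500, length.out = 10), gt,
          matrix(ifelse(gt == "0/0", 7L, 0L), 10, 10))
  groupLoci(path)
}

cliPath <- function() system.file("scripts", "sexrad", package = "sexRAD")

runCli <- function(...) {
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cliPath(), ...),
    stdout = TRUE, stderr = TRUE,
    env = c("R_TESTS=",
            sprintf("R_LIBS=%s",
                    paste(.libPaths(), collapse = .Platform$path.sep)))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
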