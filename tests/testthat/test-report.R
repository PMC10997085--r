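pipelineFixture <- function(dir, n = 20L, depth = 15, seed = 101L) {
  p <- simParams(nIndividuals = n, lociAutosome = 600L, lociX = 200L,
                 lociY = 25L, locusLength = 2L, meanDepth = depth,
                 seed = seed)
  simulateCohort(p, dir)
}

test_that("the pipeline writes the report triplet and matches truth", {
  d <- withr::local_tempdir()
  sim <- pipelineFixture(d)
  out <- file.path(d, "out")
  rep <- runSexingPipeline(sim$vcf, sim$chromMap, outDir = out,
                           verbose = FALSE)
  expect_true(file.exists(file.path(out, "final_sexing.csv")))
  expect_true(file.exists(file.path(out, "sexing_plots.pdf")))
  expect_true(file.exists(file.path(out, "class_stats.csv")))
  csv <- read.csv(file.path(out, "final_sexing.csv"))
  expect_identical(nrow(csv), 20L)
  expect_identical(csv$sex[match(sim$truthTable$individual,
                                 csv$individual)],
                   sim$truthTable$true_sex)
  expect_identical(rep@counts$unassigned, 0L)
  # report columns cover everything the indexes and plots need
  expect_true(all(c("individual", "depth_a", "depth_x", "depth_y",
                    "com_x", "com_y", "index_x", "index_y",
                    "overall_mean_depth", "sex") %in% names(csv)))
})

test_that("the report CSV round-trips to the configured precision", {
  d <- withr::local_tempdir()
  sim <- pipelineFixture(d, n = 6L)
  rep <- runSexingPipeline(sim$vcf, sim$chromMap,
                           outDir = file.path(d, "out"), plots = FALSE,
                           verbose = FALSE)
  csv <- read.csv(rep@files$csv)
  mem <- sexCalls(rep@calls)
  for (col in c("index_x", "index_y", "overall_mean_depth", "depth_a"))
    expect_equal(csv[[col]], round(mem[[col]], 4))
})

test_that("reruns on identical inputs are byte-identical", {
  d <- withr::local_tempdir()
  sim <- pipelineFixture(d, n = 8L)
  runSexingPipeline(sim$vcf, sim$chromMap, outDir = file.path(d, "a"),
                    plots = FALSE, verbose = FALSE)
  runSexingPipeline(sim$vcf, sim$chromMap, outDir = file.path(d, "b"),
                    plots = FALSE, verbose = FALSE)
  expect_identical(readLines(file.path(d, "a", "final_sexing.csv")),
                   readLines(file.path(d, "b", "final_sexing.csv")))
})

test_that("a VCF without Y sites forces Index Y to 1 with a warning", {
  d <- withr::local_tempdir()
  f <- file.path(d, "noY.vcf")
  set.seed(6)
  gt <- matrix(sample(c("0/0", "./."), 40 * 4, TRUE, prob = c(0.9, 0.1)),
               40, 4)
  makeVcf(f, rep(c("chrA", "chrX"), each = 20),
          rep(seq(1, by = 300, length.out = 20), 2), gt,
          matrix(12L, 40, 4))
  m <- file.path(d, "map.yaml")
  writeChromMap(testChromMap(), m)
  # warns once about the map's Y contig missing from the header and once
  # about the absence of Y data
  expect_warning(expect_warning(
    rep <- runSexingPipeline(f, m, outDir = file.path(d, "out"),
                             plots = FALSE, verbose = FALSE),
    "classified Y_LIKE"), "no Y_LIKE sites")
  calls <- sexCalls(rep@calls)
  expect_true(all(calls$index_y == 1))
  expect_true(all(calls$sex_by_y == "homogametic"))
})

test_that("a missing input fails with a nonzero-effect error and no outputs", {
  d <- withr::local_tempdir()
  m <- file.path(d, "map.yaml")
  writeChromMap(testChromMap(), m)
  out <- file.path(d, "out")
  expect_error(runSexingPipeline(file.path(d, "absent.vcf"), m,
                                 outDir = out, verbose = FALSE),
               "validate")
  expect_false(file.exists(file.path(out, "final_sexing.csv")))
})

test_that("plotting handles single rows and all-undefined indexes", {
  one <- classifyCohort(statsFixture("only", depthA = 20, depthX = 20,
                                     comX = 0.9, comY = 0), runConfig())
  f <- withr::local_tempfile(fileext = ".pdf")
  makeSexingPlots(one, f)
  expect_true(file.size(f) > 0)
  # all indexes undefined: placeholders plus warning
  und <- classifyCohort(SexingStats(data.frame(
    individual = "u", class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = 10, n_missing = c(10, 10, 10), depth_sum = 0)),
    runConfig())
  g <- withr::local_tempfile(fileext = ".pdf")
  expect_warning(makeSexingPlots(und, g), "placeholder")
  expect_true(file.size(g) > 0)
})

test_that("plot panels carry one point per individual with defined indexes", {
  d <- withr::local_tempdir()
  sim <- pipelineFixture(d, n = 10L)
  rep <- runSexingPipeline(sim$vcf, sim$chromMap,
                           outDir = file.path(d, "out"), verbose = FALSE)
  df <- sexCalls(rep@calls)
  expect_identical(sum(!is.na(df$index_x) & !is.na(df$index_y)), 10L)
  expect_true(file.size(rep@files$plots) > 0)
})

test_that("the command-line interface runs the pipeline and fails cleanly", {
  d <- withr::local_tempdir()
  sim <- pipelineFixture(d, n = 6L)
  out <- file.path(d, "cliout")
  res <- runCli("sex", "--vcf", sim$vcf, "--chrom-map", sim$chromMap,
                "--out-dir", out, "--no-plots")
  expect_identical(res$status, 0L)
  csv <- read.csv(file.path(out, "final_sexing.csv"))
  expect_identical(nrow(csv), 6L)

  bad <- runCli("sex", "--vcf", file.path(d, "absent.vcf"),
                "--chrom-map", sim$chromMap, "--out-dir", out)
  expect_gt(bad$status, 0L)
  usage <- runCli("frobnicate")
  expect_gt(usage$status, 0L)
})

test_that("the CLI simulate and stats subcommands produce their outputs", {
  d <- withr::local_tempdir()
  res <- runCli("simulate", "--out-dir", d, "--n", "4",
                "--loci-autosome", "200", "--loci-x", "60", "--loci-y",
                "10", "--locus-length", "2", "--depth", "15", "--seed", "5")
  expect_identical(res$status, 0L)
  expect_true(file.exists(file.path(d, "sim.all.vcf")))
  res2 <- runCli("stats", "--vcf", file.path(d, "sim.all.vcf"),
                 "--chrom-map", file.path(d, "sim_chrom_map.yaml"),
                 "--out-dir", d)
  expect_identical(res2$status, 0L)
  st <- read.csv(file.path(d, "class_stats.csv"))
  expect_identical(sort(unique(st$class)),
                   c("AUTOSOME", "X_LIKE", "Y_LIKE"))
})
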