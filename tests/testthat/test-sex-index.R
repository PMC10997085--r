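test_that("index values match the expected homogametic/heterogametic patterns exactly", {
  # homogametic: X depth equals autosomal depth, Y completeness zero
  f <- statsFixture(depthA = 20, depthX = 20, comX = 0.9, comY = 0)
  expect_identical(unname(indexX(f)), 1)
  expect_identical(unname(indexY(f)), 1)
  # heterogametic: X depth half the autosomal, X and Y completeness equal
  m <- statsFixture(depthA = 20, depthX = 10, depthY = 10,
                    comX = 0.8, comY = 0.8)
  expect_identical(unname(indexX(m)), 0.5)
  expect_identical(unname(indexY(m)), 0)
  # plain ratios
  expect_identical(unname(indexX(statsFixture(depthA = 20, depthX = 14))),
                   0.7)
  expect_identical(
    unname(indexX(statsFixture(depthA = 17.3, depthX = 17.3))), 1)
  # ComX = 0.5, ComY = 0.8 -> negative Index Y
  expect_equal(unname(indexY(statsFixture(comX = 0.5, comY = 0.8))), -0.6)
})

test_that("undefined indexes are NA with the documented triggers", {
  # ComX = 0 -> Index Y undefined
  expect_true(is.na(indexY(statsFixture(comX = 0, comY = 0))))
  # autosomal mean depth zero -> Index X undefined
  z <- SexingStats(data.frame(
    individual = "i", class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = 10, n_missing = c(0, 0, 10), depth_sum = c(0, 50, 0)))
  expect_true(is.na(indexX(z)))
  # no non-missing X site -> X mean depth undefined -> Index X undefined
  z2 <- SexingStats(data.frame(
    individual = "i", class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = 10, n_missing = c(0, 10, 10), depth_sum = c(100, 0, 0)))
  expect_true(is.na(indexX(z2)))
  # index_y <= 1 whenever defined; index_x >= 0 whenever defined
  set.seed(3)
  for (i in 1:25) {
    st <- statsFixture(depthA = runif(1, 0.5, 30), depthX = runif(1, 0, 30),
                       comX = runif(1), comY = runif(1))
    iy <- unname(indexY(st)); ix <- unname(indexX(st))
    if (!is.na(iy)) expect_lte(iy, 1)
    if (!is.na(ix)) expect_gte(ix, 0)
  }
})

test_that("only Index Y assigns sex, inclusively at the threshold", {
  cfg <- runConfig()
  a <- assignSex(indexX = 1, indexY = 0.97, overallDepth = 20, cfg)
  expect_identical(a$sex_by_y, "homogametic")
  # exactly at the threshold is homogametic
  b <- assignSex(indexX = 0.5, indexY = 0.5, overallDepth = 20, cfg)
  expect_identical(b$sex_by_y, "homogametic")
  c1 <- assignSex(indexX = 0.5, indexY = 0.4999, overallDepth = 20, cfg)
  expect_identical(c1$sex_by_y, "heterogametic")
  # strongly negative Index Y at 1.4X: heterogametic with low-depth flag
  d <- assignSex(indexX = 1, indexY = -1.6, overallDepth = 1.4, cfg)
  expect_identical(d$sex_by_y, "heterogametic")
  expect_true(d$low_depth_flag)
  # ... and the contradictory Index X advisory is suppressed at low depth
  expect_identical(d$sex_by_x, "unassigned")
  # both undefined -> unassigned with a reason
  e <- assignSex(NA_real_, NA_real_, 20, cfg)
  expect_identical(e$sex_by_y, "unassigned")
  expect_match(e$reason, "undefined")
})

test_that("the advisory Index X call picks the nearest expected value", {
  cfg <- runConfig()
  x <- assignSex(indexX = c(0.95, 0.6, 0.76, 0.74), indexY = 0,
                 overallDepth = 20, cfg)
  expect_identical(x$sex_by_x, c("homogametic", "heterogametic",
                                 "homogametic", "heterogametic"))
  agree <- assignSex(indexX = 1, indexY = 0.9, overallDepth = 20, cfg)
  expect_true(agree$agreement_flag)
  disagree <- assignSex(indexX = 0.5, indexY = 0.9, overallDepth = 20, cfg)
  expect_false(disagree$agreement_flag)
})

test_that("raising Index Y never flips a homogametic call to heterogametic", {
  cfg <- runConfig()
  iy <- sort(runif(50, -2, 1.2))
  calls <- assignSex(indexX = NA_real_, indexY = iy, overallDepth = 20,
                     cfg)$sex_by_y
  homo <- calls == "homogametic"
  expect_true(all(diff(homo) >= 0))  # once homogametic, stays homogametic
})

test_that("Index Y is invariant to uniform depth rescaling", {
  base <- statsFixture(depthA = 20, depthX = 11, depthY = 5,
                       comX = 0.8, comY = 0.5)
  for (k in c(0.1, 2, 17)) {
    scaled <- statsFixture(depthA = 20 * k, depthX = 11 * k,
                           depthY = 5 * k, comX = 0.8, comY = 0.5)
    expect_identical(indexY(scaled), indexY(base))
  }
})

test_that("Index X depends only on mean depths, not on which sites are missing", {
  a <- SexingStats(data.frame(
    individual = "i", class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = 100, n_missing = c(0, 0, 100),
    depth_sum = c(2000, 1200, 0)))
  b <- SexingStats(data.frame(
    individual = "i", class = c("AUTOSOME", "X_LIKE", "Y_LIKE"),
    n_sites = 100, n_missing = c(60, 75, 100),
    depth_sum = c(40 * 20, 25 * 12, 0)))
  expect_identical(indexX(a), indexX(b))
})

test_that("cohort classification composes per-individual calls and tallies them", {
  pc <- rbind(
    classStats(statsFixture("f1", depthA = 20, depthX = 20, comX = 0.9,
                            comY = 0)),
    classStats(statsFixture("f2", depthA = 15, depthX = 14.5, comX = 0.85,
                            comY = 0.02)),
    classStats(statsFixture("m1", depthA = 20, depthX = 10, depthY = 10,
                            comX = 0.8, comY = 0.8)))
  st <- SexingStats(pc[, c("individual", "class", "n_sites", "n_missing",
                           "depth_sum")])
  calls <- classifyCohort(st, runConfig())
  s <- cohortSummary(calls)
  expect_identical(s$n, 3L)
  expect_identical(s$female, 2L)
  expect_identical(s$male, 1L)
  expect_identical(s$unassigned, 0L)
  expect_identical(nrow(sexCalls(calls)), 3L)
  expect_error(classifyCohort(SexingStats(
    data.frame(individual = character(), class = character(),
               n_sites = numeric(), n_missing = numeric(),
               depth_sum = numeric()))), "empty")
})

test_that("simulated cohorts at moderate depth are classified to truth", {
  p <- simParams(nIndividuals = 10, lociAutosome = 1000, lociX = 300,
                 lociY = 40, locusLength = 2, meanDepth = 15, seed = 88)
  sim <- simulateCohort(p, withr::local_tempdir())
  st <- accumulateStats(sim$vcf, sim$map)
  calls <- sexCalls(classifyCohort(st, runConfig(), sim$map))
  expect_identical(calls$sex[match(sim$truthTable$individual,
                                   calls$individual)],
                   sim$truthTable$true_sex)
})
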