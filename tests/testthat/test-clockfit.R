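test_that("donor folds form a seeded, near-balanced partition", {
  donors <- paste0("D", 1:10)
  f <- assignDonorFolds(donors, 5, seed = 3)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_setequal(names(f), donors)
  expect_identical(f, assignDonorFolds(donors, 5, seed = 3))
  expect_false(identical(f, assignDonorFolds(donors, 5, seed = 4)))
  expect_error(assignDonorFolds(paste0("D", 1:4), 5), "at least 5")
  # uneven donor counts differ by at most one
  f2 <- assignDonorFolds(paste0("D", 1:13), 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
})

test_that("fitElasticNet handles degenerate responses and full shrinkage", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  cst <- fitElasticNet(X, rep(5, 10))
  expect_equal(unname(cst$coefficients), c(0, 0, 0))
  expect_equal(cst$intercept, 5)
  y <- rnorm(10, 60, 15)
  big <- fitElasticNet(X, y, alpha = 0.5, lambda = 1e9)
  expect_equal(unname(big$coefficients), c(0, 0, 0))
  expect_equal(big$intercept, mean(y), tolerance = 1e-10)
  expect_error(fitElasticNet(X, c(y[-1], NA)), "non-finite")
})

test_that("ridge at fixed penalty matches the closed-form solution", {
  set.seed(42)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rnorm(10, 50, 10)
  lam <- 0.7
  fit <- fitElasticNet(X, y, alpha = 0, lambda = lam, standardize = FALSE)
  oracle <- ridgeOracle(X, y, lam)
  expect_lt(max(abs(fit$coefficients - oracle$coefficients) /
                pmax(abs(oracle$coefficients), 1e-8)), 1e-4)
  expect_lt(abs(fit$intercept - oracle$intercept) /
              abs(oracle$intercept), 1e-4)
})

test_that("trainClock keeps CV bookkeeping honest and deterministic", {
  co <- signalCohort(nDonors = 10, nGenes = 120, seed = 6)
  pb <- bootstrapPseudobulk(co, "astrocyte", k = 20, nReplicates = 10,
                            seed = 2)
  m1 <- trainClock(pb, seed = 9)
  m2 <- trainClock(pb, seed = 9)
  expect_identical(lapply(foldModels(m1), `[[`, "coefficients"),
                   lapply(foldModels(m2), `[[`, "coefficients"))
  cvp <- cvPredictions(m1)
  # every sample appears exactly once among cv_test predictions
  expect_setequal(cvp$sample_id, colnames(pb))
  expect_equal(anyDuplicated(cvp$sample_id), 0L)
  # no donor leakage: a donor's test fold never trained on it
  for (f in 1:5) {
    testDonors <- unique(cvp$donor_id[cvp$fold == f])
    expect_length(intersect(testDonors,
                            foldModels(m1)[[f]]$trainDonors), 0)
  }
  # fold models trained on the 80% donor complement
  expect_setequal(unlist(lapply(foldModels(m1), `[[`, "trainDonors")) |>
                    unique(), names(donorFolds(m1)))
})

test_that("a clock with age signal beats the naive baseline in CV", {
  co <- signalCohort(nDonors = 12, nGenes = 200, seed = 31)
  pb <- bootstrapPseudobulk(co, "astrocyte", k = 25, nReplicates = 15,
                            seed = 4)
  m <- trainClock(pb, seed = 10)
  clockEval <- evaluateClock(aggregateByDonor(cvPredictions(m)))
  bl <- naiveMeanBaseline(pb, donorFolds(m))
  blEval <- evaluateClock(aggregateByDonor(bl))
  expect_gt(clockEval$pearson_r, 0)
  expect_lt(clockEval$mae, blEval$mae)
})

test_that("huge fixed penalty gives intercept-only folds at the train mean", {
  co <- signalCohort(nDonors = 8, nGenes = 60, seed = 12)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, lambda = 1e9, seed = 2)
  ages <- setNames(colData(pb)$age, colData(pb)$donor_id)
  for (f in 1:5) {
    fm <- foldModels(m)[[f]]
    expect_true(all(fm$coefficients == 0))
    trainAges <- colData(pb)$age[colData(pb)$donor_id %in% fm$trainDonors]
    expect_equal(fm$intercept, mean(trainAges), tolerance = 1e-8)
  }
})

test_that("predictDonorAge averages replicates and checks the universe", {
  uni <- c("g1", "g2")
  m <- toyModel(uni, rep(list(c(g1 = 1)), 5), intercepts = rep(0, 5))
  pbOne <- toyPseudobulk(rbind(g1 = c(50, 60), g2 = c(1, 1)),
                         donor = "DX", ages = 70,
                         replicate = 1:2, mode = "bootstrap")
  agg <- predictDonorAge(m, pbOne, aggregate = TRUE)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$predicted_age, 55)
  per <- predictDonorAge(m, pbOne, aggregate = FALSE)
  expect_equal(per$predicted_age, c(50, 60))
  single <- toyPseudobulk(rbind(g1 = 42, g2 = 0), donor = "DX", ages = 70)
  expect_equal(predictDonorAge(m, single)$predicted_age, 42)
  bad <- toyPseudobulk(rbind(g1 = 1, g9 = 2), donor = "DX", ages = 70)
  expect_error(predictDonorAge(m, bad), "alignGenes")
})

test_that("evaluateClock matches direct formulas and flags degeneracy", {
  p <- data.frame(chronological_age = c(20, 50, 80),
                  predicted_age = c(20, 50, 80))
  e <- evaluateClock(p)
  expect_equal(e$pearson_r, 1)
  expect_equal(e$mae, 0)
  p$predicted_age <- p$chronological_age + 5
  e2 <- evaluateClock(p)
  expect_equal(e2$pearson_r, 1)
  expect_equal(e2$mae, 5)
  toy <- data.frame(chronological_age = c(20, 50, 80),
                    predicted_age = c(30, 45, 90))
  e3 <- evaluateClock(toy)
  x <- toy$chronological_age; y <- toy$predicted_age
  rBF <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(e3$pearson_r, rBF)
  expect_equal(e3$mae, mean(abs(y - x)))
  flat <- data.frame(chronological_age = c(20, 50, 80),
                     predicted_age = c(55, 55, 55))
  expect_true(is.na(evaluateClock(flat)$pearson_r))
  expect_error(evaluateClock(p[1:2, ]), "3 points")
})

test_that("the naive baseline predicts each fold's training mean age", {
  exprs <- matrix(rnorm(10 * 10), 10, 10)
  pb <- toyPseudobulk(exprs, donor = rep(paste0("D", 1:5), each = 2),
                      ages = c(20, 40, 60, 30, 70))
  folds <- setNames(1:5, paste0("D", 1:5))
  bl <- naiveMeanBaseline(pb, folds)
  ages <- c(20, 40, 60, 30, 70)
  for (f in 1:5)
    expect_equal(unique(bl$predicted_age[bl$fold == f]), mean(ages[-f]))
  # within one fold the baseline prediction is constant -> r undefined
  expect_true(is.na(evaluateClock(
    rbind(bl[bl$fold == 1, ], bl[bl$fold == 1, ], bl[bl$fold == 1, ])
  )$pearson_r))
  # degenerate cohort: everyone the same age -> baseline MAE 0
  pbSame <- toyPseudobulk(exprs, donor = rep(paste0("D", 1:5), each = 2),
                          ages = rep(50, 5))
  expect_equal(evaluateClock(naiveMeanBaseline(pbSame, folds))$mae, 0)
})

test_that("feature genes are the all-fold non-zero set with mean and sign", {
  uni <- c("g1", "g2", "g3")
  coefs <- list(c(g1 = 0.1, g2 = -1), c(g1 = 0.2, g2 = -2),
                c(g1 = 0.3, g2 = -1), c(g1 = 0.2), c(g1 = 0.2, g2 = -3))
  m <- toyModel(uni, coefs, intercepts = rep(0, 5))
  fg <- extractFeatureGenes(m)
  expect_identical(fg$gene, "g1")  # g2 non-zero in only 4/5 folds
  expect_equal(fg$average_coefficient, 0.2)
  expect_equal(fg$sign, 1L)
  mZero <- toyModel(uni, rep(list(numeric(0)), 5), intercepts = rep(0, 5))
  expect_equal(nrow(extractFeatureGenes(mZero)), 0)
})

test_that("featureOverlap counts unique, shared and universal genes", {
  uni <- c("g1", "g2", "g3", "g4")
  mk <- function(...) toyModel(uni, rep(list(c(...)), 5),
                               intercepts = rep(0, 5))
  a <- mk(g1 = 1, g2 = 1)
  b <- mk(g3 = 1, g4 = -1)
  ov <- featureOverlap(list(a = a, b = b))
  expect_equal(ov$nUnique, 4)
  expect_equal(ov$nShared, 0)
  expect_length(ov$commonToAll, 0)
  ov2 <- featureOverlap(list(a, a))
  expect_equal(ov2$nShared, 2)
  expect_setequal(ov2$commonToAll, c("g1", "g2"))
  c3 <- mk(g1 = 1, g3 = 1)
  ov3 <- featureOverlap(list(a = a, b = mk(g1 = 1, g4 = 1), c = c3))
  expect_identical(ov3$commonToAll, "g1")
})

test_that("clock models round-trip through JSON", {
  co <- signalCohort(nDonors = 8, nGenes = 50, seed = 15)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  writeClockModel(m, path)
  back <- readClockModel(path)
  expect_identical(geneUniverse(back), geneUniverse(m))
  expect_equal(trainingGeneMeans(back), trainingGeneMeans(m))
  expect_equal(donorFolds(back), donorFolds(m))
  for (f in 1:5)
    expect_equal(foldModels(back)[[f]]$coefficients,
                 foldModels(m)[[f]]$coefficients)
  p1 <- predictDonorAge(m, pb)
  p2 <- predictDonorAge(back, pb)
  expect_equal(p2$predicted_age, p1$predicted_age)
})
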