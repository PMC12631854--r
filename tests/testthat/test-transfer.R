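test_that("alignGenes imputes missing genes with training means", {
  uni <- c("g1", "g2", "g3")
  m <- toyModel(uni, rep(list(c(g1 = 1, g3 = 2)), 5),
                intercepts = rep(0, 5),
                trainingMeans = c(g1 = 0.1, g2 = 0.7, g3 = 0.4))
  ext <- toyPseudobulk(rbind(g3 = c(1, 2), g1 = c(3, 4), gX = c(9, 9)),
                       donor = c("A", "B"), ages = c(40, 60))
  al <- alignGenes(m, ext)
  expect_identical(rownames(al$samples), uni)
  expect_equal(al$report$n_genes_matched, 2)
  expect_equal(al$report$n_genes_imputed, 1)
  expect_identical(al$report$imputed_genes, "g2")
  expect_equal(al$report$n_extra_dropped, 1)
  # the missing gene's row is constant at its training mean
  expect_equal(unname(assay(al$samples, "exprs")["g2", ]), c(0.7, 0.7))
  # matched genes are passed through, reordered
  expect_equal(unname(assay(al$samples, "exprs")["g3", ]), c(1, 2))
})

test_that("alignment with no missing genes is an identity reordering", {
  uni <- c("g1", "g2")
  m <- toyModel(uni, rep(list(c(g1 = 1)), 5), intercepts = rep(0, 5))
  ext <- toyPseudobulk(rbind(g2 = c(5, 6), g1 = c(1, 2)),
                       donor = c("A", "B"), ages = c(40, 60))
  al <- alignGenes(m, ext)
  expect_equal(assay(al$samples, "exprs"),
               as.matrix(assay(ext, "exprs"))[uni, ])
})

test_that("predictions are invariant to mean-replacement vs imputation", {
  co <- signalCohort(nDonors = 8, nGenes = 60, seed = 19)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, seed = 3)
  drop <- rownames(pb)[c(4, 10, 25)]
  # route 1: delete the genes and let alignGenes impute them
  al1 <- alignGenes(m, pb[setdiff(rownames(pb), drop), ])
  p1 <- applyClockExternal(m, al1$samples)
  # route 2: replace those genes' values by the training means directly
  E <- as.matrix(assay(pb, "exprs"))
  E[drop, ] <- trainingGeneMeans(m)[drop]
  al2 <- alignGenes(m, toyPseudobulk(E, donor = colData(pb)$donor_id,
                                     ages = donorData(co)$age))
  p2 <- applyClockExternal(m, al2$samples)
  expect_equal(p1$predicted_age, p2$predicted_age, tolerance = 1e-12)
})

test_that("alignment and prediction ignore external gene ordering", {
  co <- signalCohort(nDonors = 8, nGenes = 40, seed = 23)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, seed = 3)
  shuf <- pb[sample(nrow(pb)), ]
  p1 <- applyClockExternal(m, alignGenes(m, pb)$samples)
  p2 <- applyClockExternal(m, alignGenes(m, shuf)$samples)
  expect_equal(p2$predicted_age, p1$predicted_age)
})

test_that("the ensemble prediction is the mean of the five fold models", {
  uni <- c("g1", "g2")
  m <- toyModel(uni, rep(list(numeric(0)), 5),
                intercepts = c(60, 62, 64, 66, 68))
  ext <- toyPseudobulk(rbind(g1 = 1, g2 = 1), donor = "A", ages = 50)
  p <- applyClockExternal(m, alignGenes(m, ext)$samples)
  expect_equal(p$predicted_age, 64)
  expect_equal(dim(attr(p, "perFold")), c(1, 5))
  # five identical fold models reduce to any single model
  m2 <- toyModel(uni, rep(list(c(g1 = 2)), 5), intercepts = rep(10, 5))
  p2 <- applyClockExternal(m2, alignGenes(m2, ext)$samples)
  expect_equal(p2$predicted_age, 10 + 2 * 1)
})

test_that("imputing every gene yields one constant prediction for all", {
  co <- signalCohort(nDonors = 8, nGenes = 40, seed = 27)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, seed = 3)
  alien <- toyPseudobulk(rbind(zz1 = c(1, 5), zz2 = c(2, 6)),
                         donor = c("A", "B"), ages = c(30, 70))
  expect_warning(al <- alignGenes(m, alien), "missing")
  p <- applyClockExternal(m, al$samples)
  expect_equal(p$predicted_age[1], p$predicted_age[2])
})

test_that("feature-gene expression fraction counts detected features", {
  co <- signalCohort(nDonors = 8, nGenes = 60, seed = 29)
  pb <- simplePseudobulk(co, "astrocyte")
  m <- trainClock(pb, seed = 3)
  fg <- extractFeatureGenes(m)$gene
  expect_gt(length(fg), 1)
  expect_equal(featureGeneExpressionFraction(m, co), 1.0)
  expect_equal(featureGeneExpressionFraction(m, co[setdiff(rownames(co),
                                                           fg), ]), 0.0)
  half <- fg[seq_len(floor(length(fg) / 2))]
  expect_equal(
    featureGeneExpressionFraction(m, co[setdiff(rownames(co), half), ]),
    1 - length(half) / length(fg))
})

test_that("trend concordance matches brute-force Spearman and BH", {
  ages <- c(21, 34, 45, 58, 66, 79, 85, 92)
  n <- length(ages)
  set.seed(9)
  E <- rbind(mono = ages + 0,                      # strictly increasing
             flat = rep(2, n),                     # constant
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  co <- toyCohort(pmax(round(exp(E)), 0), donor = paste0("D", 1:n),
                  ages = ages)
  rownames(co) <- rownames(E)
  M <- Matrix::Matrix(E, sparse = TRUE,
                      dimnames = list(rownames(E), colnames(co)))
  assay(co, "logcounts") <- as(M, "CsparseMatrix")
  m <- toyModel(rownames(E),
                rep(list(c(mono = 0.5, flat = 0.2, noise1 = -0.1,
                           noise2 = 0.3, noise3 = -0.2)), 5),
                intercepts = rep(0, 5))
  cc <- featureGeneTrendConcordance(m, co)
  tab <- cc$table[match(rownames(E), cc$table$gene), ]
  # rho agrees with the brute-force rank formula for every testable gene
  for (g in c("mono", "noise1", "noise2", "noise3"))
    expect_equal(tab$rho[tab$gene == g],
                 bfSpearman(E[g, ], ages), tolerance = 1e-12)
  # BH adjustment agrees with the brute-force step-up rule
  ok <- !is.na(tab$p)
  expect_equal(tab$p_adj[ok], bfBH(tab$p[ok]), tolerance = 1e-12)
  # a strictly age-monotone, positive-coefficient gene is concordant
  expect_equal(tab$rho[tab$gene == "mono"], 1)
  expect_true(tab$concordant[tab$gene == "mono"])
  # a constant gene has undefined correlation and is non-concordant
  expect_true(is.na(tab$rho[tab$gene == "flat"]))
  expect_false(tab$concordant[tab$gene == "flat"])
})

test_that("BH step-up matches p.adjust on random p-vectors", {
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bfBH(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("six-donor Spearman toy matches element-wise rank enumeration", {
  ages <- c(25, 37, 49, 61, 73, 88)
  x <- c(0.3, 0.1, 0.5, 0.4, 0.9, 0.8)
  # ranks by direct counting, no rank() shortcut
  bfRank <- function(v) vapply(v, function(a) sum(v <= a), numeric(1))
  d <- bfRank(x) - bfRank(ages)
  rhoBF <- 1 - 6 * sum(d^2) / (6 * (6^2 - 1))
  expect_equal(cor(x, ages, method = "spearman"), rhoBF,
               tolerance = 1e-12)
  expect_equal(bfSpearman(x, ages), rhoBF, tolerance = 1e-12)
})
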