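test_that("a flat z^2 profile gives zero heritability and unit intercept", {
  m <- 2000
  ld <- simulateLdScores(m, list(name = "gamma", mean = 20, shape = 3), seed = 2)
  tab <- SumStats("flat", data.frame(
    rsid = ld$SNP, a1 = "A", a2 = "G",
    z = rep(c(-1, 1), m / 2), n = 50000, p = 2 * pnorm(-1)))
  est <- estimateH2(tab, ld, m, n_blocks = 50)
  expect_equal(est$h2, 0, tolerance = 1e-10)
  expect_equal(est$intercept, 1, tolerance = 1e-10)
})

test_that("self-covariance equals the heritability estimate exactly", {
  cfg <- uniConfig(seed = 31)
  sim <- simulateSumstats(cfg)
  a <- sim$sumstats[[1]]
  h2 <- estimateH2(a, sim$ldscores, sim$m, n_blocks = 50)
  cv <- estimateGencov(a, a, sim$ldscores, sim$m, n_blocks = 50)
  expect_identical(cv$cov, h2$h2)
  expect_identical(cv$se, h2$se)
})

test_that("estimateH2 recovers a generating heritability of 0.25", {
  cfg <- uniConfig(h2 = 0.25, n = 80000, m = 20000, seed = 7)
  sim <- simulateSumstats(cfg)
  est <- estimateH2(sim$sumstats[[1]], sim$ldscores, sim$m, n_blocks = 200)
  expect_lt(abs(est$h2 - 0.25), 2 * est$se)
  expect_gt(est$z, 10)
})

test_that("jackknife SE tracks the empirical SD over 50 replicates", {
  ests <- ses <- numeric(50)
  for (r in 1:50) {
    cfg <- uniConfig(h2 = 0.25, n = 30000, m = 6000, seed = 1000 + r)
    sim <- simulateSumstats(cfg)
    e <- estimateH2(sim$sumstats[[1]], sim$ldscores, sim$m, n_blocks = 50)
    ests[r] <- e$h2; ses[r] <- e$se
  }
  ratio <- median(ses) / sd(ests)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("independent traits give a covariance near 0; overlap is absorbed by the intercept", {
  sg <- diag(c(0.3, 0.3, 0.2))
  dimnames(sg) <- list(c("y", "x1", "x2"), c("y", "x1", "x2"))
  cfg <- triConfig(sg, m = 20000, seed = 17)
  sim <- simulateSumstats(cfg)
  cv <- estimateGencov(sim$sumstats[[1]], sim$sumstats[[2]], sim$ldscores,
                       sim$m, n_blocks = 100)
  expect_lt(abs(cv$cov), 2 * cv$se)

  # same trait pair, full sample overlap, rho_g = 0.7
  sg2 <- matrix(c(0.3, 0.7 * 0.3, 0.7 * 0.3, 0.3), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  cfg2 <- list(m_snps = 40000,
               traits = data.frame(label = c("a", "b"), n = 20000,
                                   reverse_coded = FALSE),
               loadings = t(chol(sg2)), factor_h2 = c(1, 1),
               specific_h2 = c(a = 0, b = 0),
               overlap = matrix(1, 2, 2),
               overlap_rp = matrix(c(1, 0.4, 0.4, 1), 2, 2),
               ldscore_law = list(name = "gamma", mean = 30, shape = 3),
               seed = 23)
  sim2 <- simulateSumstats(cfg2)
  cv2 <- estimateGencov(sim2$sumstats[[1]], sim2$sumstats[[2]], sim2$ldscores,
                        sim2$m, n_blocks = 100)
  expect_lt(abs(cv2$cov - 0.7 * 0.3), 2 * cv2$se)
  expect_gt(cv2$intercept, 2 * cv2$intercept_se)   # overlap shows up here
})

test_that("doubling the overlap intercept leaves the recovered covariance stable", {
  mk <- function(rp) {
    sg <- matrix(c(0.3, 0.15, 0.15, 0.3), 2, 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    list(m_snps = 20000,
         traits = data.frame(label = c("a", "b"), n = 60000,
                             reverse_coded = FALSE),
         loadings = t(chol(sg)), factor_h2 = c(1, 1),
         specific_h2 = c(a = 0, b = 0),
         overlap = matrix(1, 2, 2),
         overlap_rp = matrix(c(1, rp, rp, 1), 2, 2),
         ldscore_law = list(name = "gamma", mean = 30, shape = 3),
         seed = 29)
  }
  s1 <- simulateSumstats(mk(0.2)); s2 <- simulateSumstats(mk(0.4))
  c1 <- estimateGencov(s1$sumstats[[1]], s1$sumstats[[2]], s1$ldscores, s1$m, 100)
  c2 <- estimateGencov(s2$sumstats[[1]], s2$sumstats[[2]], s2$ldscores, s2$m, 100)
  expect_lt(abs(c1$cov - 0.15), 2 * c1$se)
  expect_lt(abs(c2$cov - 0.15), 2 * c2$se)
  expect_gt(c2$intercept, c1$intercept)
})

test_that("too few SNPs for the block count is an input error", {
  cfg <- uniConfig(m = 60, seed = 2)
  sim <- simulateSumstats(cfg)
  expect_error(estimateH2(sim$sumstats[[1]], sim$ldscores, sim$m, n_blocks = 50),
               class = "fg_input_error")
})

test_that("the joint stack matches the pairwise estimators and is calibrated", {
  ns <- nullStack()
  st <- ns$stack
  # diag(V) equals the squared SEs from the pairwise calls
  h11 <- estimateH2(ns$sim$sumstats[[1]], ns$sim$ldscores, ns$sim$m, 200)
  expect_equal(unname(gcov(st)[1, 1]), h11$h2, tolerance = 1e-10)
  expect_equal(unname(sqrt(diag(sampCov(st))[1])), h11$se, tolerance = 1e-10)
  # recovery is calibrated: most elements within 2 SEs, all within 4
  dev <- (factorGWAS:::vech(gcov(st)) - factorGWAS:::vech(ns$sim$sigma_g)) /
    sqrt(diag(sampCov(st)))
  expect_gt(mean(abs(dev) <= 2), 0.85)
  expect_lt(max(abs(dev)), 4)
})

test_that("duplicating a trait duplicates its row/column of S", {
  cfg <- uniConfig(h2 = 0.3, n = 40000, m = 6000, seed = 51)
  sim <- simulateSumstats(cfg)
  a <- sim$sumstats[[1]]
  b <- SumStats("t2", ssData(a))
  panel <- mergeCohorts(list(a, b))
  st <- buildCovarianceStack(panel, sim$ldscores, sim$m, n_blocks = 50)
  S <- gcov(st)
  expect_equal(S[1, 1], S[1, 2], tolerance = 1e-10)
  expect_equal(S[1, 1], S[2, 2], tolerance = 1e-10)
})

test_that("V from 100 and 200 blocks agree within a factor of 2 on the SE scale", {
  ns <- nullStack()
  st200 <- ns$stack
  st100 <- buildCovarianceStack(ns$panel, ns$sim$ldscores, ns$sim$m,
                                n_blocks = 100)
  r <- sqrt(diag(sampCov(st100))) / sqrt(diag(sampCov(st200)))
  expect_true(all(r > 0.5 & r < 2))
})

test_that("negating one trait's Z negates its row/column of S, |r_g| unchanged", {
  ns <- nullStack()
  panel <- ns$panel
  flipped <- panel
  flipped@Z[, 2] <- -flipped@Z[, 2]
  st1 <- buildCovarianceStack(panel, ns$sim$ldscores, ns$sim$m, 100)
  st2 <- buildCovarianceStack(flipped, ns$sim$ldscores, ns$sim$m, 100)
  S1 <- gcov(st1); S2 <- gcov(st2)
  expect_equal(S2[2, -2], -S1[2, -2], tolerance = 1e-10)
  expect_equal(S2[-2, -2], S1[-2, -2], tolerance = 1e-10)
  expect_equal(abs(cov2cor(S2)), abs(cov2cor(S1)), tolerance = 1e-10)
})

test_that("standardize reproduces the printed correlation from printed inputs", {
  labs <- c("UKB_Trails", "UKB_Pairs")
  S <- matrix(c(0.1141, 0.1471, 0.1471, 0.3765), 2, 2,
              dimnames = list(labs, labs))
  V <- diag(c(1e-4, 1e-4, 1e-4))
  st <- factorGWAS:::CovarianceStack(labs, S, V)
  sr <- standardizeStack(st)
  expect_equal(round(gcov(sr)[1, 2], 3), 0.710)  # 0.7097 to 3 d.p.
  expect_equal(gcov(sr)[1, 2], 0.1471 / sqrt(0.1141 * 0.3765), tolerance = 1e-12)
  expect_equal(unname(diag(gcov(sr))), c(1, 1))
  # idempotence
  sr2 <- standardizeStack(sr)
  expect_equal(gcov(sr2), gcov(sr), tolerance = 1e-12)
  expect_equal(sampCov(sr2), sampCov(sr), tolerance = 1e-12)
  # non-positive diagonal is a numerical error naming the trait
  S2 <- S; S2[1, 1] <- -0.01
  st2 <- factorGWAS:::CovarianceStack(labs, S2, V)
  expect_error(standardizeStack(st2), "UKB_Trails",
               class = "fg_numeric_error")
})

test_that("screenIndicators applies the heritability and collinearity rules", {
  # trait with h2 z below 1.96 excluded
  labs <- c("a", "b", "c")
  S <- diag(c(0.05, 0.3, 0.3)); S[2, 3] <- S[3, 2] <- 0.05
  dimnames(S) <- list(labs, labs)
  V <- diag(c(0.2, 0.03, 0.03, 0.03, 0.03, 0.03)^2)
  st <- factorGWAS:::CovarianceStack(labs, S, V)
  sc <- screenIndicators(st, h2_z_threshold = 1.96)
  expect_setequal(sc$retained, c("b", "c"))
  expect_match(sc$report$reason[1], "non-significant")

  # published matrix at r = 0.90 flags NIH G6 (two collinear partners)
  fx <- refGeneticCorrelations()
  full <- fixtureCovarianceStack(fx, traits = fx$tokens)
  sc2 <- screenIndicators(full, h2_z_threshold = 0, collinearity_r = 0.90)
  expect_false("NIH_G6" %in% sc2$retained)
  expect_match(sc2$report$reason[sc2$report$label == "NIH_G6"], "multicollinear")
  # all-significant low-correlation panel is fully retained
  sc3 <- screenIndicators(st, h2_z_threshold = 0.1)
  expect_setequal(sc3$retained, labs)
})

test_that("genetic multiple regression solves the normal equations with delta-method SEs", {
  labs <- c("y", "x1", "x2")
  S <- matrix(c(1, .5, .3, .5, 1, 0, .3, 0, 1), 3, 3,
              dimnames = list(labs, labs))
  st <- factorGWAS:::CovarianceStack(labs, S, diag(rep(1e-4, 6)))
  fit <- geneticMultipleRegression(st, "y", c("x1", "x2"))
  # predictors uncorrelated -> partials equal the marginal covariances
  expect_equal(fit$beta, c(0.5, 0.3), tolerance = 1e-10)
  # outcome as its own predictor -> coefficient 1, others 0
  fit2 <- geneticMultipleRegression(st, "y", c("y", "x1"))
  expect_equal(fit2$beta, c(1, 0), tolerance = 1e-10)
  # singular predictor set -> model error
  S2 <- S; S2[3, ] <- S2[2, ]; S2[, 3] <- S2[, 2]; S2[3, 3] <- 1
  st2 <- factorGWAS:::CovarianceStack(labs, S2, diag(rep(1e-4, 6)))
  expect_error(geneticMultipleRegression(st2, "y", c("x1", "x2")),
               class = "fg_model_error")
})

test_that("genetic multiple regression recovers generating partial coefficients", {
  beta <- c(0.4, -0.2)
  Spp <- matrix(c(0.3, 0.09, 0.09, 0.3), 2, 2)
  spo <- drop(Spp %*% beta)
  syy <- 0.3
  sigma <- rbind(c(syy, spo), cbind(spo, Spp))
  dimnames(sigma) <- list(c("y", "x1", "x2"), c("y", "x1", "x2"))
  cfg <- triConfig(sigma, n = c(80000, 80000, 80000), m = 20000, seed = 301)
  sim <- simulateSumstats(cfg)
  panel <- mergeCohorts(sim$sumstats)
  st <- buildCovarianceStack(panel, sim$ldscores, sim$m, n_blocks = 100)
  fit <- geneticMultipleRegression(st, "y", c("x1", "x2"))
  expect_lt(abs(fit$beta[1] - 0.4), 2 * fit$se[1])
  expect_lt(abs(fit$beta[2] + 0.2), 2 * fit$se[2])
})

test_that("jackknife V off-diagonal (h2_1, cov_12) has the empirical sign over replicates", {
  vs <- emp <- matrix(NA_real_, 30, 2)
  sg <- matrix(c(0.3, 0.18, 0.12, 0.18, 0.3, 0.1, 0.12, 0.1, 0.25), 3, 3)
  dimnames(sg) <- list(c("y", "x1", "x2"), c("y", "x1", "x2"))
  for (r in 1:30) {
    cfg <- triConfig(sg, n = c(40000, 40000, 40000), m = 5000,
                     seed = 4000 + r)
    sim <- simulateSumstats(cfg)
    panel <- mergeCohorts(sim$sumstats)
    st <- buildCovarianceStack(panel, sim$ldscores, sim$m, n_blocks = 50)
    # vech order: (1,1) is element 1, (2,1) element 2
    vs[r, 1] <- sampCov(st)[1, 2]
    emp[r, ] <- c(gcov(st)[1, 1], gcov(st)[1, 2])
  }
  expect_equal(sign(median(vs[, 1])), sign(cov(emp[, 1], emp[, 2])))
})
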