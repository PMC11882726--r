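# helper: an exact stack implied by a loading matrix + residual covariance
exactStack <- function(L, Theta, vdiag = 1e-6) {
  S <- L %*% t(L) + Theta
  labs <- rownames(L)
  dimnames(S) <- list(labs, labs)
  nv <- length(labs) * (length(labs) + 1) / 2
  factorGWAS:::CovarianceStack(labs, S, diag(rep(vdiag, nv)))
}

bifactorWmTruth <- function() {
  labs <- modelZoo()[[1]]@indicators
  L <- matrix(0, 9, 2, dimnames = list(labs, c("EF", "WM")))
  L[, "EF"] <- c(0.29, 0.49, 0.28, 0.25, 0.10, 0.26, 0.16, 0.29, 0.38)
  L[c("UKB_Pairs", "UKB_Digit", "ALSPAC_WM", "NIH_G4"), "WM"] <-
    c(-0.13, 0.19, 0.21, 0.20)
  Theta <- diag(c(0.04, 0.12, 0.06, 0.05, 0.02, 0.08, 0.07, 0.15, 0.15))
  Theta[5, 8] <- Theta[8, 5] <- 0.02
  dimnames(Theta) <- list(labs, labs)
  list(L = L, Theta = Theta)
}

test_that("an exactly-specified stack is recovered to 1e-6 with chi-square 0", {
  tr <- bifactorWmTruth()
  st <- exactStack(tr$L, tr$Theta)
  f <- fitModel(st, modelZoo()[["bifactor_wm"]])
  expect_true(f@converged)
  expect_lt(f@chisq, 1e-8)
  expect_lt(f@srmr, 1e-6)
  expect_equal(f@cfi, 1)
  est <- fitEstimates(f)
  lam <- est[grep("=~", est$label), ]
  truth <- mapply(function(lab) {
    p <- strsplit(lab, "=~")[[1]]
    tr$L[p[2], p[1]]
  }, lam$label)
  # align factor sign (the likelihood is invariant to flipping a factor)
  for (fac in c("EF", "WM")) {
    i <- startsWith(lam$label, paste0(fac, "=~"))
    if (sum(lam$est[i] * truth[i]) < 0) lam$est[i] <- -lam$est[i]
  }
  expect_lt(max(abs(lam$est - truth)), 1e-6)
})

test_that("the saturated model has zero residuals and SRMR 0", {
  tr <- bifactorWmTruth()
  st <- exactStack(tr$L, tr$Theta)
  ind <- stackLabels(st)
  sat <- paste(c(sprintf("F%d =~ 1*%s", seq_along(ind), ind),
                 apply(combn(ind, 2), 2, function(p)
                   sprintf("%s ~~ %s", p[1], p[2]))), collapse = "\n")
  f <- fitModel(st, modelSpec("saturated", sat, indicators = ind))
  expect_equal(f@df, 0)
  expect_equal(f@chisq, 0)
  expect_lt(f@srmr, 1e-7)
  expect_lt(max(abs(f@implied - gcov(st))), 1e-7)
})

test_that("AIC - chisq = 2k and df + k = 45 for every zoo model on any stack", {
  st <- fixtureCovarianceStack()
  zoo <- modelZoo(includeVariants = TRUE)
  for (nm in names(zoo)) {
    f <- fitModel(st, zoo[[nm]])
    k <- countFreeParams(zoo[[nm]])
    expect_equal(f@aic - f@chisq, 2 * k, info = nm)
    expect_equal(f@df + k, 45, info = nm)
    expect_true(f@converged, info = nm)
  }
})

test_that("fit statistics are invariant to trait permutation", {
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- modelZoo()[["three_factor"]]
  f1 <- fitModel(sm, sp)
  perm <- c(4, 1, 9, 2, 7, 3, 8, 5, 6)
  f2 <- fitModel(subsetStack(sm, stackLabels(sm)[perm]), sp)
  expect_equal(f1@chisq, f2@chisq, tolerance = 1e-5)
  expect_equal(f1@aic, f2@aic, tolerance = 1e-5)
  expect_equal(f1@srmr, f2@srmr, tolerance = 1e-6)
  e1 <- fitEstimates(f1); e2 <- fitEstimates(f2)
  expect_equal(e1$est[match(e2$label, e1$label)], e2$est, tolerance = 1e-4)
})

test_that("chi-square stays at zero along a shrinking-V sequence on exact stacks", {
  tr <- bifactorWmTruth()
  for (v in c(1e-4, 1e-6, 1e-8)) {
    f <- fitModel(exactStack(tr$L, tr$Theta, vdiag = v),
                  modelZoo()[["bifactor_wm"]])
    expect_lt(f@chisq, 1e-6)
  }
})

test_that("negative residual variances are flagged as Heywood, fit still returned", {
  labs <- c("a", "b", "c")
  l <- c(0.9, 0.5, 0.5)
  S <- outer(l, l) + diag(c(-0.05, 0.3, 0.3))
  dimnames(S) <- list(labs, labs)
  st <- factorGWAS:::CovarianceStack(labs, S, diag(rep(1e-6, 6)))
  f <- fitModel(st, modelSpec("cf", "G =~ a + b + c", indicators = labs))
  expect_true("a" %in% f@heywood)
  expect_s4_class(f, "FitResult")
})

test_that("a structurally over-parameterized model is a model error", {
  labs <- c("a", "b", "c")
  st <- factorGWAS:::CovarianceStack(labs, diag(3) * 0.5 + 0.1,
                                     diag(rep(1e-4, 6)))
  sp <- modelSpec("over", paste("F1 =~ a + b + c", "F2 =~ a + b + c",
                                "F1 ~~ F2", "a ~~ b", "a ~~ c", "b ~~ c",
                                sep = "\n"), indicators = labs)
  expect_error(fitModel(st, sp), class = "fg_model_error")
})

test_that("fitIndices reproduces the identities and checks the baseline", {
  st <- fixtureCovarianceStack()
  f <- fitModel(st, modelZoo()[["common_factor"]])
  base <- independenceFit(subsetStack(st, f@labels))
  fi <- fitIndices(f, base)
  expect_equal(fi$aic, f@chisq + 2 * f@k)
  expect_equal(fi$cfi, f@cfi)
  other <- independenceFit(subsetStack(st, stackLabels(st)[1:5]))
  expect_error(fitIndices(f, other), class = "fg_input_error")
})

test_that("classifyFit applies the published thresholds, joint label is the weaker", {
  expect_equal(classifyFit(0.96, 0.04), "good")
  expect_equal(classifyFit(0.9859904, 0.09571648), "acceptable")
  expect_equal(classifyFit(0.89, 0.04), "poor")
  expect_equal(classifyFit(0.99, 0.2), "poor")
  expect_equal(classifyFit(0.92, 0.03), "acceptable")
})

test_that("compareModels reports ties, best-by-AIC and nested differences", {
  tr <- bifactorWmTruth()
  st <- exactStack(tr$L, tr$Theta)
  f <- fitModel(st, modelZoo()[["bifactor_wm"]])
  cmp <- compareModels(list(m1 = f, m2 = f))
  expect_true(attr(cmp, "tie"))
  expect_equal(cmp$delta_aic, c(0, 0))

  # with the printed fit statistics as input, the endorsed model is best
  tab <- refModelFitStats()
  fits <- lapply(seq_len(nrow(tab)), function(i) {
    methods::new("FitResult", modelName = tab$model[i], labels = letters[1:9],
                 estimates = data.frame(), chisq = tab$chisq[i],
                 df = as.numeric(tab$df[i]), p = tab$p[i], cfi = tab$cfi[i],
                 srmr = tab$srmr[i], aic = tab$aic[i],
                 k = 45 - tab$df[i], nMoments = 45,
                 implied = diag(9), converged = TRUE, heywood = character())
  })
  names(fits) <- tab$model
  cmp2 <- compareModels(fits)
  expect_equal(cmp2$model[cmp2$best], "bifactor_wm_sub")
  # printed df difference between common-factor and three-factor fits
  expect_equal(cmp2$df[cmp2$model == "common_factor"] -
                 cmp2$df[cmp2$model == "three_factor"], 4)
})

test_that("parameter recovery on a synthetic panel from the endorsed structure", {
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- gwasSpec()
  f <- fitModel(sm, sp)
  expect_true(f@converged)
  est <- fitEstimates(f)
  lam <- est[grep("=~", est$label), ]
  Ltrue <- ns$cfg$loadings
  truth <- mapply(function(lab) {
    p <- strsplit(lab, "=~")[[1]]
    Ltrue[p[2], p[1]]
  }, lam$label)
  for (fac in c("EF", "WM", "SUB")) {
    i <- startsWith(lam$label, paste0(fac, "=~"))
    if (sum(lam$est[i] * truth[i]) < 0) lam$est[i] <- -lam$est[i]
  }
  z <- (lam$est - truth) / lam$se
  expect_gt(mean(abs(z) <= 2), 0.8)   # calibrated coverage
  expect_lt(max(abs(z)), 4)
})
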