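test_that("snpToCovariances builds the augmented matrices on the z/sqrt(N) scale", {
  labs <- c("a", "b")
  S <- matrix(c(0.3, 0.1, 0.1, 0.25), 2, 2, dimnames = list(labs, labs))
  st <- factorGWAS:::CovarianceStack(labs, S, diag(rep(1e-4, 3)))
  aug <- snpToCovariances(c(a = 2, b = 0), c(a = 10000, b = 40000), st)
  expect_equal(aug$S["SNP", "a"], 0.02)      # z / sqrt(N)
  expect_equal(aug$S["SNP", "b"], 0)
  expect_equal(aug$S["SNP", "SNP"], 1)       # standardized genotype
  expect_equal(diag(aug$V)[4:5], c(1e-4, 2.5e-5))   # 1/N per trait
  expect_true(all(aug$V[1:3, 4:5] == 0))     # zero assumed cross-terms
  # null SNP: all-zero SNP row
  aug0 <- snpToCovariances(c(a = 0, b = 0), c(a = 1e4, b = 1e4), st)
  expect_true(all(aug0$S["SNP", c("a", "b")] == 0))
  expect_error(snpToCovariances(c(a = 1), c(a = 1e4), st),
               class = "fg_input_error")
})

test_that("the degenerate single-indicator model returns the input GWAS unchanged", {
  labs <- "trait"
  S <- matrix(0.25, 1, 1, dimnames = list(labs, labs))
  st <- factorGWAS:::CovarianceStack(labs, S, matrix(1e-4, 1, 1))
  sp <- modelSpec("deg", "F =~ 1*trait", indicators = labs)
  z <- 2.1; n <- 25000
  aug <- snpToCovariances(c(trait = z), c(trait = n), st)
  eff <- fitSnp(sp, aug, st)
  expect_equal(eff$beta, z / sqrt(n), tolerance = 1e-8)
  expect_equal(eff$se, 1 / sqrt(n), tolerance = 1e-6)
  expect_equal(eff$p, 2 * pnorm(-abs(z)), tolerance = 1e-6)
})

test_that("factor-effect Z depends on the data only through the input Z-scores", {
  # N only sets the scale of the standardized-genotype effect: doubling all
  # N with the Z-scores fixed rescales beta and its SE by 1/sqrt(2) and
  # leaves the factor-effect Z (hence p) unchanged
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- gwasSpec()
  base <- fitModel(sm, sp)
  z <- withr::with_seed(77, setNames(rnorm(9, sd = 2), stackLabels(sm)))
  N <- ns$panel@N
  aug1 <- snpToCovariances(z, N, sm)
  aug2 <- snpToCovariances(z, 2 * N, sm)
  e1 <- fitSnp(sp, aug1, sm, baseFit = base)
  e2 <- fitSnp(sp, aug2, sm, baseFit = base)
  expect_equal(e1$z, e2$z, tolerance = 5e-3)
  expect_equal(e2$beta, e1$beta / sqrt(2), tolerance = 5e-3)
})

test_that("a SNP with effects proportional to the loadings has Q near zero", {
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- gwasSpec()
  base <- fitModel(sm, sp)
  lamEF <- ns$cfg$loadings[stackLabels(sm), "EF"]
  N <- ns$panel@N[stackLabels(sm)]
  gamma <- 0.01
  z <- sqrt(N) * lamEF * gamma     # exact common-pathway signal, no noise
  aug <- snpToCovariances(z, N, sm)
  q <- qsnpTest(sp, aug, sm, baseFit = base)
  expect_lt(q$chi2, 0.05)
  expect_equal(q$df, 9 - 3)
  eff <- fitSnp(sp, aug, sm, baseFit = base)
  expect_lt(abs(eff$beta[eff$factor == "EF"] - gamma), 3 * eff$se[eff$factor == "EF"])
})

test_that("a SNP acting on one indicator only is removed by the Q-SNP filter", {
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- gwasSpec()
  base <- fitModel(sm, sp)
  z <- setNames(rep(0, 9), stackLabels(sm))
  z["UKB_Trails"] <- 14      # large direct effect, nothing elsewhere
  aug <- snpToCovariances(z, ns$panel@N, sm)
  q <- qsnpTest(sp, aug, sm, baseFit = base)
  expect_lt(q$p, 5e-8)
})

test_that("runLatentGwas conserves SNPs, reconciles counts and is deterministic", {
  ns <- nullStack()
  Z <- withr::with_seed(303, matrix(rnorm(30 * 9), 30, 9,
                                    dimnames = list(NULL, ns$panel@traits)))
  # one blatant single-indicator SNP that the Q filter must remove
  Z[7, ] <- 0; Z[7, 1] <- 15
  panel <- panelFromZ(Z, ns$panel@N, ns$panel@traits)
  sp <- gwasSpec()
  g1 <- runLatentGwas(panel, ns$stack, sp)
  rep1 <- gwasReport(g1)
  expect_equal(rep1$n_input, 30)
  expect_equal(rep1$n_input - rep1$n_output,
               length(unique(gwasResults(g1)$rsid[
                 gwasResults(g1)$zdiff_removed | gwasResults(g1)$qsnp_removed])))
  expect_true(any(gwasResults(g1)$qsnp_removed[gwasResults(g1)$rsid == "snp00007"]))

  # filters disabled: output count equals panel count
  g0 <- runLatentGwas(panel, ns$stack, sp,
                      filters = list(zdiff = NA, qsnp_alpha = NA))
  expect_equal(gwasReport(g0)$n_output, 30)

  # determinism: identical runs, byte-identical factor sumstats
  g2 <- runLatentGwas(panel, ns$stack, sp)
  expect_identical(gwasResults(g1), gwasResults(g2))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeSumstats(factorSumstats(g1, panel)[["EF"]], f1)
  writeSumstats(factorSumstats(g2, panel)[["EF"]], f2)
  expect_identical(readLines(f1), readLines(f2))

  # output round-trips through the sumstats reader
  back <- readSumstats(f1, trait = "EF")
  expect_equal(nrow(ssData(back)),
               sum(!gwasResults(g1)$zdiff_removed &
                     !gwasResults(g1)$qsnp_removed &
                     gwasResults(g1)$factor == "EF"))
})

test_that("an indefinite stack triggers smoothing and the pre/post Z-difference path", {
  ns <- nullStack()
  stackI <- ns$stack
  # push one covariance far enough to break positive semidefiniteness
  i <- 1; j <- 2
  bad <- sqrt(stackI@S[i, i] * stackI@S[j, j]) * 1.4
  stackI@S[i, j] <- stackI@S[j, i] <- bad
  expect_lt(min(eigen(stackI@S, symmetric = TRUE, only.values = TRUE)$values), 0)
  Z <- withr::with_seed(505, matrix(rnorm(6 * 9), 6, 9,
                                    dimnames = list(NULL, ns$panel@traits)))
  panel <- panelFromZ(Z, ns$panel@N, ns$panel@traits)
  g <- runLatentGwas(panel, stackI, gwasSpec())
  rep <- gwasReport(g)
  expect_true(rep$smoothing$S$changed)
  expect_gt(rep$smoothing$S$max_abs_change, 1e-6)
  expect_equal(rep$n_input - rep$n_output,
               length(unique(gwasResults(g)$rsid[gwasResults(g)$zdiff_removed |
                                                   gwasResults(g)$qsnp_removed])))
})

test_that("measurement estimates stay near the SNP-free fit for null SNPs", {
  ns <- nullStack()
  sm <- smoothStack(ns$stack)$stack
  sp <- gwasSpec()
  base <- fitModel(sm, sp)
  basePar <- fitEstimates(base)$est
  sc <- factorGWAS:::.snpContexts(sp, sm, ns$panel@N)
  nMeas <- length(basePar)
  for (s in 1:20) {
    z <- withr::with_seed(600 + s, setNames(rnorm(9), stackLabels(sm)))
    r <- factorGWAS:::.snpFitBoth(sp, sc, z / sqrt(sc$N), basePar = basePar)
    expect_true(r$effect$converged[1])
  }
  # one detailed check on parameter drift
  z <- withr::with_seed(601, setNames(rnorm(9), stackLabels(sm)))
  aug <- snpToCovariances(z, ns$panel@N, sm)
  fit <- factorGWAS:::.fitEngine(sc$ctxC, c(sc$svech, aug$snpCov), sc$Vdiag,
                                 start = c(basePar, 0, 0, 0), S = sc$S,
                                 seedTag = "drift")
  expect_lt(max(abs(fit$par[seq_len(nMeas)] - basePar)), 0.02)
})

test_that("reverse-coding one indicator flips its loading, factor p unchanged", {
  ns <- nullStack()
  Z <- withr::with_seed(404, matrix(rnorm(12 * 9), 12, 9,
                                    dimnames = list(NULL, ns$panel@traits)))
  panel <- panelFromZ(Z, ns$panel@N, ns$panel@traits)
  sp <- gwasSpec()
  flip <- "CHARGE_Stroop"
  panelF <- panel
  panelF@Z[, match(flip, panel@traits)] <- -panelF@Z[, match(flip, panel@traits)]
  stackF <- ns$stack
  i <- match(flip, stackLabels(stackF))
  stackF@S[i, -i] <- -stackF@S[i, -i]
  stackF@S[-i, i] <- -stackF@S[-i, i]
  # exact sign flip of V: a vech moment changes sign iff exactly one of its
  # two indices is the flipped trait
  ii <- factorGWAS:::vechIndices(9)
  dsign <- ifelse(xor(ii[, 1] == i, ii[, 2] == i), -1, 1)
  stackF@V <- stackF@V * outer(dsign, dsign)
  g1 <- runLatentGwas(panel, ns$stack, sp,
                      filters = list(zdiff = NA, qsnp_alpha = NA))
  g2 <- runLatentGwas(panelF, stackF, sp,
                      filters = list(zdiff = NA, qsnp_alpha = NA))
  r1 <- gwasResults(g1); r2 <- gwasResults(g2)
  expect_equal(r1$p, r2$p, tolerance = 1e-4)
  f1 <- fitModel(smoothStack(ns$stack)$stack, sp)
  f2 <- fitModel(smoothStack(stackF)$stack, sp)
  l1 <- fitEstimates(f1); l2 <- fitEstimates(f2)
  ef <- grep("^EF=~", l1$label)
  # align the overall factor sign, then the flipped indicator's loading must
  # have the opposite sign and the same magnitude
  s <- sign(sum(l1$est[ef] * l2$est[ef]))
  lab <- paste0("EF=~", flip)
  e1 <- l1$est[l1$label == lab]; e2 <- s * l2$est[l2$label == lab]
  expect_equal(abs(e2), abs(e1), tolerance = 1e-3)
  expect_lt(e1 * e2, 0)
})
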