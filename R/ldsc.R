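# LD-score regression: univariate heritability, bivariate genetic
# covariance, and the joint block-jackknife sampling covariance matrix.
#
# Model per SNP j (traits a, b; sample sizes N; M SNPs; LD score l_j):
#   E[z_aj z_bj] = sqrt(N_a N_b) * sigma_g[a,b] * l_j / M + intercept_ab
# so regressing z_a z_b on x = l * sqrt(N_a N_b) / M gives the genetic
# covariance as the slope; the free intercept absorbs sample overlap (and,
# in the univariate case a == b, confounding).
#
# Regression weights (computed once from a first-pass unweighted fit and a
# per-trait unweighted heritability pass, then held fixed across the
# jackknife) are the standard LDSC heteroskedasticity x oversampling
# weights:
#   w_j = 1 / ( l_j * [ (1 + N_a h_a^2 l_j/M)(1 + N_b h_b^2 l_j/M)
#                       + (slope1 * sqrt(N_a N_b) l_j/M + int1)^2 ] )

# weighted-least-squares (intercept + slope) sufficient statistics per block
.wlsBlockSums <- function(y, x, w, blocks) {
  rowsum(cbind(w, w * x, w * x^2, w * y, w * x * y), blocks)
}

.wlsSolve <- function(a1, a2, a3, a4, a5) {
  d <- a1 * a3 - a2^2
  list(slope = (a1 * a5 - a2 * a4) / d, int = (a3 * a4 - a2 * a5) / d)
}

# full and delete-one-block estimates from block sums
.wlsJackknife <- function(bs) {
  tot <- colSums(bs)
  full <- .wlsSolve(tot[1], tot[2], tot[3], tot[4], tot[5])
  del <- sweep(-bs, 2, tot, "+")   # totals minus each block
  d <- .wlsSolve(del[, 1], del[, 2], del[, 3], del[, 4], del[, 5])
  list(slope = full$slope, int = full$int,
       slope_del = d$slope, int_del = d$int)
}

.jackSE <- function(del) {
  g <- length(del)
  sqrt((g - 1) / g * sum((del - mean(del))^2))
}

# unweighted first-pass slope of z^2 on l*N/M, truncated to [0, 1]
.pass1H2 <- function(z, n, l2, m) {
  x <- l2 * n / m
  fit <- stats::lm.fit(cbind(1, x), z^2)
  min(max(fit$coefficients[2], 0), 1)
}

.ldscWeights <- function(l2, m, na, nb, ha, hb, slope1, int1) {
  c0 <- (1 + na * ha * l2 / m) * (1 + nb * hb * l2 / m) +
    (slope1 * sqrt(na * nb) * l2 / m + int1)^2
  1 / (pmax(l2, 1) * pmax(c0, 1e-6))
}

.contiguousBlocks <- function(n, n_blocks) {
  ceiling(seq_len(n) * n_blocks / n)
}

# core pairwise regression; za/zb/l2 already intersected and ordered
.ldscPairFit <- function(za, zb, na, nb, l2, m, blocks, ha, hb) {
  x <- l2 * sqrt(na * nb) / m
  y <- za * zb
  p1 <- stats::lm.fit(cbind(1, x), y)$coefficients
  w <- .ldscWeights(l2, m, na, nb, ha, hb, p1[2], p1[1])
  .wlsJackknife(.wlsBlockSums(y, x, w, blocks))
}

#' Bivariate LD-score regression
#'
#' Estimates the genetic covariance between two traits from their summary
#' statistics by regressing the per-SNP Z-score product on
#' \code{l * sqrt(Na*Nb) / M} with standard LDSC weights; the free intercept
#' absorbs sample overlap. The standard error comes from a delete-a-block
#' jackknife over SNP blocks contiguous in the table's sort order.
#'
#' Tables are assumed allele-harmonized (see \code{\link{mergeCohorts}}).
#'
#' @param a,b \code{\link{SumStats}} objects (pass the same object twice for
#'   a heritability, or use \code{\link{estimateH2}}).
#' @param ldscores \code{data.frame(SNP, L2)}.
#' @param m total SNP count M used to scale LD scores.
#' @param n_blocks jackknife blocks (default 200, the LDSC convention).
#' @return list with \code{cov}, \code{se}, \code{intercept},
#'   \code{intercept_se}, \code{n_snps}, \code{n_blocks}.
#' @export
estimateGencov <- function(a, b, ldscores, m, n_blocks = 200) {
  da <- ssData(a); db <- ssData(b)
  shared <- intersect(intersect(da$rsid, db$rsid), ldscores$SNP)
  if (length(shared) < 2 * n_blocks)
    inputError("only %d shared SNPs; need at least 2*n_blocks = %d",
               length(shared), 2 * n_blocks)
  shared <- da$rsid[da$rsid %in% shared]   # keep a's sort order
  ia <- match(shared, da$rsid); ib <- match(shared, db$rsid)
  il <- match(shared, ldscores$SNP)
  za <- da$z[ia]; zb <- db$z[ib]
  na <- stats::median(da$n[ia]); nb <- stats::median(db$n[ib])
  l2 <- ldscores$L2[il]
  blocks <- .contiguousBlocks(length(shared), n_blocks)
  ha <- .pass1H2(za, na, l2, m)
  hb <- if (identical(da, db)) ha else .pass1H2(zb, nb, l2, m)
  fit <- .ldscPairFit(za, zb, na, nb, l2, m, blocks, ha, hb)
  list(cov = unname(fit$slope), se = .jackSE(fit$slope_del),
       intercept = unname(fit$int), intercept_se = .jackSE(fit$int_del),
       n_snps = length(shared), n_blocks = n_blocks)
}

#' Univariate LD-score regression
#'
#' SNP heritability as the slope of the weighted regression of z-squared on
#' \code{l * N / M}; implemented as the self-covariance special case of
#' \code{\link{estimateGencov}} so the two agree exactly.
#'
#' @inheritParams estimateGencov
#' @param table a \code{\link{SumStats}} object.
#' @return list with \code{h2}, \code{se}, \code{intercept},
#'   \code{intercept_se}, \code{z} (= h2/se), \code{n_snps}, \code{n_blocks}.
#' @export
estimateH2 <- function(table, ldscores, m, n_blocks = 200) {
  fit <- estimateGencov(table, table, ldscores, m, n_blocks)
  list(h2 = fit$cov, se = fit$se, intercept = fit$intercept,
       intercept_se = fit$intercept_se, z = fit$cov / fit$se,
       n_snps = fit$n_snps, n_blocks = fit$n_blocks)
}

#' Genetic covariance matrix with joint jackknife sampling covariance
#'
#' Runs all pairwise LD-score regressions on an aligned panel and assembles
#' the genetic covariance matrix S together with the sampling covariance V
#' of \code{vech(S)} from a joint delete-a-block jackknife (the same SNP
#' blocks for every element, so V captures the cross-element dependence).
#' The diagonal of V equals the squared jackknife SEs of the corresponding
#' pairwise estimates.
#'
#' @param panel an \code{\link{AlignedPanel}}.
#' @inheritParams estimateGencov
#' @return a \code{\link{CovarianceStack}}.
#' @export
buildCovarianceStack <- function(panel, ldscores, m, n_blocks = 200) {
  if (length(panel@traits) < 2) inputError("panel needs at least 2 traits")
  keep <- panel@snps$rsid %in% ldscores$SNP
  if (sum(keep) < 2 * n_blocks)
    inputError("only %d panel SNPs with LD scores; need %d",
               sum(keep), 2 * n_blocks)
  Z <- panel@Z[keep, , drop = FALSE]
  l2 <- ldscores$L2[match(panel@snps$rsid[keep], ldscores$SNP)]
  N <- panel@N
  t <- length(N)
  nv <- t * (t + 1) / 2
  blocks <- .contiguousBlocks(nrow(Z), n_blocks)
  h1 <- vapply(seq_len(t), function(i) .pass1H2(Z[, i], N[i], l2, m), 0)
  S <- matrix(0, t, t)
  intercepts <- matrix(0, t, t)
  del <- matrix(0, n_blocks, nv)
  v <- 0L
  for (k in seq_len(t)) for (i in k:t) {   # column-major lower triangle
    v <- v + 1L
    fit <- .ldscPairFit(Z[, i], Z[, k], N[i], N[k], l2, m, blocks,
                        h1[i], h1[k])
    S[i, k] <- S[k, i] <- fit$slope
    intercepts[i, k] <- intercepts[k, i] <- fit$int
    del[, v] <- fit$slope_del
  }
  g <- n_blocks
  cen <- sweep(del, 2, colMeans(del))
  V <- (g - 1) / g * crossprod(cen)
  CovarianceStack(panel@traits, S, V, nBlocks = n_blocks,
                  intercepts = intercepts)
}

#' Standardize a covariance stack to the correlation scale
#'
#' Rescales S to genetic correlations (unit diagonal) and propagates V by
#' the delta method: for \code{r_ij = s_ij / sqrt(s_ii s_jj)} the Jacobian
#' rows are \code{1/sqrt(s_ii s_jj)} w.r.t. \code{s_ij} and
#' \code{-r_ij/(2 s_ii)}, \code{-r_ij/(2 s_jj)} w.r.t. the variances;
#' diagonal moments become exact (their sampling variance is floored at a
#' tiny positive value to keep V usable as a weight matrix). Idempotent.
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @return the standardized \code{\link{CovarianceStack}}.
#' @export
standardizeStack <- function(stack) {
  S <- stack@S
  d <- diag(S)
  if (any(d <= 0))
    numericError("non-positive genetic variance for trait(s): %s",
                 paste(stack@labels[d <= 0], collapse = ", "))
  if (all(abs(d - 1) < 1e-12)) return(stack)   # already standardized
  t <- length(d)
  nv <- t * (t + 1) / 2
  idx <- vechIndices(t)
  pos <- matrix(0L, t, t)
  pos[cbind(idx[, 1], idx[, 2])] <- seq_len(nv)
  pos <- pos + t(pos); diag(pos) <- diag(pos) / 2
  R <- S / sqrt(outer(d, d))
  J <- matrix(0, nv, nv)
  for (e in seq_len(nv)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    if (i == j) next
    J[e, e] <- 1 / sqrt(d[i] * d[j])
    J[e, pos[i, i]] <- J[e, pos[i, i]] - R[i, j] / (2 * d[i])
    J[e, pos[j, j]] <- J[e, pos[j, j]] - R[i, j] / (2 * d[j])
  }
  V <- J %*% stack@V %*% t(J)
  V <- (V + t(V)) / 2
  dv <- diag(V)
  floorv <- 0.01 * min(dv[dv > 0])
  diag(V) <- pmax(dv, floorv)
  CovarianceStack(stack@labels, R, V, nBlocks = stack@nBlocks,
                  intercepts = stack@intercepts, h2z = stack@h2z)
}

#' Screen indicators for inclusion
#'
#' Applies the two published inclusion rules: traits whose SNP heritability
#' Z statistic falls below the threshold are excluded (non-significant
#' heritability), and traits whose absolute genetic correlation exceeds
#' \code{collinearity_r} with at least two other retained traits are flagged
#' as multicollinear and excluded. Heritability Z statistics are taken from
#' the stack metadata (recorded at build time), so the function accepts a
#' stack on either the covariance or the correlation scale.
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @param h2_z_threshold one-sided heritability significance threshold
#'   (default 1.645, i.e. alpha = 0.05 one-sided; configurable).
#' @param collinearity_r multicollinearity threshold on |r_g| (default 0.9).
#' @return list with \code{retained} labels and \code{report}
#'   (\code{data.frame(label, retained, reason)}).
#' @export
screenIndicators <- function(stack, h2_z_threshold = 1.645,
                             collinearity_r = 0.9) {
  labs <- stack@labels
  h2z <- stack@h2z
  R <- stats::cov2cor(stack@S)
  reason <- rep(NA_character_, length(labs))
  keep <- h2z >= h2_z_threshold
  reason[!keep] <- "non-significant h2"
  cand <- which(keep)
  nhit <- vapply(cand, function(i) {
    sum(abs(R[i, cand]) > collinearity_r) - 1L   # exclude self
  }, 0L)
  multi <- cand[nhit >= 2]
  keep[multi] <- FALSE
  reason[multi] <- sprintf(
    "multicollinear (|r_g| > %.2f with %d retained traits)",
    collinearity_r, nhit[match(multi, cand)])
  list(retained = labs[keep],
       report = data.frame(label = labs, retained = keep, reason = reason))
}

#' Genetic multiple regression on a covariance stack
#'
#' Partial genetic regression coefficients of an outcome trait on a set of
#' predictor traits, solved from the genetic normal equations
#' \code{S_pp b = S_po}; standard errors propagate the sampling covariance V
#' by the delta method. Used to control factor associations for variance
#' shared with other phenotypes (run on a standardized stack for
#' standardized partial coefficients).
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @param outcome outcome trait label.
#' @param predictors predictor trait labels.
#' @return \code{data.frame(predictor, beta, se, z, p)}.
#' @export
geneticMultipleRegression <- function(stack, outcome, predictors) {
  labs <- stack@labels
  o <- match(outcome, labs); p <- match(predictors, labs)
  if (is.na(o) || anyNA(p)) inputError("outcome/predictors not all in stack")
  S <- stack@S
  Spp <- S[p, p, drop = FALSE]
  beta <- tryCatch(solve(Spp, S[p, o]),
                   error = function(e)
                     modelError("singular predictor submatrix: %s",
                                conditionMessage(e)))
  t <- length(labs)
  idx <- vechIndices(t)
  nv <- nrow(idx)
  J <- matrix(0, length(p), nv)
  SppInv <- solve(Spp)
  for (e in seq_len(nv)) {
    i <- idx[e, 1]; j <- idx[e, 2]
    dS <- matrix(0, t, t); dS[i, j] <- dS[j, i] <- 1
    dSpo <- dS[p, o]
    dSpp <- dS[p, p, drop = FALSE]
    db <- SppInv %*% (dSpo - dSpp %*% beta)
    if (any(db != 0)) J[, e] <- db
  }
  covB <- J %*% stack@V %*% t(J)
  se <- sqrt(pmax(diag(covB), 0))
  z <- beta / se
  data.frame(predictor = predictors, beta = as.numeric(beta), se = se,
             z = as.numeric(z), p = zToP(z))
}
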