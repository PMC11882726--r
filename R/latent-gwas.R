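# Per-SNP latent-factor GWAS: augment (S, V) with one SNP, re-fit the
# measurement model with SNP -> factor regressions, test common-pathway
# violations (Q-SNP), and apply the published SNP-level QC filters.
#
# The SNP enters on the standardized-genotype scale (variance fixed to 1):
# cov(SNP, trait_i) = z_i / sqrt(N_i), with sampling variance 1/N_i and
# zero assumed cross-terms in the augmented V. The augmented moment vector
# is ordered [vech(trait block), cov(SNP, trait_1..t)]; the fixed SNP
# variance is not a fitted moment.

#' Augment a covariance stack with one SNP
#'
#' @param snpZ named per-trait Z statistics at one SNP (names = stack labels).
#' @param snpN named per-trait sample sizes.
#' @param stack the SNP-free \code{\link{CovarianceStack}}.
#' @return list with \code{S} ((t+1) x (t+1), SNP last, unit SNP variance),
#'   \code{V} (augmented sampling covariance in the documented order),
#'   \code{labels} and \code{snpCov}.
#' @export
snpToCovariances <- function(snpZ, snpN, stack) {
  labs <- stack@labels
  if (!all(labs %in% names(snpZ)) || !all(labs %in% names(snpN)))
    inputError("SNP must be present for all traits in the stack")
  z <- snpZ[labs]; n <- snpN[labs]
  cv <- z / sqrt(n)
  t <- length(labs)
  S <- rbind(cbind(stack@S, cv), c(cv, 1))
  dimnames(S) <- list(c(labs, "SNP"), c(labs, "SNP"))
  nv <- t * (t + 1) / 2
  V <- matrix(0, nv + t, nv + t)
  V[seq_len(nv), seq_len(nv)] <- stack@V
  diag(V)[nv + seq_len(t)] <- 1 / n
  list(S = S, V = V, labels = labs, snpCov = cv)
}

# Precomputed per-stack machinery shared across the SNP loop: model contexts
# for the common-pathway and independent-pathways augmentations, the inverse
# of the (block-diagonal) augmented V, and the DWLS weights.
.snpContexts <- function(spec, stack, N) {
  N <- N[stack@labels]
  ctxC <- .assembleModel(spec, stack@labels, snp = "factor")
  ctxI <- .assembleModel(spec, stack@labels, snp = "indicator")
  Vtt <- stack@V
  nv <- nrow(Vtt)
  t <- length(N)
  Vtti <- tryCatch(solve(Vtt), error = function(e)
    solve(Vtt + diag(mean(diag(Vtt)) * 1e-8, nv)))
  Vi <- matrix(0, nv + t, nv + t)
  Vi[seq_len(nv), seq_len(nv)] <- Vtti
  diag(Vi)[nv + seq_len(t)] <- N
  V <- matrix(0, nv + t, nv + t)
  V[seq_len(nv), seq_len(nv)] <- Vtt
  diag(V)[nv + seq_len(t)] <- 1 / N
  list(ctxC = ctxC, ctxI = ctxI, Vi = Vi, V = V,
       Vdiag = c(diag(Vtt), 1 / N), svech = vech(stack@S), N = N,
       S = stack@S)
}

# residual-based chi-square with precomputed V inverse
.browneChisqVi <- function(r, Vi, J, df) {
  if (df <= 0) return(0)
  u <- drop(Vi %*% r)
  if (ncol(J) == 0) return(max(drop(crossprod(r, u)), 0))
  Ju <- drop(crossprod(J, u))
  A <- crossprod(J, Vi %*% J)
  max(drop(crossprod(r, u)) - drop(crossprod(Ju, .pinvSym(A) %*% Ju)), 0)
}

# fit one SNP under both augmentations; basePar warm-starts the measurement
# parameters
.snpFitBoth <- function(spec, sc, snpCov, basePar = NULL, effectOnly = FALSE) {
  s <- c(sc$svech, snpCov)
  startC <- if (!is.null(basePar)) {
    # GLS warm start for the SNP -> factor paths given the measurement fit
    L <- .unpack(sc$ctxC, c(basePar, rep(0, sc$ctxC$nSnp)))$L
    A <- crossprod(L * sqrt(sc$N))
    b0 <- drop(.pinvSym(A) %*% crossprod(L * sc$N, snpCov))
    c(basePar, b0)
  } else NULL
  fitC <- .fitEngine(sc$ctxC, s, sc$Vdiag, start = startC, S = sc$S,
                     seedTag = spec@name)
  JC <- .deltaMat(sc$ctxC, fitC$par)
  rC <- s - .sigmaVec(sc$ctxC, fitC$par)
  w <- 1 / pmax(sc$Vdiag, .Machine$double.eps)
  se <- .sandwichSE(JC, w, sc$V)
  bIdx <- sc$ctxC$nLam + sc$ctxC$nPsi + sc$ctxC$nTh + seq_len(sc$ctxC$nSnp)
  beta <- fitC$par[bIdx]; bse <- se[bIdx]; z <- beta / bse
  eff <- data.frame(factor = sc$ctxC$factors, beta = beta, se = bse, z = z,
                    p = zToP(z), converged = fitC$converged)
  if (effectOnly) return(list(effect = eff))
  chisqC <- .browneChisqVi(rC, sc$Vi, JC, sc$ctxC$nMoments - sc$ctxC$k)
  startI <- if (!is.null(basePar)) c(basePar, snpCov) else NULL
  fitI <- .fitEngine(sc$ctxI, s, sc$Vdiag, start = startI, S = sc$S,
                     seedTag = spec@name)
  JI <- .deltaMat(sc$ctxI, fitI$par)
  rI <- s - .sigmaVec(sc$ctxI, fitI$par)
  chisqI <- .browneChisqVi(rI, sc$Vi, JI, sc$ctxI$nMoments - sc$ctxI$k)
  qdf <- length(sc$N) - length(spec@factors)
  qchi <- max(chisqC - chisqI, 0)
  list(effect = eff,
       q = list(chi2 = qchi, df = qdf,
                p = max(stats::pchisq(qchi, qdf, lower.tail = FALSE),
                        .Machine$double.xmin)))
}

#' Per-SNP latent-factor effects
#'
#' Re-fits the measurement model with the SNP regressed onto every latent
#' factor (common-pathway model) and returns the per-factor effect, sandwich
#' SE, Z and two-sided normal p-value. The factor disturbance variances stay
#' fixed at 1; SNP effects are tiny on this scale, so factor variances
#' remain 1 to numerical accuracy.
#'
#' @param spec a \code{\link{ModelSpec}} previously fitted on the SNP-free
#'   stack.
#' @param aug augmented matrices from \code{\link{snpToCovariances}}.
#' @param stack the SNP-free stack (used for labels).
#' @param baseFit optional \code{\link{FitResult}} of \code{spec} on the
#'   SNP-free stack; its estimates warm-start the per-SNP fit.
#' @return \code{data.frame(factor, beta, se, z, p, converged)}.
#' @export
fitSnp <- function(spec, aug, stack, baseFit = NULL) {
  sc <- .snpContexts(spec, stack, .augN(aug))
  warm <- if (!is.null(baseFit)) baseFit@estimates$est else NULL
  .snpFitBoth(spec, sc, aug$snpCov, basePar = warm, effectOnly = TRUE)$effect
}

# per-trait N implied by the augmented V (sampling variance of z/sqrt(N))
.augN <- function(aug) {
  t <- length(aug$labels)
  nv <- t * (t + 1) / 2
  stats::setNames(1 / diag(aug$V)[nv + seq_len(t)], aug$labels)
}

#' Q-SNP heterogeneity test
#'
#' Chi-square difference between the common-pathway model (the SNP acts only
#' through the latent factors) and the independent-pathways model (the SNP
#' has a direct effect on every indicator), with df = indicators - SNP
#' paths. Large values mean the SNP's indicator effects are not proportional
#' to the loadings, violating the common-pathway assumption.
#'
#' @inheritParams fitSnp
#' @return list \code{(chi2, df, p)}.
#' @export
qsnpTest <- function(spec, aug, stack, baseFit = NULL) {
  sc <- .snpContexts(spec, stack, .augN(aug))
  warm <- if (!is.null(baseFit)) baseFit@estimates$est else NULL
  .snpFitBoth(spec, sc, aug$snpCov, basePar = warm)$q
}

#' Run the latent-factor GWAS with the published QC sequence
#'
#' Smooths the covariance stack to the nearest PSD matrices, fits the
#' measurement model, and loops over the panel's SNPs estimating factor
#' effects and Q-SNP statistics. When smoothing changed the matrices, every
#' SNP is also run under the pre-smoothed stack and SNPs whose factor-effect
#' Z changes by strictly more than \code{filters$zdiff} on any factor are
#' removed; SNPs with Q-SNP p below \code{filters$qsnp_alpha} are removed.
#' Removal counts reconcile exactly with input minus output.
#'
#' @param panel an \code{\link{AlignedPanel}}.
#' @param stack the SNP-free \code{\link{CovarianceStack}} for the panel's
#'   traits (pre-smoothing).
#' @param spec a \code{\link{ModelSpec}}.
#' @param filters list: \code{zdiff} (threshold on |dZ|, default 1; NA
#'   disables), \code{qsnp_alpha} (default 5e-8; NA disables).
#' @param snps optional subset of rsids to analyse.
#' @return a \code{\link{LatentGwasResult}}.
#' @export
runLatentGwas <- function(panel, stack, spec,
                          filters = list(zdiff = 1, qsnp_alpha = 5e-8),
                          snps = NULL) {
  zdiffThr <- filters$zdiff %||% 1
  qsnpAlpha <- filters$qsnp_alpha %||% 5e-8
  # align stack to the model's indicator order so warm starts line up
  stack <- subsetStack(stack, spec@indicators)
  sm <- smoothStack(stack)
  post <- sm$stack
  needPre <- sm$report$S$changed &&
    sm$report$S$max_abs_change > 1e-12 && !is.na(zdiffThr)
  baseFit <- fitModel(post, spec)
  baseFitPre <- if (needPre) fitModel(stack, spec) else NULL
  rows <- if (is.null(snps)) seq_len(nrow(panel@Z)) else
    match(snps, panel@snps$rsid)
  if (anyNA(rows)) inputError("requested SNPs missing from the panel")
  facs <- spec@factors
  out <- vector("list", length(rows))
  preZ <- matrix(NA_real_, length(rows), length(facs),
                 dimnames = list(panel@snps$rsid[rows], facs))
  postZ <- preZ
  scPost <- .snpContexts(spec, post, panel@N)
  scPre <- if (needPre) .snpContexts(spec, stack, panel@N) else NULL
  basePar <- baseFit@estimates$est
  baseParPre <- if (needPre) baseFitPre@estimates$est else NULL
  cvScale <- 1 / sqrt(panel@N[post@labels])
  for (ii in seq_along(rows)) {
    j <- rows[ii]
    z <- panel@Z[j, ]; names(z) <- panel@traits
    miss <- !is.finite(z)
    if (any(miss)) {
      message(sprintf("runLatentGwas: skipping %s (missing traits: %s)",
                      panel@snps$rsid[j],
                      paste(panel@traits[miss], collapse = ",")))
      next
    }
    snpCov <- z[post@labels] * cvScale
    res <- .snpFitBoth(spec, scPost, snpCov, basePar = basePar)
    eff <- res$effect; q <- res$q
    postZ[ii, ] <- eff$z
    if (needPre) {
      effPre <- .snpFitBoth(spec, scPre, snpCov, basePar = baseParPre,
                            effectOnly = TRUE)$effect
      preZ[ii, ] <- effPre$z
    } else preZ[ii, ] <- eff$z
    out[[ii]] <- data.frame(rsid = panel@snps$rsid[j], factor = facs,
                            beta = eff$beta, se = eff$se, z = eff$z,
                            p = eff$p, qsnp_chi2 = q$chi2, qsnp_df = q$df,
                            qsnp_p = q$p, converged = eff$converged)
  }
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  zd <- zdiffFilter(preZ[keep, , drop = FALSE], postZ[keep, , drop = FALSE],
                    threshold = if (is.na(zdiffThr)) Inf else zdiffThr)
  zdRemoved <- rownames(preZ)[keep][zd$removed]
  res$zdiff_removed <- res$rsid %in% zdRemoved
  res$qsnp_removed <- if (is.na(qsnpAlpha)) FALSE else res$qsnp_p < qsnpAlpha
  nIn <- length(which(keep))
  removedSnps <- unique(res$rsid[res$zdiff_removed | res$qsnp_removed])
  qOnly <- unique(res$rsid[res$qsnp_removed & !res$rsid %in% zdRemoved])
  report <- list(
    n_input = nIn,
    n_skipped = sum(!keep),
    n_zdiff_removed = length(zdRemoved),
    n_qsnp_removed = length(qOnly),
    n_output = nIn - length(removedSnps),
    zdiff_threshold = zdiffThr,
    qsnp_alpha = qsnpAlpha,
    smoothing = sm$report)
  methods::new("LatentGwasResult", results = res, factors = facs,
               report = report)
}

#' Factor summary-statistics tables from a latent GWAS
#'
#' Converts a \code{\link{LatentGwasResult}} into one canonical-dialect
#' table per factor, dropping filtered SNPs. The per-SNP sample size is the
#' chi-square-implied effective N (1/se^2 on the standardized scale, the
#' value that makes z^2 = n * beta^2).
#'
#' @param gwas a \code{\link{LatentGwasResult}}.
#' @param panel the \code{\link{AlignedPanel}} that produced it (for SNP
#'   coordinates and alleles).
#' @return named list of \code{data.frame}s (one per factor) with canonical
#'   lowercase columns plus \code{factor}, \code{qsnp_chi2}, \code{qsnp_df},
#'   \code{qsnp_p}; write with \code{\link{writeSumstats}}.
#' @export
factorSumstats <- function(gwas, panel) {
  res <- gwas@results
  res <- res[!res$zdiff_removed & !res$qsnp_removed, , drop = FALSE]
  snps <- panel@snps
  lapply(stats::setNames(gwas@factors, gwas@factors), function(f) {
    d <- res[res$factor == f, , drop = FALSE]
    i <- match(d$rsid, snps$rsid)
    data.frame(rsid = d$rsid, chrom = snps$chrom[i], pos = snps$pos[i],
               a1 = snps$a1[i], a2 = snps$a2[i], z = d$z,
               n = round(1 / d$se^2), p = d$p, beta = d$beta, se = d$se,
               factor = f, qsnp_chi2 = d$qsnp_chi2, qsnp_df = d$qsnp_df,
               qsnp_p = d$qsnp_p)
  })
}
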