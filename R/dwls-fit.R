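# Diagonally weighted least squares estimation of genomic confirmatory
# factor models on a covariance stack (S, V).
#
# Estimation: theta-hat minimizes (s - sigma(theta))' D^-1 (s - sigma(theta))
# with D = diag(V) (DWLS); standard errors use the full-V sandwich
#   (D'WD)^-1 D'W V W D (D'WD)^-1,  W = D^-1,  D = d(sigma)/d(theta).
# Model chi-square: the residual-based quadratic form
#   T = r' [V^-1 - V^-1 Delta (Delta' V^-1 Delta)^-1 Delta' V^-1] r
# which has expectation df for a correctly specified model under any
# consistent estimator; it is exercised through identities (AIC = T + 2k,
# df + k = number of moments) and calibration, not against external values.
# The optimizer is damped Gauss-Newton (Levenberg-Marquardt) on the weighted
# residual system with analytic Jacobian, with 5 seeded jittered restarts on
# nonconvergence.

.assembleModel <- function(spec, labels, snp = c("none", "factor", "indicator")) {
  snp <- match.arg(snp)
  t <- length(labels)
  if (!setequal(spec@indicators, labels))
    modelError("model '%s' indicators do not match stack labels", spec@name)
  facs <- spec@factors
  f <- length(facs)
  L <- matrix(0, t, f, dimnames = list(labels, facs))
  Lfree <- matrix(FALSE, t, f)
  for (r in seq_len(nrow(spec@loadings))) {
    ld <- spec@loadings[r, ]
    i <- match(ld$indicator, labels); j <- match(ld$factor, facs)
    if (ld$free) Lfree[i, j] <- TRUE else L[i, j] <- ld$value
  }
  Psi <- diag(1, f); Pfree <- matrix(FALSE, f, f)
  for (r in seq_len(nrow(spec@psi))) {
    ps <- spec@psi[r, ]
    i <- match(ps$f1, facs); j <- match(ps$f2, facs)
    if (ps$free) Pfree[i, j] <- Pfree[j, i] <- TRUE
    else Psi[i, j] <- Psi[j, i] <- ps$value
  }
  Theta <- matrix(0, t, t); Tfree <- matrix(FALSE, t, t)
  for (r in seq_len(nrow(spec@theta))) {
    th <- spec@theta[r, ]
    i <- match(th$t1, labels); j <- match(th$t2, labels)
    if (is.na(i) || is.na(j))
      modelError("residual term on unknown indicator in '%s'", spec@name)
    if (th$free) Tfree[i, j] <- Tfree[j, i] <- TRUE
    else Theta[i, j] <- Theta[j, i] <- th$value
  }
  lamIdx <- which(Lfree, arr.ind = TRUE)
  psiIdx <- which(Pfree & lower.tri(Pfree), arr.ind = TRUE)
  thIdx <- which(Tfree & lower.tri(Tfree, diag = TRUE), arr.ind = TRUE)
  nSnp <- switch(snp, none = 0L, factor = f, indicator = t)
  parLabels <- c(
    sprintf("%s=~%s", facs[lamIdx[, 2]], labels[lamIdx[, 1]]),
    sprintf("%s~~%s", facs[psiIdx[, 2]], facs[psiIdx[, 1]]),
    sprintf("%s~~%s", labels[thIdx[, 2]], labels[thIdx[, 1]]),
    switch(snp, none = character(),
           factor = sprintf("%s~SNP", facs),
           indicator = sprintf("%s~SNP", labels)))
  lowIdx <- which(lower.tri(matrix(0, t, t), diag = TRUE))
  vi <- vechIndices(t)
  list(t = t, f = f, labels = labels, factors = facs, snp = snp,
       L = L, lamIdx = lamIdx, Psi = Psi, psiIdx = psiIdx,
       Theta = Theta, thIdx = thIdx, nSnp = nSnp,
       nLam = nrow(lamIdx), nPsi = nrow(psiIdx), nTh = nrow(thIdx),
       k = nrow(lamIdx) + nrow(psiIdx) + nrow(thIdx) + nSnp,
       parLabels = parLabels, lowIdx = lowIdx,
       ia = vi[, 1], ib = vi[, 2],   # row/col of each vech moment
       nMoments = t * (t + 1) / 2 + switch(snp, none = 0L, t))
}

.unpack <- function(ctx, par) {
  L <- ctx$L; Psi <- ctx$Psi; Theta <- ctx$Theta
  o <- 0L
  if (ctx$nLam) L[ctx$lamIdx] <- par[o + seq_len(ctx$nLam)]
  o <- o + ctx$nLam
  if (ctx$nPsi) for (r in seq_len(ctx$nPsi)) {
    i <- ctx$psiIdx[r, 1]; j <- ctx$psiIdx[r, 2]
    Psi[i, j] <- Psi[j, i] <- par[o + r]
  }
  o <- o + ctx$nPsi
  if (ctx$nTh) for (r in seq_len(ctx$nTh)) {
    i <- ctx$thIdx[r, 1]; j <- ctx$thIdx[r, 2]
    Theta[i, j] <- Theta[j, i] <- par[o + r]
  }
  o <- o + ctx$nTh
  b <- if (ctx$nSnp) par[o + seq_len(ctx$nSnp)] else numeric()
  list(L = L, Psi = Psi, Theta = Theta, b = b)
}

.sigmaVec <- function(ctx, par, m = .unpack(ctx, par)) {
  if (ctx$snp == "factor") {
    C <- m$Psi + tcrossprod(m$b)
    Syy <- m$L %*% C %*% t(m$L) + m$Theta
    c(Syy[ctx$lowIdx], drop(m$L %*% m$b))
  } else if (ctx$snp == "indicator") {
    Syy <- m$L %*% m$Psi %*% t(m$L) + m$Theta
    c(Syy[ctx$lowIdx], m$b)
  } else {
    Syy <- m$L %*% m$Psi %*% t(m$L) + m$Theta
    Syy[ctx$lowIdx]
  }
}

.deltaMat <- function(ctx, par, m = .unpack(ctx, par)) {
  t <- ctx$t
  ia <- ctx$ia; ib <- ctx$ib
  C <- if (ctx$snp == "factor") m$Psi + tcrossprod(m$b) else m$Psi
  Lb <- if (ctx$snp == "factor") drop(m$L %*% m$b) else NULL
  nyg <- if (ctx$snp == "none") 0L else t
  nlow <- length(ctx$lowIdx)
  J <- matrix(0, nlow + nyg, ctx$k)
  col <- 0L
  for (r in seq_len(ctx$nLam)) {
    col <- col + 1L
    i <- ctx$lamIdx[r, 1]; j <- ctx$lamIdx[r, 2]
    u <- drop(m$L %*% C[, j])
    J[seq_len(nlow), col] <- u[ib] * (ia == i) + u[ia] * (ib == i)
    if (ctx$snp == "factor") J[nlow + i, col] <- m$b[j]
  }
  for (r in seq_len(ctx$nPsi)) {
    col <- col + 1L
    i <- ctx$psiIdx[r, 1]; j <- ctx$psiIdx[r, 2]
    J[seq_len(nlow), col] <- m$L[ia, i] * m$L[ib, j] + m$L[ia, j] * m$L[ib, i]
  }
  for (r in seq_len(ctx$nTh)) {
    col <- col + 1L
    i <- ctx$thIdx[r, 1]; j <- ctx$thIdx[r, 2]
    J[seq_len(nlow), col] <- if (i == j) as.numeric(ia == i & ib == i)
      else as.numeric((ia == i & ib == j) | (ia == j & ib == i))
  }
  if (ctx$snp == "factor") {
    for (kk in seq_len(ctx$f)) {
      col <- col + 1L
      J[seq_len(nlow), col] <- m$L[ia, kk] * Lb[ib] + Lb[ia] * m$L[ib, kk]
      J[nlow + seq_len(t), col] <- m$L[, kk]
    }
  } else if (ctx$snp == "indicator") {
    J[cbind(nlow + seq_len(t), col + seq_len(t))] <- 1
  }
  J
}

.startValues <- function(ctx, S) {
  d <- pmax(diag(S), 1e-6)
  start <- numeric(ctx$k)
  o <- 0L
  if (ctx$nLam)
    start[o + seq_len(ctx$nLam)] <- 0.5 * sqrt(d[ctx$lamIdx[, 1]])
  o <- o + ctx$nLam
  if (ctx$nPsi) start[o + seq_len(ctx$nPsi)] <- 0.2
  o <- o + ctx$nPsi
  if (ctx$nTh) {
    diagTh <- ctx$thIdx[, 1] == ctx$thIdx[, 2]
    start[o + which(diagTh)] <- 0.5 * d[ctx$thIdx[diagTh, 1]]
  }
  start
}

.lmOptim <- function(ctx, s, w, start, maxit = 500) {
  par <- start
  r <- s - .sigmaVec(ctx, par)
  fval <- sum(w * r^2)
  mu <- 1e-3
  converged <- FALSE
  lastRel <- Inf
  # predicted objective decrease restricted to the identified (non-flat)
  # parameter subspace; the criterion ignores ridge directions along which
  # the implied moments (hence the fit) do not change
  predDecrease <- function(A, g) {
    eg <- eigen(A, symmetric = TRUE)
    keep <- eg$values > 1e-7 * max(eg$values, .Machine$double.eps)
    gu <- drop(crossprod(eg$vectors[, keep, drop = FALSE], g))
    sum(gu^2 / eg$values[keep])
  }
  for (it in seq_len(maxit)) {
    mm <- .unpack(ctx, par)
    J <- .deltaMat(ctx, par, mm)
    g <- drop(crossprod(J, w * r))
    A <- crossprod(J * sqrt(w))
    if (max(abs(g)) < 1e-9 * (1 + abs(fval)) ||
        (it > 3 && predDecrease(A, g) < 1e-9 * (1 + abs(fval)))) {
      converged <- TRUE; break
    }
    improved <- FALSE
    for (tries in 1:40) {
      M <- A + mu * diag(pmax(diag(A), 1e-10), ctx$k)
      step <- tryCatch(solve(M, g), error = function(e) NULL)
      if (!is.null(step)) {
        newpar <- par + step
        nr <- s - .sigmaVec(ctx, newpar)
        nf <- sum(w * nr^2)
        if (is.finite(nf) && nf <= fval + 1e-14) {
          rel <- (fval - nf) / max(fval, 1e-12)
          par <- newpar; r <- nr; fval <- nf
          mu <- max(mu / 3, 1e-12)
          improved <- TRUE
          lastRel <- rel
          if (rel < 1e-13 && max(abs(step)) < 1e-10) converged <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e14) break
    }
    if (!improved || converged) {
      # a stall after only negligible recent progress is a numerical
      # minimum (ill-conditioned flat valleys stop the line search before
      # the raw gradient test is met)
      if (!improved)
        converged <- lastRel < 1e-8 ||
          predDecrease(A, g) < 1e-6 * (1 + abs(fval))
      break
    }
  }
  if (!converged) {
    J <- .deltaMat(ctx, par)
    g <- drop(crossprod(J, w * r))
    converged <- max(abs(g)) < 1e-6 * (1 + abs(fval))
  }
  list(par = par, fval = fval, converged = converged)
}

.fitEngine <- function(ctx, s, Vdiag, start = NULL, S = NULL, seedTag = "fit",
                       maxStarts = 5) {
  if (ctx$k > ctx$nMoments)
    modelError("model not identified: %d free parameters > %d moments",
               ctx$k, ctx$nMoments)
  w <- 1 / pmax(Vdiag, .Machine$double.eps)
  if (is.null(start)) start <- .startValues(ctx, S)
  best <- .lmOptim(ctx, s, w, start)
  attempt <- 0L
  while (!best$converged && attempt < maxStarts) {
    attempt <- attempt + 1L
    jit <- withSeed(childSeed(sum(utf8ToInt(seedTag)), paste0("start", attempt)),
                    start * (1 + 0.3 * stats::rnorm(length(start))) +
                      0.05 * stats::rnorm(length(start)))
    cand <- .lmOptim(ctx, s, w, jit)
    if (cand$converged || cand$fval < best$fval) best <- cand
  }
  best
}

# symmetric pseudo-inverse: two-indicator orthogonal specific factors leave
# the information matrix rank-deficient (empirical under-identification);
# the implied moments are unique along the flat direction, so fit statistics
# remain well-defined when the projection uses the achieved rank.
.pinvSym <- function(A, tol = 1e-10) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(abs(eg$values), .Machine$double.eps)
  if (all(keep)) return(eg$vectors %*% ((1 / eg$values) * t(eg$vectors)))
  eg$vectors[, keep, drop = FALSE] %*%
    ((1 / eg$values[keep]) * t(eg$vectors[, keep, drop = FALSE]))
}

# residual-based model chi-square with full V
.browneChisq <- function(r, V, J, df) {
  if (df <= 0) return(0)
  n <- length(r)
  Vi <- tryCatch(solve(V),
                 error = function(e) solve(V + diag(mean(diag(V)) * 1e-8, n)))
  u <- drop(Vi %*% r)
  if (ncol(J) == 0) return(max(drop(crossprod(r, u)), 0))
  Ju <- drop(crossprod(J, u))
  A <- crossprod(J, Vi %*% J)
  T <- drop(crossprod(r, u)) - drop(crossprod(Ju, .pinvSym(A) %*% Ju))
  max(T, 0)
}

.sandwichSE <- function(J, w, V) {
  A <- crossprod(J * sqrt(w))
  Ainv <- .pinvSym(A)
  WJ <- J * w
  B <- Ainv %*% crossprod(WJ, V %*% WJ) %*% Ainv
  sqrt(pmax(diag(B), 0))
}

#' Subset a covariance stack
#'
#' Restricts S and V (with the matching vech elements) to a subset of
#' traits, e.g. after indicator screening.
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @param labels traits to keep, in the desired order.
#' @return a \code{\link{CovarianceStack}}.
#' @export
subsetStack <- function(stack, labels) {
  sel <- match(labels, stack@labels)
  if (anyNA(sel)) inputError("unknown trait(s) in subsetStack")
  tFull <- length(stack@labels)
  pos <- matrix(0L, tFull, tFull)
  idx <- vechIndices(tFull)
  pos[cbind(idx[, 1], idx[, 2])] <- seq_len(nrow(idx))
  pos <- pos + t(pos); diag(pos) <- diag(pos) / 2
  newIdx <- vechIndices(length(sel))
  vsel <- pos[cbind(sel[newIdx[, 1]], sel[newIdx[, 2]])]
  CovarianceStack(labels, stack@S[sel, sel, drop = FALSE],
                  stack@V[vsel, vsel, drop = FALSE],
                  nBlocks = stack@nBlocks,
                  intercepts = stack@intercepts[sel, sel, drop = FALSE],
                  h2z = stack@h2z[sel])
}

#' Independence (baseline) model fit
#'
#' Fits the model with all covariances fixed to 0 and free variances — the
#' baseline for the comparative fit index. The DWLS solution is closed form
#' (each variance reproduces its own moment).
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @return a \code{\link{FitResult}}.
#' @export
independenceFit <- function(stack) {
  t <- length(stack@labels)
  nv <- t * (t + 1) / 2
  idx <- vechIndices(t)
  s <- vech(stack@S)
  sig <- ifelse(idx[, 1] == idx[, 2], s, 0)
  J <- matrix(0, nv, t)
  J[cbind(which(idx[, 1] == idx[, 2]), seq_len(t))] <- 1
  r <- s - sig
  chisq <- .browneChisq(r, stack@V, J, nv - t)
  est <- data.frame(matrix = "theta", row = stack@labels, col = stack@labels,
                    label = sprintf("%s~~%s", stack@labels, stack@labels),
                    est = s[idx[, 1] == idx[, 2]],
                    se = NA_real_, z = NA_real_, free = TRUE)
  methods::new("FitResult", modelName = "independence",
               labels = stack@labels, estimates = est, chisq = chisq,
               df = nv - t, p = stats::pchisq(chisq, nv - t, lower.tail = FALSE),
               cfi = NA_real_, srmr = NA_real_, aic = chisq + 2 * t,
               k = t, nMoments = nv, implied = diag(diag(stack@S), t),
               converged = TRUE, heywood = character())
}

#' Fit a confirmatory factor model by DWLS
#'
#' Estimates the model on a covariance stack by diagonally weighted least
#' squares (weights: inverse diagonal of V) with full-V sandwich standard
#' errors, and computes the residual-based model chi-square, CFI against the
#' independence baseline, SRMR (root mean square standardized residual over
#' the lower triangle including the diagonal) and AIC = chi-square + 2k.
#' Negative residual variance estimates are flagged as Heywood cases, never
#' constrained; nonconvergence (after 5 jittered restarts) is reported in
#' the result, never silently accepted.
#'
#' @param stack a \code{\link{CovarianceStack}} (PSD after smoothing; traits
#'   beyond the model's indicators are dropped automatically).
#' @param spec a \code{\link{ModelSpec}}.
#' @param start optional start values (parameter order of the result table).
#' @return a \code{\link{FitResult}}.
#' @export
fitModel <- function(stack, spec, start = NULL) {
  if (!setequal(spec@indicators, stack@labels))
    stack <- subsetStack(stack, intersect(spec@indicators, stack@labels))
  stack <- subsetStack(stack, spec@indicators)   # model order
  ctx <- .assembleModel(spec, stack@labels)
  s <- vech(stack@S)
  Vdiag <- diag(stack@V)
  fit <- .fitEngine(ctx, s, Vdiag, start = start, S = stack@S,
                    seedTag = spec@name)
  J <- .deltaMat(ctx, fit$par)
  w <- 1 / pmax(Vdiag, .Machine$double.eps)
  se <- .sandwichSE(J, w, stack@V)
  r <- s - .sigmaVec(ctx, fit$par)
  df <- ctx$nMoments - ctx$k
  chisq <- .browneChisq(r, stack@V, J, df)
  base <- independenceFit(stack)
  cfi <- .cfi(chisq, df, base@chisq, base@df)
  m <- .unpack(ctx, fit$par)
  implied <- m$L %*% m$Psi %*% t(m$L) + m$Theta
  dimnames(implied) <- list(stack@labels, stack@labels)
  dd <- diag(stack@S)
  stdres <- (stack@S - implied) / sqrt(outer(dd, dd))
  srmr <- sqrt(mean(stdres[lower.tri(stdres, diag = TRUE)]^2))
  # Heywood cases: negative estimates among the free residual variances
  diagFree <- ctx$thIdx[, 1] == ctx$thIdx[, 2]
  hw <- ctx$thIdx[diagFree, 1][
    fit$par[ctx$nLam + ctx$nPsi + which(diagFree)] < 0]
  heywood <- stack@labels[hw]
  est <- data.frame(label = ctx$parLabels, est = fit$par, se = se,
                    z = fit$par / se, free = TRUE)
  methods::new("FitResult", modelName = spec@name, labels = stack@labels,
               estimates = est, chisq = chisq, df = df,
               p = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1,
               cfi = cfi, srmr = srmr, aic = chisq + 2 * ctx$k, k = ctx$k,
               nMoments = ctx$nMoments, implied = implied,
               converged = fit$converged, heywood = heywood)
}

.cfi <- function(chisq, df, chisqB, dfB) {
  num <- max(chisq - df, 0)
  den <- max(chisqB - dfB, chisq - df, 0)
  if (den <= 0) return(1)
  min(max(1 - num / den, 0), 1)
}

#' Fit indices from a fitted model and its baseline
#'
#' AIC = chi-square + 2k; CFI = 1 - max(chisq_m - df_m, 0) /
#' max(chisq_b - df_b, chisq_m - df_m, 0), bounded to [0, 1]; SRMR as stored
#' on the fit. The baseline must be the independence fit of the same stack.
#'
#' @param fit a \code{\link{FitResult}}.
#' @param baseline \code{\link{independenceFit}} of the same stack.
#' @return list \code{(chisq, df, p, cfi, srmr, aic)}.
#' @export
fitIndices <- function(fit, baseline) {
  if (!identical(fit@labels, baseline@labels))
    inputError("baseline was fitted on a different stack")
  list(chisq = fit@chisq, df = fit@df, p = fit@p,
       cfi = .cfi(fit@chisq, fit@df, baseline@chisq, baseline@df),
       srmr = fit@srmr, aic = fit@chisq + 2 * fit@k)
}

#' Classify model fit
#'
#' Absolute fit thresholds: CFI >= 0.95 good, >= 0.90 acceptable; SRMR
#' < 0.05 good, < 0.10 acceptable. The joint label is the weaker of the two.
#'
#' @param cfi,srmr fit indices.
#' @return \code{"good"}, \code{"acceptable"} or \code{"poor"}.
#' @export
classifyFit <- function(cfi, srmr) {
  lab <- function(x) c("good", "acceptable", "poor")[x]
  cl <- lab(if (cfi >= 0.95) 1L else if (cfi >= 0.90) 2L else 3L)
  sl <- lab(if (srmr < 0.05) 1L else if (srmr < 0.10) 2L else 3L)
  c("good", "acceptable", "poor")[max(match(cl, c("good", "acceptable", "poor")),
                                      match(sl, c("good", "acceptable", "poor")))]
}

#' Compare fitted models
#'
#' Tabulates chi-square, df, AIC, CFI, SRMR and fit label for a set of fits
#' on the same stack, flags the minimum-AIC model (ties reported), and
#' reports the chi-square and df differences relative to the best model.
#'
#' @param fits named list of \code{\link{FitResult}} objects.
#' @return \code{data.frame}, one row per model, ordered as supplied, with
#'   attribute \code{"tie"} (logical).
#' @export
compareModels <- function(fits) {
  if (!length(fits)) inputError("no fits supplied")
  labs0 <- fits[[1]]@labels
  for (f in fits) if (!setequal(f@labels, labs0))
    inputError("fits are not on the same stack")
  nm <- names(fits) %||% vapply(fits, function(f) f@modelName, "")
  tab <- data.frame(
    model = nm,
    chisq = vapply(fits, function(f) f@chisq, 0),
    df = vapply(fits, function(f) f@df, 0),
    p = vapply(fits, function(f) f@p, 0),
    k = vapply(fits, function(f) f@k, 0),
    aic = vapply(fits, function(f) f@aic, 0),
    cfi = vapply(fits, function(f) f@cfi, 0),
    srmr = vapply(fits, function(f) f@srmr, 0),
    converged = vapply(fits, function(f) f@converged, TRUE))
  tab$fit_label <- mapply(classifyFit, tab$cfi, tab$srmr)
  best <- min(tab$aic)
  tab$delta_aic <- tab$aic - best
  tab$best <- tab$aic <= best + 1e-9
  bi <- which(tab$best)[1]
  tab$delta_chisq <- tab$chisq - tab$chisq[bi]
  tab$delta_df <- tab$df - tab$df[bi]
  attr(tab, "tie") <- sum(tab$best) > 1
  rownames(tab) <- NULL
  tab
}
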