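#' @import methods
NULL

#' Per-trait GWAS summary statistics
#'
#' A \code{SumStats} object holds the association records of one GWAS:
#' one row per SNP with rsID, genomic coordinates, effect (\code{a1}) and
#' other (\code{a2}) allele, a signed Z statistic on the \code{a1}-count
#' scale, the per-SNP sample size and the association p-value (plus an
#' optional effect-allele frequency \code{maf}).
#'
#' @slot trait single trait label.
#' @slot data \code{data.frame} with columns \code{rsid}, \code{chrom},
#'   \code{pos}, \code{a1}, \code{a2}, \code{z}, \code{n}, \code{p} and
#'   optionally \code{maf}.
#'
#' @examples
#' ss <- SumStats("demo", data.frame(
#'   rsid = "rs1", chrom = "1", pos = 1000L, a1 = "A", a2 = "G",
#'   z = 1.5, n = 10000, p = 2 * pnorm(-1.5)))
#' traitLabel(ss)
#' @export
setClass("SumStats", slots = c(trait = "character", data = "data.frame"))

setValidity("SumStats", function(object) {
  d <- object@data
  need <- c("rsid", "a1", "a2", "z", "n", "p")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$rsid)) return("rsids must be unique within a table")
  if (nrow(d)) {
    if (!all(is.finite(d$z))) return("z must be finite")
    if (!all(d$n >= 1)) return("n must be >= 1")
    if (!all(d$p > 0 & d$p <= 1)) return("p must lie in (0, 1]")
    if (any(d$a1 == d$a2)) return("a1 must differ from a2")
  }
  TRUE
})

#' @param trait trait label.
#' @param data summary-statistic \code{data.frame} (see slots).
#' @rdname SumStats-class
#' @export
SumStats <- function(trait, data) {
  if (!"chrom" %in% names(data)) data$chrom <- NA_character_
  if (!"pos" %in% names(data)) data$pos <- NA_integer_
  data$a1 <- toupper(as.character(data$a1))
  data$a2 <- toupper(as.character(data$a2))
  data$rsid <- as.character(data$rsid)
  methods::new("SumStats", trait = trait, data = as.data.frame(data))
}

#' Multi-trait SNP panel aligned to a common allele orientation
#'
#' The row-matched input to LD-score regression and the per-SNP latent GWAS
#' loop: the SNP intersection of several cohort tables, a Z matrix with one
#' column per trait, and per-trait sample sizes. All alleles are harmonized
#' to a single shared orientation.
#'
#' @slot snps \code{data.frame} with \code{rsid}, \code{chrom}, \code{pos},
#'   \code{a1}, \code{a2} (shared orientation).
#' @slot Z numeric matrix, SNPs x traits.
#' @slot N named per-trait sample sizes.
#' @slot traits trait labels (column order of \code{Z}).
#' @export
setClass("AlignedPanel", slots = c(
  snps = "data.frame", Z = "matrix", N = "numeric", traits = "character"))

setValidity("AlignedPanel", function(object) {
  if (nrow(object@Z) != nrow(object@snps)) return("Z and snps row mismatch")
  if (ncol(object@Z) != length(object@traits)) return("Z column / trait mismatch")
  if (length(object@N) != length(object@traits)) return("N / trait mismatch")
  TRUE
})

#' Genetic covariance matrix with jackknife sampling covariance
#'
#' Holds the LDSC genetic covariance matrix \code{S} across traits together
#' with the sampling covariance \code{V} of the half-vectorized elements of
#' \code{S} (column-major lower triangle including the diagonal), the LDSC
#' intercept matrix, and the univariate heritability Z statistics used for
#' indicator screening.
#'
#' @slot labels trait labels.
#' @slot S genetic covariance (or, after \code{\link{standardizeStack}},
#'   correlation) matrix.
#' @slot V sampling covariance of \code{vech(S)}, dimension t(t+1)/2.
#' @slot nBlocks jackknife block count (0 for fixture/surrogate stacks).
#' @slot intercepts LDSC intercept matrix (diagonal: univariate intercepts;
#'   off-diagonal: sample-overlap intercepts).
#' @slot h2z univariate heritability Z statistics (h2 / jackknife SE),
#'   preserved across standardization so screening remains possible.
#' @export
setClass("CovarianceStack", slots = c(
  labels = "character", S = "matrix", V = "matrix", nBlocks = "integer",
  intercepts = "matrix", h2z = "numeric"))

setValidity("CovarianceStack", function(object) {
  t <- length(object@labels)
  if (!all(dim(object@S) == c(t, t))) return("S dimension mismatch")
  if (max(abs(object@S - t(object@S))) > 1e-8 * max(1, max(abs(object@S))))
    return("S must be symmetric")
  if (!all(dim(object@V) == rep(t * (t + 1) / 2, 2)))
    return("V must be t(t+1)/2 square")
  if (any(diag(object@V) <= 0)) return("diag(V) must be positive")
  TRUE
})

CovarianceStack <- function(labels, S, V, nBlocks = 0L,
                            intercepts = NULL, h2z = NULL) {
  t <- length(labels)
  dimnames(S) <- list(labels, labels)
  vl <- vechLabels(labels)
  dimnames(V) <- list(vl, vl)
  if (is.null(intercepts)) intercepts <- diag(1, t)
  dimnames(intercepts) <- list(labels, labels)
  if (is.null(h2z)) {
    ii <- match(paste(labels, labels, sep = ":"), vl)
    h2z <- diag(S) / sqrt(diag(V)[ii])
  }
  names(h2z) <- labels
  methods::new("CovarianceStack", labels = labels, S = S, V = V,
               nBlocks = as.integer(nBlocks), intercepts = intercepts,
               h2z = h2z)
}

#' Confirmatory factor model specification
#'
#' A genomic CFA structure: which indicator loads on which factor (free or
#' fixed values), which factor covariances are free (all factor variances
#' are fixed to 1 for identification), and the residual structure including
#' fixed residual variances and correlated residual pairs. Constructed from
#' a compact lavaan-like model string by \code{\link{modelSpec}}.
#'
#' @slot name model label.
#' @slot indicators indicator (trait) labels in model order.
#' @slot factors factor labels.
#' @slot loadings \code{data.frame(indicator, factor, free, value)}.
#' @slot psi \code{data.frame(f1, f2, free, value)} factor (co)variances.
#' @slot theta \code{data.frame(t1, t2, free, value)} residual (co)variances.
#' @export
setClass("ModelSpec", slots = c(
  name = "character", indicators = "character", factors = "character",
  loadings = "data.frame", psi = "data.frame", theta = "data.frame"))

setValidity("ModelSpec", function(object) {
  if (!all(object@loadings$indicator %in% object@indicators))
    return("loading on unknown indicator")
  if (!all(object@loadings$factor %in% object@factors))
    return("loading on unknown factor")
  orphan <- setdiff(object@indicators, object@loadings$indicator)
  if (length(orphan))
    return(paste("indicator loads on no factor:", paste(orphan, collapse = ", ")))
  fixed <- c(object@loadings$value[!object@loadings$free],
             object@psi$value[!object@psi$free],
             object@theta$value[!object@theta$free])
  if (length(fixed) && !all(is.finite(fixed))) return("fixed values must be finite")
  TRUE
})

#' Fitted genomic CFA
#'
#' Result of a diagonally-weighted-least-squares fit: parameter estimates
#' with sandwich standard errors, the residual-based model chi-square and
#' derived fit statistics (CFI, SRMR, AIC = chi-square + 2k), convergence
#' and Heywood diagnostics.
#'
#' @slot modelName model label.
#' @slot labels indicator labels in stack order.
#' @slot estimates \code{data.frame(matrix, row, col, label, est, se, z, free)}.
#' @slot chisq,df,p model chi-square, degrees of freedom, p-value.
#' @slot cfi,srmr,aic fit indices.
#' @slot k free-parameter count; \code{nMoments} number of fitted moments.
#' @slot implied model-implied covariance matrix.
#' @slot converged logical; \code{heywood} labels of negative residual
#'   variances (flagged, never constrained).
#' @export
setClass("FitResult", slots = c(
  modelName = "character", labels = "character", estimates = "data.frame",
  chisq = "numeric", df = "numeric", p = "numeric", cfi = "numeric",
  srmr = "numeric", aic = "numeric", k = "numeric", nMoments = "numeric",
  implied = "matrix", converged = "logical", heywood = "character"))

#' Latent-factor GWAS results
#'
#' Per-SNP effects on each latent factor with Q-SNP heterogeneity statistics
#' and the QC filter flags (pre/post-smoothing Z-difference, Q-SNP), plus a
#' reconciliation report of removal counts.
#'
#' @slot results long \code{data.frame}: one row per SNP x factor with
#'   \code{rsid, factor, beta, se, z, p, qsnp_chi2, qsnp_df, qsnp_p,
#'   zdiff_removed, qsnp_removed}.
#' @slot factors factor labels carrying SNP effects.
#' @slot report list of counts and thresholds used.
#' @export
setClass("LatentGwasResult", slots = c(
  results = "data.frame", factors = "character", report = "list"))
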