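#' @rdname SumStats-class
#' @export
setMethod("traitLabel", "SumStats", function(x) x@trait)

#' @rdname SumStats-class
#' @export
setMethod("ssData", "SumStats", function(x) x@data)

#' @rdname SumStats-class
#' @export
setMethod("length", "SumStats", function(x) nrow(x@data))

#' @rdname CovarianceStack-class
#' @export
setMethod("gcov", "CovarianceStack", function(x) x@S)

#' @rdname CovarianceStack-class
#' @export
setMethod("sampCov", "CovarianceStack", function(x) x@V)

#' @rdname CovarianceStack-class
#' @export
setMethod("stackLabels", "CovarianceStack", function(x) x@labels)

#' @rdname CovarianceStack-class
#' @export
setMethod("ldscIntercepts", "CovarianceStack", function(x) x@intercepts)

#' @rdname CovarianceStack-class
#' @export
setMethod("h2Z", "CovarianceStack", function(x) x@h2z)

#' @rdname FitResult-class
#' @export
setMethod("fitEstimates", "FitResult", function(x) x@estimates)

#' @rdname LatentGwasResult-class
#' @export
setMethod("gwasResults", "LatentGwasResult", function(x) x@results)

#' @rdname LatentGwasResult-class
#' @export
setMethod("gwasReport", "LatentGwasResult", function(x) x@report)

setMethod("show", "SumStats", function(object) {
  cat(sprintf("SumStats '%s': %d SNPs, median N = %s\n",
              object@trait, nrow(object@data),
              format(stats::median(object@data$n))))
})

setMethod("show", "AlignedPanel", function(object) {
  cat(sprintf("AlignedPanel: %d SNPs x %d traits\n  traits: %s\n",
              nrow(object@Z), length(object@traits),
              paste(object@traits, collapse = ", ")))
})

setMethod("show", "CovarianceStack", function(object) {
  std <- all(abs(diag(object@S) - 1) < 1e-12)
  cat(sprintf("CovarianceStack: %d traits (%s scale), %d jackknife blocks\n",
              length(object@labels),
              if (std) "correlation" else "covariance", object@nBlocks))
  cat(sprintf("  h2 Z range: %.2f .. %.2f\n",
              min(object@h2z), max(object@h2z)))
})

setMethod("show", "ModelSpec", function(object) {
  k <- countFreeParams(object)
  cat(sprintf("ModelSpec '%s': %d indicators, %d factors, k = %d free parameters\n",
              object@name, length(object@indicators),
              length(object@factors), k))
  for (f in object@factors) {
    l <- object@loadings[object@loadings$factor == f, ]
    cat(sprintf("  %s =~ %s\n", f, paste(l$indicator, collapse = " + ")))
  }
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult '%s': chisq(%d) = %.4f, p = %.3g\n",
              object@modelName, as.integer(object@df), object@chisq, object@p))
  cat(sprintf("  AIC = %.4f, CFI = %.5f, SRMR = %.5f [%s]%s%s\n",
              object@aic, object@cfi, object@srmr,
              classifyFit(object@cfi, object@srmr),
              if (object@converged) "" else "  (NOT CONVERGED)",
              if (length(object@heywood))
                paste0("  Heywood: ", paste(object@heywood, collapse = ", "))
              else ""))
})

setMethod("show", "LatentGwasResult", function(object) {
  r <- object@report
  cat(sprintf("LatentGwasResult: %d SNPs in, %d retained (%d z-diff removed, %d Q-SNP removed)\n",
              r$n_input, r$n_output, r$n_zdiff_removed, r$n_qsnp_removed))
  cat(sprintf("  factors: %s\n", paste(object@factors, collapse = ", ")))
})
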