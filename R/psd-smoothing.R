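# Nearest positive-semidefinite smoothing by eigenvalue clipping, and the
# per-SNP pre/post-smoothing Z-difference filter.

#' Nearest positive-semidefinite matrix by eigenvalue clipping
#'
#' Replaces eigenvalues below \code{floor} by \code{floor} and reconstructs
#' the matrix from the clipped eigendecomposition (the Frobenius-nearest PSD
#' matrix for floor 0). Inputs already satisfying the floor are returned
#' unchanged elementwise. Single-pass and deterministic; adequate at the
#' dimensions of a genetic covariance stack.
#'
#' @param a symmetric matrix.
#' @param floor minimum retained eigenvalue (default 1e-10).
#' @param tol symmetry tolerance relative to \code{max(|a|)}.
#' @return list with \code{mat} (the smoothed matrix) and \code{report}
#'   (\code{pre_min_eig}, \code{post_min_eig}, \code{max_abs_change},
#'   \code{changed}).
#' @export
nearestPSD <- function(a, floor = 1e-10, tol = 1e-8) {
  if (!is.matrix(a) || nrow(a) != ncol(a) ||
      max(abs(a - t(a))) > tol * max(1, max(abs(a))))
    inputError("nearestPSD requires a symmetric square matrix")
  a <- (a + t(a)) / 2
  eg <- eigen(a, symmetric = TRUE)
  preMin <- min(eg$values)
  if (preMin >= floor) {
    report <- list(pre_min_eig = preMin, post_min_eig = preMin,
                   max_abs_change = 0, changed = FALSE)
    return(list(mat = a, report = report))
  }
  vals <- pmax(eg$values, floor)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(a)
  list(mat = out,
       report = list(pre_min_eig = preMin,
                     post_min_eig = min(eigen(out, symmetric = TRUE,
                                              only.values = TRUE)$values),
                     max_abs_change = max(abs(out - a)),
                     changed = TRUE))
}

#' Smooth a covariance stack
#'
#' Applies \code{\link{nearestPSD}} to both S and V of a stack.
#'
#' @param stack a \code{\link{CovarianceStack}}.
#' @param floor minimum retained eigenvalue.
#' @return list with \code{stack} (smoothed) and \code{report} (per-matrix
#'   smoothing reports).
#' @export
smoothStack <- function(stack, floor = 1e-10) {
  sm <- nearestPSD(stack@S, floor)
  vm <- nearestPSD(stack@V, floor)
  out <- CovarianceStack(stack@labels, sm$mat, vm$mat,
                         nBlocks = stack@nBlocks,
                         intercepts = stack@intercepts, h2z = stack@h2z)
  list(stack = out, report = list(S = sm$report, V = vm$report))
}

#' Pre/post-smoothing Z-difference filter
#'
#' Removes SNPs whose latent-factor association Z statistic changes by
#' strictly more than \code{threshold} between the runs under the
#' pre-smoothed and post-smoothed covariance matrices (the published rule is
#' "more than 1", so |dZ| exactly equal to the threshold is retained). With
#' several factors a SNP is removed if any factor's |dZ| exceeds the
#' threshold.
#'
#' @param pre_z,post_z numeric vectors or matrices (SNP x factor) with
#'   identical dimensions and SNP names/order.
#' @param threshold removal threshold on |dZ| (default 1, strict).
#' @return list with \code{retained} (indices), \code{removed} (indices) and
#'   \code{log} (\code{data.frame(snp, max_abs_dz, removed)}).
#' @export
zdiffFilter <- function(pre_z, post_z, threshold = 1) {
  pre <- as.matrix(pre_z); post <- as.matrix(post_z)
  if (!all(dim(pre) == dim(post)) ||
      !identical(rownames(pre), rownames(post)))
    inputError("pre_z and post_z must be indexed identically")
  dz <- abs(pre - post)
  maxdz <- apply(dz, 1, max)
  removed <- maxdz > threshold
  list(retained = which(!removed), removed = which(removed),
       log = data.frame(snp = rownames(pre) %||% seq_along(maxdz),
                        max_abs_dz = unname(maxdz),
                        removed = unname(removed)))
}
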