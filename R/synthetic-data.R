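# Simulation of multi-cohort GWAS summary statistics from a known latent
# genetic factor model, directly at the Z-score level under the LDSC moment
# structure: for SNP j and traits i, k
#   E[z_ij z_kj] = sqrt(N_i N_k) * sigma_g[i,k] * l_j / M + I0[i,k]
# where I0 has unit diagonal and off-diagonal sample-overlap intercepts.
# No individual-level genotypes are simulated; every assumption used by the
# downstream estimators (and nothing more) is encoded here.

#' Simulate LD scores
#'
#' Draws per-SNP LD scores from a named law, always >= 1 and reproducible
#' for a fixed seed.
#'
#' @param m_snps number of SNPs.
#' @param law list with \code{name} in \code{"constant"}, \code{"gamma"},
#'   \code{"uniform"} and its parameters: \code{value} (constant);
#'   \code{mean}, \code{shape} (gamma: \code{l = 1 + Gamma(shape,
#'   scale = (mean-1)/shape)}); \code{min}, \code{max} (uniform).
#' @param seed integer seed.
#' @return \code{data.frame(SNP, L2)}.
#' @export
simulateLdScores <- function(m_snps, law = list(name = "gamma", mean = 30, shape = 3),
                             seed = 1L) {
  if (m_snps < 1) inputError("m_snps must be >= 1")
  l2 <- withSeed(seed, switch(
    law$name,
    constant = rep(max(1, law$value %||% 1), m_snps),
    gamma = {
      mu <- law$mean %||% 30
      if (mu < 1) configError("gamma LD-score law needs mean >= 1")
      shape <- law$shape %||% 3
      1 + stats::rgamma(m_snps, shape = shape, scale = (mu - 1) / shape)
    },
    uniform = stats::runif(m_snps, max(1, law$min %||% 1), law$max %||% 60),
    configError("unknown LD-score law '%s'", law$name)
  ))
  data.frame(SNP = sprintf("rs%07d", seq_len(m_snps)), L2 = l2)
}

#' Default generator configuration
#'
#' The packaged study conditions: nine cohort traits with the published
#' per-study sample sizes, genetic loadings patterned on the accepted
#' bifactor structure (a general executive-function factor over all nine
#' indicators, an orthogonal working-memory factor over Digit Span, Pairs
#' (negative), the ALSPAC working-memory component and NIH G4, an orthogonal
#' substitution factor over the two symbol/digit substitution tests, and a
#' correlated residual between prospective memory and ALSPAC working
#' memory), total SNP heritabilities matching the published diagonal, a
#' shared-sample fraction of 0.9 with phenotypic correlation 0.25 among the
#' five UK Biobank tests, M = 50,000 SNPs and a gamma LD-score law with
#' mean 30.
#'
#' @param m_snps SNP count (default 50,000).
#' @param overlap_frac,overlap_rp UK Biobank shared-sample fraction and
#'   phenotypic correlation for overlapping samples.
#' @return a generator configuration list (see \code{\link{simulateSumstats}}).
#' @export
defaultGeneratorConfig <- function(m_snps = 50000, overlap_frac = 0.9,
                                   overlap_rp = 0.25) {
  labels <- c("UKB_Trails", "UKB_Pairs", "UKB_SDST", "UKB_Digit",
              "UKB_PMemory", "CHARGE_DSST", "CHARGE_Stroop", "ALSPAC_WM",
              "NIH_G4")
  n <- c(93024, 81701, 84125, 81701, 162335, 32070, 12866, 4611, 9879)
  h2 <- c(0.1141, 0.3765, 0.1564, 0.1433, 0.0368, 0.156, 0.1035, 0.279, 0.3436)
  # standardized loadings (correlation metric), converted below to the
  # genetic-covariance metric via the per-trait heritabilities
  std <- matrix(0, 9, 3, dimnames = list(labels, c("EF", "WM", "SUB")))
  std[, "EF"] <- c(0.85, 0.80, 0.70, 0.65, 0.50, 0.65, 0.50, 0.55, 0.65)
  std[c("UKB_Pairs", "UKB_Digit", "ALSPAC_WM", "NIH_G4"), "WM"] <-
    c(-0.25, 0.45, 0.45, 0.35)
  # the accepted structure fixes the CHARGE DSST residual to 0 (empirical
  # under-identification of a two-indicator specific factor), so its
  # loadings explain its variance exactly
  std[c("UKB_SDST", "CHARGE_DSST"), "SUB"] <- c(0.55, sqrt(1 - 0.65^2))
  specStd <- 1 - rowSums(std^2)
  loadings <- std * sqrt(h2)
  specific <- specStd * h2
  residCor <- 0.20   # standardized residual correlation PMemory ~~ ALSPAC
  residCov <- residCor * sqrt(specific["UKB_PMemory"] * specific["ALSPAC_WM"])
  overlap <- diag(1, 9); dimnames(overlap) <- list(labels, labels)
  ukb <- grep("^UKB_", labels)
  overlap[ukb, ukb] <- overlap_frac; diag(overlap) <- 1
  rp <- matrix(0, 9, 9, dimnames = list(labels, labels))
  rp[ukb, ukb] <- overlap_rp; diag(rp) <- 1
  list(
    m_snps = m_snps,
    traits = data.frame(label = labels, n = n, reverse_coded = FALSE),
    loadings = loadings,
    factor_h2 = c(EF = 1, WM = 1, SUB = 1),
    specific_h2 = specific,
    residual_cov = list(list("UKB_PMemory", "ALSPAC_WM", unname(residCov))),
    overlap = overlap,
    overlap_rp = rp,
    ldscore_law = list(name = "gamma", mean = 30, shape = 3),
    seed = 1L)
}

# Generating genetic covariance matrix implied by a config.
.generatorSigmaG <- function(config) {
  L <- as.matrix(config$loadings)
  sg <- L %*% diag(config$factor_h2, ncol(L)) %*% t(L) +
    diag(config$specific_h2, nrow(L))
  dimnames(sg) <- list(config$traits$label, config$traits$label)
  for (rc in config$residual_cov %||% list()) {
    sg[rc[[1]], rc[[2]]] <- sg[rc[[1]], rc[[2]]] + rc[[3]]
    sg[rc[[2]], rc[[1]]] <- sg[rc[[1]], rc[[2]]]
  }
  sg
}

# Cross-trait LDSC intercept matrix implied by the overlap settings.
.generatorIntercepts <- function(config) {
  n <- config$traits$n
  t <- length(n)
  frac <- config$overlap %||% diag(1, t)
  rp <- config$overlap_rp %||% diag(1, t)
  ns <- frac * outer(n, n, pmin)           # shared sample counts
  i0 <- ns * rp / sqrt(outer(n, n))
  diag(i0) <- 1
  dimnames(i0) <- list(config$traits$label, config$traits$label)
  i0
}

#' Simulate multi-cohort GWAS summary statistics
#'
#' Draws per-SNP Z-score vectors from the exact LDSC moment structure of a
#' latent genetic factor model: the genetic covariance is
#' \code{loadings \%*\% diag(factor_h2) \%*\% t(loadings) + diag(specific_h2)}
#' (plus any declared correlated residuals), sample overlap enters only
#' through the cross-trait intercept (shared-sample fraction times the
#' phenotypic correlation of the overlapping subsample), and reverse-coded
#' traits have all Z negated.
#'
#' @param config configuration list as produced by
#'   \code{\link{defaultGeneratorConfig}}; \code{seed} is mandatory.
#' @param ldscores optional precomputed LD-score table; by default drawn
#'   from \code{config$ldscore_law}.
#' @return list with \code{sumstats} (list of \code{\link{SumStats}}),
#'   \code{ldscores} (\code{data.frame(SNP, L2)}), \code{m}, and the
#'   generating \code{sigma_g} and \code{intercepts} matrices.
#' @export
simulateSumstats <- function(config, ldscores = NULL) {
  if (is.null(config$seed)) configError("generator config requires a seed")
  labels <- config$traits$label
  t <- length(labels)
  sg <- .generatorSigmaG(config)
  h2 <- diag(sg)
  if (any(h2 < 0 | h2 > 1))
    configError("per-trait total SNP heritability outside [0,1]: %s",
                paste(labels[h2 < 0 | h2 > 1], collapse = ", "))
  ov <- config$overlap %||% diag(1, t)
  if (max(abs(ov - t(ov))) > 1e-12 || any(abs(diag(ov) - 1) > 1e-12))
    configError("overlap matrix must be symmetric with unit diagonal")
  m <- config$m_snps
  if (is.null(ldscores))
    ldscores <- simulateLdScores(m, config$ldscore_law,
                                 seed = childSeed(config$seed, "ldscores"))
  l2 <- ldscores$L2
  i0 <- .generatorIntercepts(config)
  n <- config$traits$n
  # z_j = L0 e1 + sqrt(l_j/M) * B e2,  L0 L0' = I0,  B B' = diag(sqrt(N)) sg diag(sqrt(N))
  # eigen factorizations (chol would fail on the PSD boundary, e.g. full
  # overlap with unit phenotypic correlation)
  e0 <- eigen(i0, symmetric = TRUE)
  L0 <- e0$vectors %*% diag(sqrt(pmax(e0$values, 0)), t)
  eg <- eigen(sg, symmetric = TRUE)
  B <- diag(sqrt(n), t) %*% eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t)
  Z <- withSeed(childSeed(config$seed, "zscores"), {
    E1 <- matrix(stats::rnorm(m * t), m, t)
    E2 <- matrix(stats::rnorm(m * t), m, t)
    E1 %*% t(L0) + (E2 * sqrt(l2 / m)) %*% t(B)
  })
  rev <- config$traits$reverse_coded %||% rep(FALSE, t)
  Z[, rev] <- -Z[, rev]
  # SNP metadata: 22 contiguous chromosome chunks, 3 kb spacing, fixed
  # non-ambiguous allele pairs
  chrom <- as.character(rep(1:22, length.out = 22)[
    cut(seq_len(m), 22, labels = FALSE)])
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 10000L + 3000L * (seq_along(idx) - 1L)
  }
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  pick <- withSeed(childSeed(config$seed, "alleles"),
                   sample.int(nrow(pairs), m, replace = TRUE))
  tables <- lapply(seq_len(t), function(i) {
    SumStats(labels[i], data.frame(
      rsid = ldscores$SNP, chrom = chrom, pos = pos,
      a1 = pairs[pick, 1], a2 = pairs[pick, 2],
      z = Z[, i], n = n[i], p = zToP(Z[, i])))
  })
  names(tables) <- labels
  list(sumstats = tables, ldscores = ldscores, m = m,
       sigma_g = sg, intercepts = i0, config = config)
}

#' Write a simulated data set to disk
#'
#' Writes one canonical-dialect sumstats file per trait, a two-column
#' LD-score file (\code{SNP}, \code{L2}) and an \code{M} count file, the
#' formats the pipeline reads back.
#'
#' @param sim output of \code{\link{simulateSumstats}}.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$sumstats, function(ss) {
    p <- file.path(dir, paste0(traitLabel(ss), ".sumstats"))
    writeSumstats(ss, p)
    p
  }, "")
  ldp <- file.path(dir, "ldscores.l2.ldscore")
  data.table::fwrite(sim$ldscores, ldp, sep = "\t", quote = FALSE)
  mp <- file.path(dir, "ldscores.l2.M")
  writeLines(as.character(sim$m), mp)
  invisible(c(paths, ldscore = ldp, M = mp))
}
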