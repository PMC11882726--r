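# Shared fixtures, built once per test session. All synthetic inputs are
# generated in code; nothing is read from disk.

.fg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fg_cache)) assign(key, expr, envir = .fg_cache)
  get(key, envir = .fg_cache)
}

# The full-scale recovery panel: the packaged study conditions (nine traits,
# published sample sizes, accepted structure, M = 50,000) at seed 1.
recoverySim <- function() cached("recoverySim", {
  cfg <- defaultGeneratorConfig()
  cfg$seed <- 1L
  sim <- simulateSumstats(cfg)
  panel <- mergeCohorts(sim$sumstats)
  stack <- buildCovarianceStack(panel, sim$ldscores, sim$m, n_blocks = 200)
  list(cfg = cfg, sim = sim, panel = panel, stack = stack)
})

# A no-overlap stack for SNP-level calibration (the augmented sampling
# covariance assumes zero cross-trait terms, which holds without overlap).
nullStack <- function() cached("nullStack", {
  cfg <- defaultGeneratorConfig(m_snps = 30000)
  t <- nrow(cfg$traits)
  cfg$overlap <- diag(1, t); cfg$overlap_rp <- diag(1, t)
  dimnames(cfg$overlap) <- dimnames(cfg$overlap_rp) <-
    list(cfg$traits$label, cfg$traits$label)
  cfg$seed <- 11L
  sim <- simulateSumstats(cfg)
  panel <- mergeCohorts(sim$sumstats)
  stack <- buildCovarianceStack(panel, sim$ldscores, sim$m, n_blocks = 200)
  list(cfg = cfg, sim = sim, panel = panel, stack = stack)
})

gwasSpec <- function() modelZoo(includeVariants = TRUE)[["bifactor_wm_sub_id"]]

# build an AlignedPanel directly from a Z matrix (one fake coordinate per SNP)
panelFromZ <- function(Z, N, traits = colnames(Z)) {
  m <- nrow(Z)
  snps <- data.frame(rsid = sprintf("snp%05d", seq_len(m)),
                     chrom = "1", pos = seq_len(m) * 1000L,
                     a1 = "A", a2 = "G")
  methods::new("AlignedPanel", snps = snps, Z = unname(Z),
               N = stats::setNames(N, traits), traits = traits)
}

# small SumStats table for IO tests
toySumstats <- function(trait = "toy", n = 50, seed = 1) {
  withr::with_seed(seed, {
    pairs <- matrix(c("A", "G", "T", "C", "A", "C", "G", "T"), ncol = 2,
                    byrow = TRUE)
    pick <- sample.int(4, n, replace = TRUE)
    z <- rnorm(n)
    SumStats(trait, data.frame(
      rsid = sprintf("rs%04d", seq_len(n)), chrom = "2",
      pos = seq_len(n) * 500L, a1 = pairs[pick, 1], a2 = pairs[pick, 2],
      z = z, n = 12000, p = 2 * pnorm(-abs(z))))
  })
}

# single-trait generator config for univariate LDSC checks
uniConfig <- function(h2 = 0.25, n = 30000, m = 8000, seed = 1) {
  list(m_snps = m,
       traits = data.frame(label = "t1", n = n, reverse_coded = FALSE),
       loadings = matrix(sqrt(h2), 1, 1, dimnames = list("t1", "F1")),
       factor_h2 = 1, specific_h2 = c(t1 = 0),
       overlap = matrix(1, 1, 1, dimnames = list("t1", "t1")),
       overlap_rp = matrix(1, 1, 1, dimnames = list("t1", "t1")),
       ldscore_law = list(name = "gamma", mean = 30, shape = 3),
       seed = seed)
}

# three-trait config with a target genetic covariance matrix (loadings are
# its Cholesky factor, so sigma_g equals the target exactly)
triConfig <- function(sigma, n = c(60000, 60000, 60000), m = 20000, seed = 1) {
  L <- t(chol(sigma))
  labs <- rownames(sigma) %||% c("y", "x1", "x2")
  dimnames(L) <- list(labs, paste0("F", 1:3))
  list(m_snps = m,
       traits = data.frame(label = labs, n = n, reverse_coded = FALSE),
       loadings = L, factor_h2 = c(1, 1, 1),
       specific_h2 = stats::setNames(rep(0, 3), labs),
       overlap = diag(1, 3), overlap_rp = diag(1, 3),
       ldscore_law = list(name = "gamma", mean = 30, shape = 3),
       seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
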