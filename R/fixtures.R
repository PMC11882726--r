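# Packaged transcriptions of the published reference tables: the 11-trait
# genetic-correlation matrix with SNP heritabilities on the diagonal, and
# the printed fit statistics of the nine confirmatory factor models. These
# are inputs (printed values), not outputs of this package.

.FIXTURE_LABELS <- c("UKB Trails", "UKB Pairs", "UKB SDST", "UKB Digit",
                     "UKB P.Memory", "CHARGE DSST", "CHARGE Stroop",
                     "ALSPAC WM", "Stop-Signal", "NIH G6", "NIH G4")

# canonical modelling tokens for the fixture labels
.FIXTURE_TOKENS <- c("UKB_Trails", "UKB_Pairs", "UKB_SDST", "UKB_Digit",
                     "UKB_PMemory", "CHARGE_DSST", "CHARGE_Stroop",
                     "ALSPAC_WM", "Stop_Signal", "NIH_G6", "NIH_G4")

.fixtureUpper <- function(values) {
  m <- matrix(0, 11, 11, dimnames = list(.FIXTURE_LABELS, .FIXTURE_LABELS))
  k <- 1L
  for (i in 1:10) for (j in (i + 1):11) {
    m[i, j] <- values[k]; m[j, i] <- values[k]; k <- k + 1L
  }
  m
}

#' Published genetic correlations among the executive-function GWAS
#'
#' Exact transcription of the published LDSC genetic-correlation matrix for
#' the eleven candidate indicators, with SNP heritabilities (and their
#' standard errors) from the diagonal. The printed upper triangle is
#' completed symmetrically; \code{r_g} carries a unit diagonal.
#'
#' @return list with \code{labels}, \code{tokens} (white-space free label
#'   aliases used by \code{\link{modelZoo}}), \code{r_g} (11 x 11 symmetric,
#'   unit diagonal), \code{se} (matching SEs; diagonal: heritability SEs),
#'   \code{h2} and \code{h2_se}.
#' @examples
#' fx <- refGeneticCorrelations()
#' fx$r_g["UKB Trails", "UKB Pairs"]   # 0.7097
#' fx$h2[["UKB Trails"]]               # 0.1141
#' @export
refGeneticCorrelations <- function() {
  r <- .fixtureUpper(c(
    # UKB Trails vs ...
    0.7097, 0.7133, 0.6685, 0.3358, 0.5832, 0.3873, 0.4237, -0.1003, 0.9472, 0.6379,
    # UKB Pairs vs ...
    0.6571, 0.4390, 0.3331, 0.5568, 0.2358, 0.3240, 0.0614, 0.8126, 0.5340,
    # UKB SDST vs ...
    0.3224, 0.2257, 0.8745, 0.3596, 0.3136, 0.2078, 1.0443, 0.4092,
    # UKB Digit vs ...
    0.2328, 0.3836, 0.4496, 0.6427, -0.0349, 0.6290, 0.6060,
    # UKB P.Memory vs ...
    0.3206, 0.2728, 0.4875, 0.1959, 0.5353, 0.6067,
    # CHARGE DSST vs ...
    0.5018, 0.3977, 0.4738, 1.1107, 0.3564,
    # CHARGE Stroop vs ...
    -0.2293, -0.3916, 0.0503, 0.2171,
    # ALSPAC WM vs ...
    0.5458, 0.6750, 0.4308,
    # Stop-Signal vs ...
    0.0534, -0.2009,
    # NIH G6 vs NIH G4
    0.6175))
  diag(r) <- 1
  se <- .fixtureUpper(c(
    0.0445, 0.0466, 0.0470, 0.0569, 0.0663, 0.1108, 0.1151, 0.1235, 0.1063, 0.0794,
    0.0409, 0.0339, 0.0461, 0.0559, 0.0772, 0.0789, 0.0945, 0.0872, 0.0561,
    0.0442, 0.0506, 0.0717, 0.0986, 0.1125, 0.1232, 0.0999, 0.0717,
    0.0514, 0.0605, 0.1077, 0.1090, 0.1317, 0.1062, 0.0724,
    0.0770, 0.1326, 0.1459, 0.1684, 0.1385, 0.0907,
    0.1355, 0.1579, 0.1730, 0.1533, 0.1022,
    0.2989, 0.3010, 0.2526, 0.1597,
    0.3198, 0.2609, 0.1842,
    0.2997, 0.2166,
    0.2003))
  h2 <- c(0.1141, 0.3765, 0.1564, 0.1433, 0.0368, 0.1560, 0.1035, 0.2790,
          0.0489, 0.1388, 0.3436)
  h2_se <- c(0.0082, 0.0163, 0.0094, 0.0091, 0.0035, 0.0178, 0.0336, 0.1097,
             0.0272, 0.0552, 0.0597)
  names(h2) <- .FIXTURE_LABELS; names(h2_se) <- .FIXTURE_LABELS
  diag(se) <- h2_se
  list(labels = .FIXTURE_LABELS, tokens = .FIXTURE_TOKENS,
       r_g = r, se = se, h2 = h2, h2_se = h2_se)
}

#' Published fit statistics of the nine confirmatory factor models
#'
#' The printed chi-square, df, p, AIC, CFI and SRMR of the model set, keyed
#' by the \code{\link{modelZoo}} names. \code{df_reconciles} marks the rows
#' whose printed df equals \code{45 - countFreeParams(spec)} for the
#' transcribed structure (the remaining rows are off by one or two free
#' parameters in ways the published description leaves open).
#'
#' @return \code{data.frame(model, chisq, df, p, aic, cfi, srmr,
#'   df_reconciles)}.
#' @export
refModelFitStats <- function() {
  data.frame(
    model = c("common_factor", "three_factor", "three_factor_sub",
              "bifactor_wm", "bifactor_wm_sub", "bifactor_wm_sub_shift",
              "bifactor_drop_pairs", "bifactor_pmem_wm",
              "bifactor_sub_residual"),
    chisq = c(236.1202, 219.4508, 158.1513, 186.1265, 47.0705, 47.11906,
              75.56783, 64.11958, 129.9266),
    df = c(27L, 23L, 20L, 22L, 19L, 19L, 20L, 20L, 21L),
    p = c(2.776111e-35, 5.467484e-34, 1.706908e-23, 5.753337e-28,
          0.0003489703, 0.0003434276, 2.190229e-08, 1.610782e-06,
          1.047574e-17),
    aic = c(272.1202, 263.4508, 208.1513, 232.1265, 99.0705, 99.11906,
            125.5678, 114.1196, 177.9266),
    cfi = c(0.895631, 0.9019541, 0.9310506, 0.9180867, 0.9859904,
            0.9859662, 0.9722669, 0.9779805, 0.9456362),
    srmr = c(0.1306878, 0.1246057, 0.1131072, 0.1081619, 0.09571648,
             0.1049589, 0.09663167, 0.104505, 0.09716726),
    df_reconciles = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                      TRUE))
}

#' Covariance stack from the packaged correlation fixture
#'
#' Builds a standardized \code{\link{CovarianceStack}} from the published
#' correlation matrix with a diagonal sampling-covariance surrogate (the
#' squared printed standard errors; the published off-diagonal sampling
#' covariance is not available). Intended for exercising the model zoo;
#' estimate-level agreement with the published fits is not implied.
#'
#' @param fx fixture list from \code{\link{refGeneticCorrelations}}.
#' @param traits labels (or tokens) to retain, default: the nine indicators
#'   kept in the published models (Stop-Signal and NIH G6 excluded).
#' @return a standardized \code{\link{CovarianceStack}} labelled with
#'   modelling tokens.
#' @export
fixtureCovarianceStack <- function(fx = refGeneticCorrelations(),
                                   traits = setdiff(fx$tokens,
                                                    c("Stop_Signal", "NIH_G6"))) {
  tok <- fx$tokens
  sel <- match(traits, tok)
  if (anyNA(sel)) sel <- match(traits, fx$labels)
  if (anyNA(sel)) inputError("unknown fixture trait(s)")
  S <- fx$r_g[sel, sel, drop = FALSE]
  seM <- fx$se[sel, sel, drop = FALSE]
  labels <- tok[sel]
  dimnames(S) <- list(labels, labels)
  V <- diag(vech(seM)^2)
  CovarianceStack(labels, S, V, nBlocks = 0L,
                  h2z = stats::setNames(fx$h2[sel] / fx$h2_se[sel], labels))
}
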