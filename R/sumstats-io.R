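# Reading, harmonizing, reverse-coding and merging GWAS summary statistics.

.canonicalDialect <- function() {
  list(rsid = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
       z = "Z", n = "N", p = "P", maf = "MAF", beta = "BETA", se = "SE")
}

#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited summary-statistics file (optionally
#' gzipped, header required) into a \code{\link{SumStats}} object. Column
#' names are resolved through a dialect map from canonical fields
#' (\code{rsid, chrom, pos, a1, a2, z, n, p, maf, beta, se}) to the file's
#' headers; matching is case-insensitive. When no \code{z} column is mapped
#' but \code{beta} and \code{se} are, \code{z = beta/se}. Missing \code{n}
#' or \code{p} columns fall back to \code{defaults$n} (a per-trait constant)
#' and \code{p = 2*pnorm(-|z|)}. Alleles are uppercased and rows violating
#' the table invariants (non-finite z, n < 1, p outside (0,1], a1 == a2,
#' duplicate rsid) are dropped with a message reporting the count.
#'
#' @param path file path.
#' @param trait trait label (default: file name).
#' @param dialect named list overriding entries of the canonical dialect
#'   (\code{SNP, CHR, BP, A1, A2, Z, N, P, MAF, BETA, SE}).
#' @param defaults list of fallback constants, e.g. \code{list(n = 9879)}.
#' @return a \code{\link{SumStats}} object.
#' @export
readSumstats <- function(path, trait = NULL, dialect = list(), defaults = list()) {
  if (!file.exists(path)) inputError("sumstats file not found: %s", path)
  dia <- utils::modifyList(.canonicalDialect(), dialect)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  names(dt) <- toupper(names(dt))
  get_col <- function(field) {
    nm <- toupper(dia[[field]])
    if (nm %in% names(dt)) dt[[nm]] else NULL
  }
  rsid <- get_col("rsid"); a1 <- get_col("a1"); a2 <- get_col("a2")
  for (f in c("rsid", "a1", "a2"))
    if (is.null(get_col(f)))
      configError("mandatory column '%s' (mapped to '%s') not found in %s",
                  f, dia[[f]], path)
  z <- get_col("z")
  if (is.null(z)) {
    beta <- get_col("beta"); se <- get_col("se")
    if (is.null(beta) || is.null(se))
      configError("no Z column and no BETA/SE pair mappable in %s", path)
    z <- beta / se
  }
  n <- get_col("n") %||% rep(defaults$n %||% NA_real_, length(z))
  if (all(is.na(n)))
    configError("no N column and no default n supplied for %s", path)
  p <- get_col("p") %||% zToP(z)
  d <- data.frame(
    rsid = as.character(rsid),
    chrom = as.character(get_col("chrom") %||% NA_character_),
    pos = as.integer(get_col("pos") %||% NA_integer_),
    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
    z = as.numeric(z), n = as.numeric(n), p = as.numeric(p))
  maf <- get_col("maf")
  if (!is.null(maf)) d$maf <- as.numeric(maf)
  ok <- is.finite(d$z) & !is.na(d$n) & d$n >= 1 & !is.na(d$p) &
    d$p > 0 & d$p <= 1 & d$a1 != d$a2 & !duplicated(d$rsid)
  if (any(!ok))
    message(sprintf("readSumstats: dropped %d of %d rows failing invariants (%s)",
                    sum(!ok), length(ok), path))
  d <- d[ok, , drop = FALSE]
  if (!nrow(d)) inputError("no valid rows left after filtering: %s", path)
  SumStats(trait %||% sub("\\.(txt|tsv|sumstats)(\\.gz)?$", "", basename(path)), d)
}

#' Write summary statistics in the canonical dialect
#'
#' Writes tab-delimited columns \code{SNP CHR BP A1 A2 Z N P} (plus
#' \code{MAF} and any extra columns present, e.g. factor-GWAS \code{FACTOR}
#' and \code{QSNP_P}); readable back with \code{\link{readSumstats}}.
#'
#' @param x a \code{\link{SumStats}} object or a data.frame with canonical
#'   lowercase columns.
#' @param path output path (".gz" suffix gzips).
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  d <- if (methods::is(x, "SumStats")) ssData(x) else as.data.frame(x)
  core <- c(rsid = "SNP", chrom = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
            z = "Z", n = "N", p = "P", maf = "MAF")
  out <- d[, intersect(names(core), names(d)), drop = FALSE]
  names(out) <- core[names(out)]
  extra <- setdiff(names(d), names(core))
  if (length(extra)) out <- cbind(out, d[, extra, drop = FALSE])
  # full 17-digit precision so a read -> write -> read round-trip is
  # bit-exact for every retained numeric field
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.STRAND_AMBIGUOUS <- c("A:T", "T:A", "C:G", "G:C")
.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize allele orientation against a reference
#'
#' Aligns a summary-statistics table to a reference allele orientation:
#' rows whose (a1, a2) pair is swapped relative to the reference have their
#' Z (and effect-allele frequency, if present) flipped and alleles swapped;
#' strand-ambiguous SNPs (A/T, C/G) are dropped, as are rows whose alleles
#' are incompatible with the reference (also after strand complementing).
#' SNPs absent from the reference are kept unchanged.
#'
#' @param table a \code{\link{SumStats}} object.
#' @param reference \code{data.frame} with columns \code{rsid, a1, a2}
#'   (e.g. \code{ssData()} of another table).
#' @param dropAmbiguous drop strand-ambiguous SNPs (default TRUE; they
#'   cannot be oriented without reliable frequencies).
#' @return harmonized \code{\link{SumStats}}; attribute \code{"dropped"}
#'   carries the per-reason drop counts.
#' @export
harmonizeAlleles <- function(table, reference, dropAmbiguous = TRUE) {
  d <- ssData(table)
  ref <- as.data.frame(reference)[, c("rsid", "a1", "a2")]
  ref$a1 <- toupper(ref$a1); ref$a2 <- toupper(ref$a2)
  i <- match(d$rsid, ref$rsid)
  has <- !is.na(i)
  key <- paste(d$a1, d$a2, sep = ":")
  ambiguous <- key %in% .STRAND_AMBIGUOUS
  same <- has & d$a1 == ref$a1[i] & d$a2 == ref$a2[i]
  swapped <- has & d$a1 == ref$a2[i] & d$a2 == ref$a1[i]
  flipA1 <- unname(.complement[d$a1]); flipA2 <- unname(.complement[d$a2])
  strandSame <- has & !is.na(flipA1) & flipA1 == ref$a1[i] & flipA2 == ref$a2[i]
  strandSwap <- has & !is.na(flipA1) & flipA1 == ref$a2[i] & flipA2 == ref$a1[i]
  incompatible <- has & !(same | swapped | strandSame | strandSwap)
  keep <- !(incompatible | (dropAmbiguous & ambiguous))
  doSwap <- (swapped | strandSwap) & keep & !ambiguous
  doStrand <- (strandSame | strandSwap) & keep & !ambiguous
  d$z[doSwap] <- -d$z[doSwap]
  if ("maf" %in% names(d)) d$maf[doSwap] <- 1 - d$maf[doSwap]
  tmp <- d$a1[doSwap]; d$a1[doSwap] <- d$a2[doSwap]; d$a2[doSwap] <- tmp
  d$a1[doStrand & !doSwap] <- unname(.complement[d$a1[doStrand & !doSwap]])
  d$a2[doStrand & !doSwap] <- unname(.complement[d$a2[doStrand & !doSwap]])
  # after a swap of complemented alleles the stored alleles must match the
  # reference orientation exactly
  d$a1[doStrand & doSwap] <- ref$a1[i[doStrand & doSwap]]
  d$a2[doStrand & doSwap] <- ref$a2[i[doStrand & doSwap]]
  dropped <- c(ambiguous = sum(dropAmbiguous & ambiguous),
               incompatible = sum(incompatible & !(dropAmbiguous & ambiguous)))
  if (sum(dropped))
    message(sprintf("harmonizeAlleles (%s): dropped %d ambiguous, %d incompatible",
                    traitLabel(table), dropped[["ambiguous"]],
                    dropped[["incompatible"]]))
  out <- SumStats(traitLabel(table), d[keep, , drop = FALSE])
  attr(out, "dropped") <- dropped
  out
}

#' Reverse-code a trait
#'
#' Negates every Z statistic so that positive effects correspond to the
#' opposite phenotypic direction (used so all positive factor loadings mean
#' better task performance). P-values, sample sizes and alleles are
#' unchanged; applying it twice restores the original table.
#'
#' @param table a \code{\link{SumStats}} object.
#' @return the reverse-coded \code{\link{SumStats}}.
#' @export
reverseCode <- function(table) {
  d <- ssData(table)
  d$z <- -d$z
  SumStats(traitLabel(table), d)
}

#' Merge cohort tables into an aligned panel
#'
#' Restricts all tables to their common SNPs, harmonizes every table to the
#' first table's allele orientation (\code{\link{harmonizeAlleles}}), and
#' assembles the per-trait Z matrix and sample sizes.
#'
#' @param tables list of \code{\link{SumStats}} (>= 2).
#' @return an \code{\link{AlignedPanel}}.
#' @export
mergeCohorts <- function(tables) {
  if (length(tables) < 2) inputError("mergeCohorts needs at least 2 tables")
  labs <- vapply(tables, traitLabel, "")
  ref <- ssData(tables[[1]])[, c("rsid", "a1", "a2")]
  tabs <- c(tables[1], lapply(tables[-1], harmonizeAlleles, reference = ref))
  ids <- lapply(tabs, function(x) ssData(x)$rsid)
  common <- Reduce(intersect, ids)
  if (!length(common)) {
    for (j in 2:length(ids))
      if (!length(intersect(ids[[1]], ids[[j]])))
        inputError("no shared SNPs between '%s' and '%s'", labs[1], labs[j])
    inputError("empty SNP intersection across the %d tables", length(ids))
  }
  first <- ssData(tabs[[1]])
  first <- first[match(common, first$rsid), ]
  Z <- vapply(tabs, function(x) {
    d <- ssData(x); d$z[match(common, d$rsid)]
  }, numeric(length(common)))
  colnames(Z) <- labs
  N <- vapply(tabs, function(x) {
    d <- ssData(x); stats::median(d$n[match(common, d$rsid)])
  }, 0)
  names(N) <- labs
  methods::new("AlignedPanel",
               snps = first[, c("rsid", "chrom", "pos", "a1", "a2")],
               Z = Z, N = N, traits = labs)
}
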