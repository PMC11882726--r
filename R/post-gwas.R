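# Post-GWAS: independent significant SNPs, lead SNPs and genomic risk loci
# from factor summary statistics, and the novelty filter against previously
# reported associations.

#' LD lookup table
#'
#' Builds a symmetric lookup from SNP-pair r-squared records; absent pairs
#' have r2 = 0 and self-pairs r2 = 1.
#'
#' @param pairs \code{data.frame(rsid_a, rsid_b, r2)} (any caller-supplied
#'   pair table, e.g. exported from an LD reference).
#' @return an object of class \code{LDTable}.
#' @export
ldTable <- function(pairs = data.frame(rsid_a = character(),
                                       rsid_b = character(), r2 = numeric())) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) && (any(pairs$r2 < 0) || any(pairs$r2 > 1)))
    inputError("r2 must lie in [0, 1]")
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(pairs)) {
    key <- ifelse(pairs$rsid_a < pairs$rsid_b,
                  paste(pairs$rsid_a, pairs$rsid_b, sep = "|"),
                  paste(pairs$rsid_b, pairs$rsid_a, sep = "|"))
    for (i in seq_len(nrow(pairs))) assign(key[i], pairs$r2[i], envir = env)
  }
  structure(list(env = env), class = "LDTable")
}

#' @rdname ldTable
#' @param ld an \code{LDTable}.
#' @param a,b rsid vectors (recycled).
#' @export
ldR2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  key <- ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (a[i] == b[i]) out[i] <- 1
    else out[i] <- mget(key[i], envir = ld$env, ifnotfound = 0)[[1]]
  }
  out
}

#' Clump significant SNPs into independent significant and lead SNPs
#'
#' Greedy selection by ascending p-value among genome-wide-significant SNPs
#' (ties broken by ascending position, then rsid): a SNP is independent
#' significant if its r2 with every already-selected independent SNP is
#' below \code{r2_indep}; lead SNPs are selected the same way among the
#' independent SNPs at \code{r2_lead}. Every significant SNP is assigned to
#' the first independent SNP that pruned it (and every independent SNP to
#' its lead), giving a complete accounting.
#'
#' @param table \code{\link{SumStats}} or data.frame with \code{rsid, p} and
#'   (for tie-breaks and loci) \code{chrom, pos}.
#' @param ld an \code{\link{ldTable}}.
#' @param p_sig genome-wide significance threshold (default 5e-8, strict <).
#' @param r2_indep,r2_lead independence / lead thresholds (defaults 0.6 and
#'   0.1, the FUMA conventions).
#' @return list with \code{independent}, \code{leads} (data.frames) and
#'   \code{assignments} (\code{data.frame(rsid, status, assigned_to,
#'   lead)}).
#' @export
clumpSnps <- function(table, ld, p_sig = 5e-8, r2_indep = 0.6, r2_lead = 0.1) {
  if (any(c(p_sig, r2_indep, r2_lead) <= 0) ||
      any(c(r2_indep, r2_lead) >= 1))
    inputError("thresholds must lie in (0, 1)")
  d <- if (methods::is(table, "SumStats")) ssData(table) else as.data.frame(table)
  sig <- d[d$p < p_sig, , drop = FALSE]
  if (!nrow(sig))
    return(list(independent = sig, leads = sig,
                assignments = data.frame(rsid = character(),
                                         status = character(),
                                         assigned_to = character(),
                                         lead = character())))
  pos <- if ("pos" %in% names(sig)) sig$pos else rep(0L, nrow(sig))
  sig <- sig[order(sig$p, pos, sig$rsid), , drop = FALSE]
  indep <- character(); assigned <- rep(NA_character_, nrow(sig))
  status <- rep(NA_character_, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    r2 <- if (length(indep)) ldR2(ld, sig$rsid[i], indep) else numeric()
    hit <- which(r2 >= r2_indep)
    if (!length(hit)) {
      indep <- c(indep, sig$rsid[i])
      status[i] <- "independent"; assigned[i] <- sig$rsid[i]
    } else {
      status[i] <- "pruned"; assigned[i] <- indep[hit[1]]
    }
  }
  indTab <- sig[status == "independent", , drop = FALSE]
  leads <- character(); leadOf <- stats::setNames(rep(NA_character_, nrow(indTab)),
                                                  indTab$rsid)
  for (i in seq_len(nrow(indTab))) {
    r2 <- if (length(leads)) ldR2(ld, indTab$rsid[i], leads) else numeric()
    hit <- which(r2 >= r2_lead)
    if (!length(hit)) {
      leads <- c(leads, indTab$rsid[i])
      leadOf[i] <- indTab$rsid[i]
    } else leadOf[i] <- leads[hit[1]]
  }
  assignments <- data.frame(rsid = sig$rsid, status = status,
                            assigned_to = assigned,
                            lead = unname(leadOf[assigned]))
  list(independent = indTab,
       leads = indTab[indTab$rsid %in% leads, , drop = FALSE],
       assignments = assignments)
}

#' Define genomic risk loci
#'
#' Builds one candidate interval per lead SNP spanning all significant SNPs
#' assigned to it (closed, 1-based, bounds = min/max member positions) and
#' merges intervals on the same chromosome lying within \code{merge_window}
#' base pairs of each other. The locus lead is its smallest-p member lead.
#'
#' @param clump output of \code{\link{clumpSnps}}.
#' @param snpInfo data.frame with \code{rsid, chrom, pos, p} covering the
#'   significant SNPs.
#' @param merge_window merge distance in bp (default 250000).
#' @return \code{data.frame(chrom, start, end, lead, n_snps, members)}.
#' @export
defineLoci <- function(clump, snpInfo, merge_window = 250000) {
  asg <- clump$assignments
  if (!nrow(asg))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), lead = character(),
                      n_snps = integer(), members = character()))
  info <- as.data.frame(snpInfo)
  i <- match(asg$rsid, info$rsid)
  if (anyNA(i)) inputError("positions missing for some significant SNPs")
  asg$chrom <- info$chrom[i]; asg$pos <- info$pos[i]; asg$p <- info$p[i]
  gr <- split(asg, asg$lead)
  cand <- do.call(rbind, lapply(gr, function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
               lead = g$lead[1])
  }))
  grx <- GenomicRanges::GRanges(cand$chrom,
                                IRanges::IRanges(cand$start, cand$end))
  red <- GenomicRanges::reduce(grx, min.gapwidth = merge_window + 1L)
  hits <- GenomicRanges::findOverlaps(grx, red)
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  out <- lapply(seq_along(red), function(li) {
    leadsIn <- cand$lead[grp == li]
    mem <- asg[asg$lead %in% leadsIn, , drop = FALSE]
    best <- mem$rsid[mem$status == "independent"][
      which.min(mem$p[mem$status == "independent"])]
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)[li]),
               start = GenomicRanges::start(red)[li],
               end = GenomicRanges::end(red)[li],
               lead = best, n_snps = nrow(mem),
               members = paste(mem$rsid, collapse = ";"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Novelty filter against previously reported associations
#'
#' Three published stages: (1) remove significant SNPs whose rsID matches a
#' previously reported significant SNP; (2) remove SNPs in LD (r2 strictly
#' greater than \code{r2_novel}) with any previously reported significant
#' SNP; (3) remove risk loci overlapping a previously reported locus by at
#' least 1 bp (closed intervals, same chromosome). The audit trail names the
#' removing rule for every removed item.
#'
#' @param current list with \code{snps} (character rsids or data.frame with
#'   \code{rsid}) and \code{loci} (locus data.frame as from
#'   \code{\link{defineLoci}}).
#' @param prior list with \code{rsids} (character) and \code{loci}
#'   (data.frame \code{chrom, start, end}).
#' @param ld an \code{\link{ldTable}}.
#' @param r2_novel LD threshold for stage 2 (default 0.6; boundary r2 equal
#'   to the threshold survives).
#' @return list with \code{novel_snps}, \code{novel_loci}, \code{audit}.
#' @export
noveltyFilter <- function(current, prior, ld, r2_novel = 0.6) {
  snps <- current$snps
  if (is.data.frame(snps)) snps <- snps$rsid
  priorIds <- unique(prior$rsids %||% character())
  audit <- list()
  s1 <- snps %in% priorIds
  for (s in snps[s1])
    audit[[length(audit) + 1L]] <-
      data.frame(item = s, type = "snp", stage = 1L,
                 rule = "rsID matches prior significant SNP")
  keep <- snps[!s1]
  s2rm <- vapply(keep, function(s) {
    length(priorIds) > 0 && any(ldR2(ld, s, priorIds) > r2_novel)
  }, TRUE)
  for (s in keep[s2rm])
    audit[[length(audit) + 1L]] <-
      data.frame(item = s, type = "snp", stage = 2L,
                 rule = sprintf("r2 > %.2f with prior significant SNP", r2_novel))
  novelSnps <- keep[!s2rm]
  loci <- current$loci
  novelLoci <- loci
  if (!is.null(loci) && nrow(loci) && !is.null(prior$loci) && nrow(prior$loci)) {
    cur <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$start, loci$end))
    pri <- GenomicRanges::GRanges(prior$loci$chrom,
                                  IRanges::IRanges(prior$loci$start,
                                                   prior$loci$end))
    # disjoint chromosome sets are a legitimate "no overlap", not a warning
    ov <- unique(S4Vectors::queryHits(
      suppressWarnings(GenomicRanges::findOverlaps(cur, pri))))
    for (li in ov)
      audit[[length(audit) + 1L]] <-
        data.frame(item = sprintf("%s:%d-%d", loci$chrom[li], loci$start[li],
                                  loci$end[li]),
                   type = "locus", stage = 3L,
                   rule = "overlaps prior risk locus (>= 1 bp)")
    if (length(ov)) novelLoci <- loci[-ov, , drop = FALSE]
  }
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(item = character(), type = character(), stage = integer(),
               rule = character())
  list(novel_snps = novelSnps, novel_loci = novelLoci, audit = audit)
}

#' Read a plain rsID list / prior locus table
#'
#' \code{readRsidList}: one rsID per line. \code{readPriorLoci}: three
#' whitespace-delimited columns (chrom, start, end), interpreted as 1-based
#' closed intervals.
#'
#' @param path file path.
#' @return character vector / \code{data.frame(chrom, start, end)}.
#' @export
readRsidList <- function(path) {
  if (!file.exists(path)) inputError("rsID list not found: %s", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname readRsidList
#' @export
readPriorLoci <- function(path) {
  if (!file.exists(path)) inputError("locus file not found: %s", path)
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "integer", "integer"))
  d
}
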