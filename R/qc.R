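## Per-variant quality control: observed MAF, call rate and the exact
## conditional Hardy-Weinberg test, with the filter conventions used for
## array-style QC (MAF strictly above threshold, call rate at-or-above,
## HWE p at-or-above a very permissive floor).

#' QC thresholds
#'
#' @param maf_min Variants are kept when observed MAF is strictly greater
#'   than this (default 0.005, i.e. MAF > 0.5%).
#' @param callrate_min Minimum fraction of non-missing genotypes (default
#'   0.95, i.e. missingness of at most 5%); the boundary is kept.
#' @param hwe_p_min Variants with a Hardy-Weinberg exact p-value at or above
#'   this floor are retained (default 1e-40; in very large cohorts even
#'   negligible departures from equilibrium are formally significant, so the
#'   filter is meant to catch genotyping failures only).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.005, callrate_min = 0.95,
                          hwe_p_min = 1e-40) {
  check_fraction(c(maf_min, callrate_min, hwe_p_min), "thresholds",
                 lo_open = TRUE)
  structure(list(maf_min = maf_min, callrate_min = callrate_min,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

#' Observed minor allele frequency and call rate per variant
#'
#' The allele frequency of the counted allele is computed from non-missing
#' dosages and folded to the minor side (<= 0.5). Variants with no
#' non-missing genotypes get `maf_obs = NA` and `call_rate = 0`.
#'
#' @param genotypes A `genotype_matrix`.
#' @return `data.frame` with columns `id`, `maf_obs`, `call_rate`.
#' @export
compute_maf_callrate <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  n_obs <- colSums(!is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[n_obs == 0L] <- NA_real_
  data.frame(id = colnames(dos), maf_obs = unname(maf),
             call_rate = unname(n_obs / nrow(dos)),
             stringsAsFactors = FALSE)
}

## Log-probabilities of the conditional distribution of the heterozygote
## count given the allele counts (the Levene-Haldane distribution). `n` is
## the number of individuals and `nA` the count of the rarer allele.
hwe_het_logprob <- function(n, nA) {
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  lp <- hets * log(2) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - nA - hets) / 2 + 1)
  lp <- lp - logsumexp(lp)
  list(hets = hets, logprob = lp)
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, the heterozygote count follows
#' the Levene-Haldane distribution under equilibrium. The p-value is the
#' total probability of all heterozygote counts no more probable than the
#' observed one (the standard exact test); the computation is carried out in
#' log space so extreme departures do not underflow. The mid-p variant
#' (counting only half the probability of the observed outcome) is available
#' behind a flag and is off by default.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @param midp Use the mid-p correction (default `FALSE`).
#' @return The exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # observed count is the conditional mode -> 1
hwe_exact_test <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required", call. = FALSE)
  nA <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)  # rarer allele count
  if (nA == 0L) return(1)
  d <- hwe_het_logprob(n, nA)
  obs <- d$logprob[match(n_Aa, d$hets)]
  sel <- d$logprob <= obs + 1e-12
  p <- exp(logsumexp(d$logprob[sel]))
  if (midp) p <- p - 0.5 * exp(obs)
  min(max(p, .Machine$double.xmin), 1)
}

#' Apply MAF, call-rate and HWE filters to a QC report
#'
#' Conventions: `pass_maf` iff `maf_obs > maf_min` (monomorphic or
#' all-missing variants fail), `pass_callrate` iff
#' `call_rate >= callrate_min`, `pass_hwe` iff `hwe_p >= hwe_p_min`.
#'
#' @param report `data.frame` with columns `maf_obs`, `call_rate`, `hwe_p`.
#' @param thresholds A [qc_thresholds()] object.
#' @return The report with logical columns `pass_maf`, `pass_callrate`,
#'   `pass_hwe`, `pass_all` appended (or replaced).
#' @export
apply_variant_filters <- function(report, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(report),
            all(c("maf_obs", "call_rate", "hwe_p") %in% names(report)))
  report$pass_maf <- !is.na(report$maf_obs) &
    report$maf_obs > thresholds$maf_min
  report$pass_callrate <- report$call_rate >= thresholds$callrate_min
  report$pass_hwe <- !is.na(report$hwe_p) &
    report$hwe_p >= thresholds$hwe_p_min
  report$pass_all <- report$pass_maf & report$pass_callrate & report$pass_hwe
  report
}

#' Full per-variant QC report
#'
#' Computes observed MAF, call rate and the Hardy-Weinberg exact test for
#' every variant, then applies the filters in that order (MAF, call rate,
#' HWE; the flags are independent, so the order only matters for reporting).
#'
#' @param genotypes A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return `data.frame` with columns `id`, `chrom`, `pos`, `maf_obs`,
#'   `call_rate`, `hwe_p` and the four pass flags.
#' @export
variant_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  mc <- compute_maf_callrate(genotypes)
  dos <- genotypes$dosages
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  report <- data.frame(
    id = mc$id,
    chrom = genotypes$variants$chrom[match(mc$id, genotypes$variants$id)],
    pos = genotypes$variants$pos[match(mc$id, genotypes$variants$id)],
    maf_obs = mc$maf_obs, call_rate = mc$call_rate, hwe_p = hwe_p,
    stringsAsFactors = FALSE
  )
  apply_variant_filters(report, thresholds)
}
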