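## Anchor-centric pair-wise pleiotropy: Fisher's combined test over the two
## univariate p-values of each (variant, anchor, trait) pair, plus the tiered
## genome-wide / suggestive significance rules. All combination arithmetic is
## done in log space so tails far below double-precision granularity survive.

#' Tier thresholds for pleiotropic significance
#'
#' @param p_gw Genome-wide threshold on the combined p-value (default 5e-8).
#' @param p_suggestive Suggestive-level threshold (default 5e-6); a pair is
#'   suggestive when `p_gw <= p_fisher < p_suggestive`.
#' @param p_ad_max Univariate threshold for the anchor trait (default 5e-4).
#' @param p_trait_max Univariate threshold for the non-anchor trait
#'   (default 5e-2).
#' @return A list of class `tier_thresholds`.
#' @export
tier_thresholds <- function(p_gw = 5e-8, p_suggestive = 5e-6,
                            p_ad_max = 5e-4, p_trait_max = 5e-2) {
  check_fraction(c(p_gw, p_suggestive, p_ad_max, p_trait_max), "thresholds",
                 lo_open = TRUE, hi_open = TRUE)
  if (p_gw >= p_suggestive) stop("p_gw must be < p_suggestive", call. = FALSE)
  structure(list(p_gw = p_gw, p_suggestive = p_suggestive,
                 p_ad_max = p_ad_max, p_trait_max = p_trait_max),
            class = "tier_thresholds")
}

#' Fisher's combined p-value for a pair of tests
#'
#' Combines two independent p-values via `chi2 = -2 (ln p_a + ln p_b)`,
#' referred to a chi-square distribution with 4 degrees of freedom. The tail
#' probability is evaluated with `lower.tail = FALSE` (and is available on
#' the log scale), so combined tails near 1e-300 retain full relative
#' accuracy. Vectorised over both arguments.
#'
#' @param p_a,p_b P-values in `(0, 1]` (recycled to a common length).
#' @return `data.frame` with columns `chi2`, `p_fisher`, `log10_p`.
#' @export
#' @examples
#' fisher_combine(1.56e-4, 3.36e-8)  # anchor and trait p -> combined 1.4e-10
fisher_combine <- function(p_a, p_b) {
  check_p(p_a, "p_a")
  check_p(p_b, "p_b")
  chi2 <- -2 * (log(p_a) + log(p_b))
  logp <- stats::pchisq(chi2, df = 4, lower.tail = FALSE, log.p = TRUE)
  data.frame(chi2 = chi2, p_fisher = exp(logp), log10_p = logp / log(10))
}

#' Classify a pleiotropic pair into significance tiers
#'
#' `GW` requires `p_fisher < p_gw` together with the univariate filters
#' (`p_ad < p_ad_max`, `p_trait < p_trait_max`); `SUGGESTIVE` requires
#' `p_gw <= p_fisher < p_suggestive` with the same univariate filters (the
#' filters can be dropped from the suggestive tier via
#' `suggestive_filter = FALSE`); everything else is `NONE`. Vectorised.
#'
#' @param p_ad,p_trait,p_fisher P-value vectors.
#' @param thresholds A [tier_thresholds()] object.
#' @param suggestive_filter Apply the univariate filters to the suggestive
#'   tier as well (default `TRUE`).
#' @return Character vector in `{"GW", "SUGGESTIVE", "NONE"}`.
#' @export
classify_tier <- function(p_ad, p_trait, p_fisher,
                          thresholds = tier_thresholds(),
                          suggestive_filter = TRUE) {
  check_p(p_ad, "p_ad"); check_p(p_trait, "p_trait")
  check_p(p_fisher, "p_fisher")
  uni <- p_ad < thresholds$p_ad_max & p_trait < thresholds$p_trait_max
  gw <- p_fisher < thresholds$p_gw & uni
  sug <- p_fisher >= thresholds$p_gw & p_fisher < thresholds$p_suggestive &
    (if (suggestive_filter) uni else TRUE)
  ifelse(gw, "GW", ifelse(sug, "SUGGESTIVE", "NONE"))
}

#' Anchor-centric pair-wise pleiotropy scan
#'
#' For every variant, pairs the anchor trait's univariate record with each
#' other trait's record, combines the two Wald p-values by Fisher's method
#' and classifies the tier. Pairs in which either fit failed (status other
#' than `"ok"`) are skipped, with the reasons collected in
#' `attr(, "skipped")`.
#'
#' @param assoc Association table from [run_ewas()].
#' @param anchor_trait Name of the anchor trait (default `"AD"`).
#' @param thresholds A [tier_thresholds()] object.
#' @param suggestive_filter See [classify_tier()].
#' @return `data.frame` with columns `variant`, `trait`, `p_ad`, `p_trait`,
#'   `chi2`, `p_fisher`, `log10_p_fisher`, `tier`, ordered by variant then
#'   trait.
#' @export
run_pairwise_pleiotropy <- function(assoc, anchor_trait = "AD",
                                    thresholds = tier_thresholds(),
                                    suggestive_filter = TRUE) {
  stopifnot(is.data.frame(assoc),
            all(c("variant", "trait", "p", "status") %in% names(assoc)))
  if (!anchor_trait %in% assoc$trait) {
    stop("anchor trait '", anchor_trait, "' absent from association table",
         call. = FALSE)
  }
  ok <- assoc$status == "ok" & !is.na(assoc$p)
  anchor <- assoc[ok & assoc$trait == anchor_trait, ]
  others <- assoc[assoc$trait != anchor_trait, ]
  merged <- merge(others,
                  anchor[, c("variant", "p")],
                  by = "variant", suffixes = c("", "_anchor"))
  skipped <- merged[!(merged$status == "ok" & !is.na(merged$p)), ]
  merged <- merged[merged$status == "ok" & !is.na(merged$p), ]
  fc <- fisher_combine(merged$p_anchor, merged$p)
  res <- data.frame(
    variant = merged$variant, trait = merged$trait,
    p_ad = merged$p_anchor, p_trait = merged$p,
    chi2 = fc$chi2, p_fisher = fc$p_fisher, log10_p_fisher = fc$log10_p,
    tier = classify_tier(merged$p_anchor, merged$p, fc$p_fisher,
                         thresholds, suggestive_filter),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$variant, res$trait), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- if (nrow(skipped)) {
    data.frame(variant = skipped$variant, trait = skipped$trait,
               reason = skipped$status, stringsAsFactors = FALSE)
  } else NULL
  res
}
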