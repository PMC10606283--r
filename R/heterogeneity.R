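## Phenotype correlations (individual-level and summary-statistic based),
## exact 2x2 case/control contrasts, and classification of antagonistic
## genetic heterogeneity: a pleiotropic pair is antagonistic when the sign of
## the product of its two genetic effects opposes the sign of the phenotypic
## correlation between the two traits.

#' Pearson correlation on individual-level data
#'
#' Pearson r over complete pairs, with the two-sided p-value from the t
#' transform on `n - 2` degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length.
#' @return `data.frame` with `r`, `p`, `n`, `basis = "individual_level"`.
#' @export
pearson_individual <- function(x, y) {
  stopifnot(length(x) == length(y))
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), p = max(ct$p.value, .Machine$double.xmin),
             n = length(x), basis = "individual_level",
             stringsAsFactors = FALSE)
}

#' Correlation of association summary statistics between two traits
#'
#' Merges two association tables on shared variants (requiring identical
#' effect-allele orientation), converts each record to a z-score
#' `beta / se` (the scale-free default; raw betas are available behind the
#' `method` flag) and returns the Pearson correlation across variants.
#'
#' @param assoc_a,assoc_b Association tables from [run_ewas()] (or any table
#'   with `variant`, `effect_allele`, `beta`, `se`, `status`).
#' @param method `"z"` (default) correlates `beta/se`; `"beta"` correlates
#'   raw effects.
#' @return `data.frame` with `r`, `p`, `n`, `basis = "summary_statistic"`.
#' @export
pearson_summary <- function(assoc_a, assoc_b, method = c("z", "beta")) {
  method <- match.arg(method)
  need <- c("variant", "effect_allele", "beta", "se", "status")
  stopifnot(all(need %in% names(assoc_a)), all(need %in% names(assoc_b)))
  a <- assoc_a[assoc_a$status == "ok", need]
  b <- assoc_b[assoc_b$status == "ok", need]
  m <- merge(a, b, by = "variant", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stop("fewer than 3 shared variants", call. = FALSE)
  if (any(m$effect_allele_a != m$effect_allele_b)) {
    stop("effect-allele orientation mismatch between tables", call. = FALSE)
  }
  va <- if (method == "z") m$beta_a / m$se_a else m$beta_a
  vb <- if (method == "z") m$beta_b / m$se_b else m$beta_b
  est <- pearson_individual(va, vb)
  est$basis <- "summary_statistic"
  est
}

#' Exact two-sided test for a 2x2 contingency table
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all tables
#' whose point probability does not exceed the observed table's
#' (the minimum-likelihood convention). Probabilities are accumulated in log
#' space, so extreme tails are returned with full relative accuracy.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value in `(0, 1]`. A degenerate margin (an empty
#'   row or column) yields `p = 1` with a warning.
#' @export
#' @examples
#' fisher_exact_2x2(10, 10, 10, 10)  # perfectly balanced -> 1
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  if (r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) {
    warning("degenerate margin: p = 1")
    return(1)
  }
  support <- max(0, r1 - c2):min(r1, c1)
  lp <- stats::dhyper(support, c1, c2, r1, log = TRUE)
  obs <- lp[match(a, support)]
  sel <- lp <= obs + 1e-7          # relative tolerance on the point mass
  min(exp(logsumexp(lp[sel])), 1)
}

#' Classify antagonistic genetic heterogeneity for pleiotropic pairs
#'
#' A pair is antagonistic when the sign of `beta_ad * beta_trait` and the
#' sign of the phenotypic correlation `r(anchor, trait)` are both non-zero
#' and differ. Pairs whose correlation is not significant (two-sided p at or
#' above `alpha`) are flagged not evaluable and are never called
#' antagonistic. Vectorised.
#'
#' @param beta_ad,beta_trait Effect sizes of the pair (finite).
#' @param r_ad_trait Phenotypic correlation between anchor and trait.
#' @param r_p Optional p-value of that correlation; `NA` means "treat as
#'   evaluable".
#' @param alpha Significance gate on the correlation (default 0.05).
#' @return `data.frame` with `sign_product`, `corr_sign`, `evaluable`,
#'   `antagonistic`.
#' @export
classify_antagonism <- function(beta_ad, beta_trait, r_ad_trait,
                                r_p = NA_real_, alpha = 0.05) {
  if (any(!is.finite(beta_ad) | !is.finite(beta_trait) |
            !is.finite(r_ad_trait))) {
    stop("effects and correlation must be finite", call. = FALSE)
  }
  k <- max(length(beta_ad), length(beta_trait), length(r_ad_trait))
  sp <- sign_int(rep_len(beta_ad, k) * rep_len(beta_trait, k))
  cs <- sign_int(rep_len(r_ad_trait, k))
  rp <- rep_len(r_p, k)
  evaluable <- is.na(rp) | rp < alpha
  data.frame(
    sign_product = sp, corr_sign = cs, evaluable = evaluable,
    antagonistic = evaluable & sp != 0L & cs != 0L & sp != cs
  )
}

#' Summarise antagonism calls overall, per trait and per phenotype cluster
#'
#' @param calls `data.frame` with at least `trait`, `antagonistic`,
#'   `evaluable` (e.g. the output of [classify_antagonism()] bound to the
#'   pair identifiers). Only evaluable calls enter the fractions.
#' @param cluster_labels Named vector mapping every trait in `calls` to a
#'   phenotype cluster.
#' @return List with `overall` (n, n_antagonistic, fraction), `per_trait`
#'   and `per_cluster` data frames; clusters are partitioned into those
#'   containing antagonism and homogeneous ones.
#' @export
summarize_antagonism <- function(calls, cluster_labels) {
  stopifnot(is.data.frame(calls),
            all(c("trait", "antagonistic", "evaluable") %in% names(calls)))
  if (!all(calls$trait %in% names(cluster_labels))) {
    stop("unlabeled trait(s): ",
         paste(setdiff(calls$trait, names(cluster_labels)), collapse = ", "),
         call. = FALSE)
  }
  ev <- calls[calls$evaluable, , drop = FALSE]
  frac <- function(x) if (length(x)) mean(x) else NA_real_
  per_trait <- do.call(rbind, lapply(split(ev, ev$trait), function(d) {
    data.frame(trait = d$trait[1], n = nrow(d),
               n_antagonistic = sum(d$antagonistic),
               fraction = frac(d$antagonistic), stringsAsFactors = FALSE)
  }))
  ev$cluster <- cluster_labels[ev$trait]
  per_cluster <- do.call(rbind, lapply(split(ev, ev$cluster), function(d) {
    data.frame(cluster = d$cluster[1], n = nrow(d),
               n_antagonistic = sum(d$antagonistic),
               fraction = frac(d$antagonistic),
               contains_antagonism = any(d$antagonistic),
               stringsAsFactors = FALSE)
  }))
  rownames(per_trait) <- rownames(per_cluster) <- NULL
  list(
    overall = list(n = nrow(ev), n_antagonistic = sum(ev$antagonistic),
                   fraction = frac(ev$antagonistic)),
    per_trait = per_trait,
    per_cluster = per_cluster,
    clusters = list(n = nrow(per_cluster),
                    n_with_antagonism = sum(per_cluster$contains_antagonism),
                    fraction = frac(per_cluster$contains_antagonism))
  )
}
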