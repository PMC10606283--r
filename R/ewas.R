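## Univariate exome-wide association scan: one regression per
## (variant, trait) with additive minor-allele coding, sex+age adjustment,
## case-wise deletion of missing genotypes and Wald inference.

#' Linear association fit with Wald inference
#'
#' Ordinary least squares of `y` on an intercept, the dosage `g` and optional
#' covariates, with case-wise deletion of incomplete rows. The Wald p-value
#' comes from the t statistic on the genotype coefficient. A zero-residual
#' (saturated) fit is flagged as degenerate: the coefficient is exact but
#' `se = 0` and `p = NA`.
#'
#' @param y Numeric response.
#' @param g Dosage vector (same length).
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @return A list with `beta`, `se`, `p`, `n_used`, `status` (`"ok"` or
#'   `"degenerate"`).
#' @export
fit_linear_wald <- function(y, g, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g, covariates)
  cc <- stats::complete.cases(X, y)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  p_par <- ncol(X)
  if (length(y) <= p_par) {
    stop("need more complete cases than parameters", call. = FALSE)
  }
  if (stats::var(X[, "g"]) == 0) {
    stop("monomorphic in analysis set", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p_par) {
    stop("singular design (genotype collinear with covariates)",
         call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  df <- length(y) - p_par
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  j <- match("g", colnames(X)[fit$qr$pivot])
  beta <- unname(fit$coefficients["g"])
  if (rss <= 1e-12 * sum(y^2)) {
    return(list(beta = beta, se = 0, p = NA_real_, n_used = length(y),
                status = "degenerate"))
  }
  se <- sqrt(rss / df * xtx_inv[j, j])
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df),
       n_used = length(y), status = "ok")
}

#' Logistic association fit with Wald inference
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' intercept, the dosage and optional covariates, fitted by iteratively
#' reweighted least squares (deviance tolerance 1e-8, at most 50 iterations).
#' The Wald p-value comes from the z statistic on the genotype coefficient.
#' Non-convergence or a genotype coefficient of magnitude above 15 (a
#' practical marker of separation with rare variants) yields status
#' `"separation"` / `"nonconverged"` so the record can be excluded
#' downstream.
#'
#' @param y01 Binary response in `{0, 1}`.
#' @param g Dosage vector.
#' @param covariates Optional numeric covariate matrix.
#' @return A list with `beta`, `se`, `p`, `n_used`, `status`.
#' @export
fit_logistic_wald <- function(y01, g, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g, covariates)
  cc <- stats::complete.cases(X, y01)
  X <- X[cc, , drop = FALSE]
  y <- y01[cc]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("one-class outcome among complete cases", call. = FALSE)
  }
  if (stats::var(X[, "g"]) == 0) {
    stop("monomorphic in analysis set", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)
  ))
  beta <- unname(fit$coefficients["g"])
  w <- fit$weights
  xtwx <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(chol2inv(chol(xtwx))[2L, 2L]), error = function(e) NA)
  status <- if (!fit$converged) "nonconverged"
            else if (!is.finite(beta) || abs(beta) > 15) "separation"
            else "ok"
  z <- beta / se
  list(beta = beta, se = se,
       p = if (status == "ok") 2 * stats::pnorm(-abs(z)) else NA_real_,
       n_used = length(y), status = status)
}

#' Run a univariate association scan over variants and traits
#'
#' One regression per (variant, trait): linear for quantitative traits,
#' logistic for binary ones, always adjusted for sex and age, with the minor
#' allele as the effect allele. If a variant's counted allele turns out to be
#' the major one among complete cases, its dosage is flipped (`2 - g`) and
#' the allele labels are swapped, so reported effects are always per
#' minor-allele copy. Failed fits are kept as records with an explicit
#' `status` and `NA` statistics.
#'
#' @param cohort Phenotype table from [simulate_cohort()] or
#'   [read_phenotypes_tsv()]; must contain `sex`, `age` and the trait
#'   columns.
#' @param genotypes A `genotype_matrix` (typically restricted to QC-passing
#'   variants, see [variant_qc()]).
#' @param traits Character vector of trait names to scan; defaults to every
#'   trait listed in `attr(cohort, "traits")`.
#' @param trait_types Named character vector (`"binary"`/`"quantitative"`);
#'   defaults to the types in `attr(cohort, "traits")`.
#' @return `data.frame` of association records: `variant`, `chrom`, `pos`,
#'   `trait`, `effect_allele`, `other_allele`, `maf`, `beta`, `se`, `p`,
#'   `n_used`, `status`.
#' @export
run_ewas <- function(cohort, genotypes, traits = NULL, trait_types = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(cohort))
  panel <- attr(cohort, "traits")
  if (is.null(traits)) {
    if (is.null(panel)) stop("no trait panel available", call. = FALSE)
    traits <- panel$trait
  }
  if (is.null(trait_types)) {
    if (is.null(panel)) stop("trait types must be supplied", call. = FALSE)
    trait_types <- stats::setNames(panel$type, panel$trait)
  }
  missing_traits <- setdiff(traits, names(cohort))
  if (length(missing_traits)) {
    stop("unknown trait(s): ", paste(missing_traits, collapse = ", "),
         call. = FALSE)
  }
  if (!all(traits %in% names(trait_types))) {
    stop("trait type missing for some traits", call. = FALSE)
  }
  if (nrow(cohort) != nrow(genotypes$dosages)) {
    stop("cohort and genotype matrix have different numbers of individuals",
         call. = FALSE)
  }
  covar <- cbind(sex = cohort$sex, age = cohort$age)
  vmeta <- genotypes$variants
  out <- vector("list", ncol(genotypes$dosages) * length(traits))
  idx <- 0L
  for (j in seq_len(ncol(genotypes$dosages))) {
    g <- genotypes$dosages[, j]
    af <- mean(g, na.rm = TRUE) / 2
    ref <- vmeta$ref[j]; alt <- vmeta$alt[j]
    if (is.finite(af) && af > 0.5) {        # fold to the minor allele
      g <- 2L - g
      af <- 1 - af
      tmp <- ref; ref <- alt; alt <- tmp
    }
    for (tn in traits) {
      idx <- idx + 1L
      rec <- tryCatch(
        if (trait_types[[tn]] == "binary") {
          fit_logistic_wald(cohort[[tn]], g, covar)
        } else {
          fit_linear_wald(cohort[[tn]], g, covar)
        },
        error = function(e) list(beta = NA_real_, se = NA_real_,
                                 p = NA_real_, n_used = sum(!is.na(g)),
                                 status = conditionMessage(e))
      )
      out[[idx]] <- data.frame(
        variant = vmeta$id[j], chrom = vmeta$chrom[j], pos = vmeta$pos[j],
        trait = tn, effect_allele = alt, other_allele = ref,
        maf = af, beta = rec$beta, se = rec$se, p = rec$p,
        n_used = rec$n_used, status = rec$status,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
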