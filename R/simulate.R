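## Synthetic cohort generator -------------------------------------------------
##
## Generates genotype matrices, correlated phenotype panels and planted
## pleiotropic effects with the statistical structure the downstream analysis
## assumes: biallelic variants in Hardy-Weinberg proportions, additive minor
## allele dosages with optional missingness, quantitative traits driven by
## planted genetic effects + sex/age + correlated Gaussian noise, and binary
## diseases drawn from a logistic model whose intercept is solved to hit a
## target prevalence.

#' Default 17-trait phenotype panel
#'
#' Returns the trait panel used throughout the package: the anchor disease
#' (Alzheimer's disease, `AD`), six further diseases and ten quantitative
#' cardio-metabolic traits, together with realistic population means,
#' standard deviations and disease prevalences for a late-middle-aged
#' biobank-style cohort.
#'
#' @return A `data.frame` with columns `trait`, `type` (`"binary"` or
#'   `"quantitative"`), `prevalence` (binary traits), `mean` and `sd`
#'   (quantitative traits, measurement units).
#' @export
#' @examples
#' trait_panel()
trait_panel <- function() {
  data.frame(
    trait = c("AD", "DM", "HT", "CHD", "MI", "STROKE", "HF",
              "BG", "BMI", "HEIGHT", "WEIGHT", "SBP", "DBP",
              "HDLC", "LDLC", "TC", "TG"),
    type = c(rep("binary", 7L), rep("quantitative", 10L)),
    prevalence = c(0.0019, 0.0588, 0.2419, 0.0872, 0.0312, 0.0245, 0.0173,
                   rep(NA_real_, 10L)),
    mean = c(rep(NA_real_, 7L),
             92.13, 27.34, 168.67, 78.03, 139.78, 82.13,
             56.49, 138.07, 221.19, 154.26),
    sd = c(rep(NA_real_, 7L),
           21.19, 4.73, 9.24, 15.83, 19.58, 10.65,
           14.82, 33.44, 43.99, 89.82),
    stringsAsFactors = FALSE
  )
}

## Small latent correlations between the anchor and the other traits, plus the
## handful of strong trait-trait correlations a cardio-metabolic panel shows
## (lipids, blood pressure, anthropometry). Everything unlisted is zero.
default_latent_cor <- function(traits) {
  k <- nrow(traits)
  R <- diag(k)
  dimnames(R) <- list(traits$trait, traits$trait)
  ad <- c(HT = 0.029, CHD = 0.0248, MI = 0.018, STROKE = 0.0166,
          DM = 0.0164, HF = 0.0128, BG = 0.0025, BMI = -0.0031,
          HEIGHT = -0.007, WEIGHT = -0.0066, SBP = 0.0143, DBP = -0.0014,
          HDLC = 0.0038, LDLC = -0.0057, TC = -0.0042, TG = -0.0024)
  for (t in names(ad)) R["AD", t] <- R[t, "AD"] <- ad[[t]]
  pairs <- list(c("LDLC", "TC", 0.95), c("CHD", "MI", 0.58),
                c("SBP", "DBP", 0.67), c("WEIGHT", "BMI", 0.83),
                c("WEIGHT", "HEIGHT", 0.54), c("HDLC", "TG", -0.44),
                c("HDLC", "WEIGHT", -0.46))
  for (p in pairs) {
    R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  }
  ## Unlisted cells default to zero, which can make the patchwork indefinite;
  ## project onto the nearest correlation matrix (eigenvalue clipping, then
  ## rescale to unit diagonal).
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    R <- e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(traits$trait, traits$trait)
  }
  R
}

#' Specify the generative model for a synthetic cohort
#'
#' Bundles everything `simulate_cohort()` needs: the trait panel, the latent
#' (noise) correlation structure among traits, planted per-(variant, trait)
#' additive effects, covariate effects of sex and age, and the sampling model
#' for the covariates themselves.
#'
#' Planted effect sizes are expressed in trait-standard-deviation units per
#' minor-allele copy for quantitative traits and in log-odds per copy for
#' binary traits, matching the scale on which the association scan reports
#' them.
#'
#' @param traits Trait panel as returned by [trait_panel()] (may be a subset,
#'   but must keep the same columns).
#' @param latent_cor Positive semi-definite correlation matrix (one row per
#'   trait, dimnames matching `traits$trait`) for the shared latent Gaussian
#'   factors that induce trait-trait correlations.
#' @param beta `data.frame` with columns `variant`, `trait`, `beta`: the
#'   planted additive genetic effects. May be empty (pure null model).
#' @param age_beta,sex_beta Named numeric vectors of covariate effects per
#'   trait (standardised units for quantitative traits, log-odds for binary
#'   ones). Unnamed traits get zero.
#' @param age_range Length-2 numeric, uniform sampling range for age in years.
#' @param sex_prob Probability that `sex == 1` (female).
#' @param frailty_scale Coefficient with which a binary trait's latent factor
#'   enters its logit; larger values give stronger induced correlations
#'   between diseases and the rest of the panel.
#' @return An object of class `effects_spec`.
#' @export
effects_spec <- function(traits = trait_panel(),
                         latent_cor = default_latent_cor(traits),
                         beta = data.frame(variant = character(),
                                           trait = character(),
                                           beta = numeric()),
                         age_beta = NULL,
                         sex_beta = NULL,
                         age_range = c(40, 70),
                         sex_prob = 0.55,
                         frailty_scale = 2) {
  stopifnot(is.data.frame(traits),
            all(c("trait", "type") %in% names(traits)),
            all(traits$type %in% c("binary", "quantitative")))
  if (!identical(dim(latent_cor), c(nrow(traits), nrow(traits)))) {
    stop("'latent_cor' must be square with one row per trait", call. = FALSE)
  }
  if (is.null(dimnames(latent_cor))) {
    dimnames(latent_cor) <- list(traits$trait, traits$trait)
  }
  if (!isTRUE(all.equal(latent_cor, t(latent_cor)))) {
    stop("'latent_cor' must be symmetric", call. = FALSE)
  }
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("'latent_cor' is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  prev <- traits$prevalence[traits$type == "binary"]
  check_fraction(prev, "prevalence", lo_open = TRUE, hi_open = TRUE)
  stopifnot(is.data.frame(beta),
            all(c("variant", "trait", "beta") %in% names(beta)))
  if (!all(beta$trait %in% traits$trait)) {
    stop("planted effects reference unknown traits", call. = FALSE)
  }
  fill <- function(v) {
    out <- stats::setNames(numeric(nrow(traits)), traits$trait)
    if (!is.null(v)) out[names(v)] <- v
    out
  }
  structure(
    list(traits = traits, latent_cor = latent_cor, beta = beta,
         age_beta = fill(age_beta), sex_beta = fill(sex_beta),
         age_range = age_range, sex_prob = sex_prob,
         frailty_scale = frailty_scale),
    class = "effects_spec"
  )
}

#' Simulate variant records
#'
#' Draws `m` biallelic variants with true minor allele frequencies uniform on
#' `[maf_low, maf_high]`, spread across chromosomes 1-22 with increasing
#' positions.
#'
#' @param m Number of variants (>= 1).
#' @param maf_low,maf_high Bounds of the uniform MAF distribution,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `true_maf`.
#' @export
#' @examples
#' simulate_variants(5, 0.05, 0.5, seed = 1)
simulate_variants <- function(m, maf_low = 0.005, maf_high = 0.5, seed) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("'m' must be a count >= 1", call. = FALSE)
  }
  m <- as.integer(m)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  with_seed(seed, {
    chrom <- as.character(rep_len(1:22, m))
    pos <- integer(m)
    for (c in unique(chrom)) {
      idx <- which(chrom == c)
      pos[idx] <- cumsum(sample.int(5e4, length(idx), replace = TRUE)) + 1e6L
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    data.frame(
      id = sprintf("var%05d", seq_len(m)),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      true_maf = stats::runif(m, maf_low, maf_high),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a genotype dosage matrix under Hardy-Weinberg proportions
#'
#' Each dosage is the sum of two independent Bernoulli(`true_maf`) allele
#' draws, i.e. genotype frequencies follow Hardy-Weinberg proportions.
#' Entries are then masked missing independently with probability
#' `missing_rate`.
#'
#' @param variants Variant table from [simulate_variants()].
#' @param n Number of individuals (>= 1).
#' @param missing_rate Per-entry missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: a list with `variants` and
#'   `dosages` (an `n x m` integer matrix of minor-allele counts, `NA` for
#'   missing, individuals in rows).
#' @export
simulate_genotypes <- function(variants, n, missing_rate = 0, seed) {
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a count >= 1", call. = FALSE)
  }
  check_fraction(missing_rate, "missing_rate", hi_open = TRUE)
  n <- as.integer(n)
  m <- nrow(variants)
  with_seed(seed, {
    dos <- matrix(
      stats::rbinom(n * m, size = 2L, prob = rep(variants$true_maf, each = n)),
      nrow = n, ncol = m,
      dimnames = list(sprintf("ind%05d", seq_len(n)), variants$id)
    )
    if (missing_rate > 0) {
      dos[stats::runif(n * m) < missing_rate] <- NA_integer_
    }
    genotype_matrix(variants, dos)
  })
}

#' Construct a genotype matrix object
#'
#' @param variants Variant metadata `data.frame` (columns `id`, `chrom`,
#'   `pos`, `ref`, `alt`, optionally `true_maf`).
#' @param dosages Integer matrix, individuals x variants, entries in
#'   `{0, 1, 2, NA}` counting minor-allele copies.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, dosages) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("non-missing dosages must be in {0, 1, 2}", call. = FALSE)
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  structure(list(variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

## Solve the logistic intercept so that mean(plogis(b0 + eta)) hits the
## target prevalence. Warns and reports the realised prevalence when the
## target is unreachable on the searched interval.
solve_prevalence_intercept <- function(eta, target) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0) {
    warning(sprintf(
      "prevalence target %.4g unreachable; realised expectation %.4g",
      target, mean(stats::plogis(ifelse(f(lo) > 0, lo, hi) + eta))))
    return(ifelse(f(lo) > 0, lo, hi))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate a phenotype/covariate table conditional on genotypes
#'
#' Quantitative traits are linear combinations of the planted additive
#' genetic effects, sex and age effects, and correlated Gaussian noise
#' (shared latent factors per `spec$latent_cor`), rescaled to the panel's
#' means and standard deviations. Binary diseases are drawn from a logistic
#' model whose linear predictor carries the planted log-odds effects, the
#' covariate effects and `frailty_scale` times the trait's latent factor; the
#' intercept is solved by 1-D root finding so the expected prevalence matches
#' the target.
#'
#' Missing dosages are mean-imputed (2 x true MAF) for phenotype generation
#' only; the analysis functions still see the missing entries.
#'
#' @param genotypes A `genotype_matrix`.
#' @param spec An [effects_spec()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `id`, `sex`, `age` and one column per
#'   trait; the trait panel is attached as `attr(, "traits")`.
#' @export
simulate_cohort <- function(genotypes, spec, seed) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(spec, "effects_spec"))
  if (nrow(spec$beta) &&
      !all(spec$beta$variant %in% genotypes$variants$id)) {
    stop("planted effects reference variants absent from the genotype matrix",
         call. = FALSE)
  }
  n <- nrow(genotypes$dosages)
  traits <- spec$traits
  k <- nrow(traits)
  with_seed(seed, {
    sex <- stats::rbinom(n, 1L, spec$sex_prob)
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    age_c <- (age - mean(spec$age_range)) /
      (diff(spec$age_range) / sqrt(12))  # standardised age
    sex_c <- sex - spec$sex_prob

    ## shared latent factors inducing the trait-trait correlations
    z <- matrix(stats::rnorm(n * k), n, k) %*%
      chol(spec$latent_cor + diag(1e-10, k))
    colnames(z) <- traits$trait

    ## per-trait genetic score and its theoretical variance
    gscore <- matrix(0, n, k, dimnames = list(NULL, traits$trait))
    gvar <- stats::setNames(numeric(k), traits$trait)
    if (nrow(spec$beta)) {
      maf <- stats::setNames(genotypes$variants$true_maf,
                             genotypes$variants$id)
      if (anyNA(maf)) {
        maf[is.na(maf)] <- colMeans(genotypes$dosages, na.rm = TRUE)[
          names(maf)[is.na(maf)]] / 2
      }
      for (i in seq_len(nrow(spec$beta))) {
        v <- spec$beta$variant[i]; t <- spec$beta$trait[i]
        b <- spec$beta$beta[i]
        g <- genotypes$dosages[, v]
        g[is.na(g)] <- 2 * maf[[v]]
        gscore[, t] <- gscore[, t] + b * (g - 2 * maf[[v]])
        gvar[[t]] <- gvar[[t]] + b^2 * 2 * maf[[v]] * (1 - maf[[v]])
      }
    }

    out <- data.frame(id = rownames(genotypes$dosages), sex = sex, age = age,
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      tn <- traits$trait[j]
      covar_eff <- spec$age_beta[[tn]] * age_c + spec$sex_beta[[tn]] * sex_c
      covar_var <- spec$age_beta[[tn]]^2 +
        spec$sex_beta[[tn]]^2 * spec$sex_prob * (1 - spec$sex_prob)
      if (traits$type[j] == "quantitative") {
        noise_sd <- sqrt(max(1 - gvar[[tn]] - covar_var, 0.05))
        y_std <- gscore[, tn] + covar_eff + noise_sd * z[, tn]
        out[[tn]] <- pmax(traits$mean[j] + traits$sd[j] * y_std, 0)
      } else {
        eta <- gscore[, tn] + covar_eff + spec$frailty_scale * z[, tn]
        b0 <- solve_prevalence_intercept(eta, traits$prevalence[j])
        out[[tn]] <- stats::rbinom(n, 1L, stats::plogis(b0 + eta))
      }
    }
    attr(out, "traits") <- traits
    out
  })
}

#' Derive the planted ground truth implied by an effects specification
#'
#' For every planted pleiotropic pair (a variant with non-zero effects on the
#' anchor trait and on at least one other trait) the expected
#' effect-direction concordance sign, the expected sign of the induced
#' anchor-trait correlation, and the implied antagonism label are returned,
#' together with the expected phenotype blocks (traits sharing an identical
#' planted variant/sign support belong to one block).
#'
#' The induced correlation sign is derived from the expected covariance
#' between the anchor's linear predictor and the trait on the standardised
#' scale, summing the three channels the generator uses: shared latent
#' factors (`frailty_scale^2 * latent_cor` between two diseases,
#' `frailty_scale * latent_cor` between a disease and a quantitative trait),
#' shared covariate effects (`age_beta` products plus `sex_beta` products
#' weighted by the sex variance), and the planted genetic covariance
#' `sum(beta_anchor * beta_trait * 2 maf (1 - maf))`.
#'
#' @param spec An [effects_spec()].
#' @param anchor Name of the anchor trait, default `"AD"`.
#' @param maf Optional named vector of true MAFs for the genetic covariance
#'   term; when absent a nominal common-variant weight `2 maf (1 - maf) = 0.32`
#'   is used.
#' @return A list of class `planted_truth` with elements `pairs` (a
#'   `data.frame`: `variant`, `trait`, `sign_product`, `corr_sign`,
#'   `antagonistic`) and `blocks` (a named integer vector of expected block
#'   labels for traits carrying planted effects).
#' @export
planted_truth <- function(spec, anchor = "AD", maf = NULL) {
  stopifnot(inherits(spec, "effects_spec"))
  b <- spec$beta
  empty <- list(
    pairs = data.frame(variant = character(), trait = character(),
                       sign_product = integer(), corr_sign = integer(),
                       antagonistic = logical(), stringsAsFactors = FALSE),
    blocks = stats::setNames(integer(0), character(0))
  )
  if (!nrow(b)) return(structure(empty, class = "planted_truth"))
  b_anchor <- b[b$trait == anchor, ]
  b_other <- b[b$trait != anchor, ]
  keep <- b_other$variant %in% b_anchor$variant
  b_other <- b_other[keep, , drop = FALSE]
  if (!nrow(b_other)) return(structure(empty, class = "planted_truth"))
  beta_a <- stats::setNames(b_anchor$beta, b_anchor$variant)

  type_of <- stats::setNames(spec$traits$type, spec$traits$trait)
  lam <- function(t) if (type_of[[t]] == "binary") spec$frailty_scale else 1
  corr_sign_of <- function(trait) {
    latent <- lam(anchor) * lam(trait) * spec$latent_cor[anchor, trait]
    covar <- spec$age_beta[[anchor]] * spec$age_beta[[trait]] +
      spec$sex_beta[[anchor]] * spec$sex_beta[[trait]] *
        spec$sex_prob * (1 - spec$sex_prob)
    rows <- b_other[b_other$trait == trait, , drop = FALSE]
    w <- if (is.null(maf)) rep(0.32, nrow(rows)) else {
      2 * maf[rows$variant] * (1 - maf[rows$variant])
    }
    genetic <- sum(beta_a[rows$variant] * rows$beta * w)
    sign_int(latent + covar + genetic)
  }
  sign_product <- sign_int(beta_a[b_other$variant] * b_other$beta)
  corr_sign <- vapply(b_other$trait, corr_sign_of, integer(1))
  pairs <- data.frame(
    variant = b_other$variant, trait = b_other$trait,
    sign_product = unname(sign_product), corr_sign = unname(corr_sign),
    antagonistic = unname(sign_product != 0L & corr_sign != 0L &
                            sign_product != corr_sign),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ## blocks: traits with identical (variant, concordance-sign) support
  sig <- vapply(split(pairs, pairs$trait), function(d) {
    paste(sort(paste(d$variant, d$sign_product)), collapse = ";")
  }, "")
  blocks <- stats::setNames(match(sig, unique(sig)), names(sig))
  structure(list(pairs = pairs, blocks = blocks), class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: %d pleiotropic pairs, %d phenotype blocks\n",
              nrow(x$pairs), length(unique(x$blocks))))
  invisible(x)
}

#' Planted three-block demonstration design
#'
#' A ready-made [effects_spec()] used by the recovery tests and the worked
#' examples: 13 pleiotropic index SNPs with strong anchor-disease effects and
#' three phenotype blocks -- lipids (LDLC, TC, TG, HDLC; SNPs 1-5), blood
#' pressure (SBP, DBP, HT; SNPs 6-9) and anthropometry (BMI, WEIGHT; SNPs
#' 10-13) -- with a mix of same-direction and opposite-direction
#' (antagonistic) configurations. The anchor prevalence is raised to 0.20
#' (a case-enriched design) so that logistic fits at moderate sample sizes
#' are informative. Anchor-trait correlations strong enough to be evaluable
#' for antagonism (|r| around 0.06-0.1) are induced through a shared age
#' effect: the anchor risk rises steeply with age, so age-linked traits
#' correlate with it in the direction of their own age effect. Diseases get
#' no latent frailty (`frailty_scale = 0`), so their generative logit
#' contains exactly the planted genetics plus the modelled covariates; this
#' keeps the planted conditional log-odds recoverable by a correctly
#' specified logistic fit (with a non-zero frailty the marginal single-SNP
#' estimate is attenuated by noncollapsibility). The per-block concordance
#' signs are balanced so the planted genetic covariance never flips the
#' induced correlation sign.
#'
#' @param variant_ids Character vector of at least 13 variant ids; the first
#'   13 receive the planted effects.
#' @param beta_quant Planted effect, trait-SD units, for quantitative traits.
#' @param beta_binary Planted log-odds effect for binary traits.
#' @param beta_anchor Planted log-odds effect on the anchor disease.
#' @return An `effects_spec`.
#' @export
planted_demo_spec <- function(variant_ids, beta_quant = 0.25,
                              beta_binary = 0.55, beta_anchor = 0.5) {
  if (length(variant_ids) < 13L) {
    stop("need at least 13 variant ids", call. = FALSE)
  }
  snps <- variant_ids[1:13]
  traits <- trait_panel()
  traits$prevalence[traits$trait == "AD"] <- 0.20
  traits$prevalence[traits$trait == "HT"] <- 0.25

  R <- diag(nrow(traits))
  dimnames(R) <- list(traits$trait, traits$trait)
  ad_r <- c(LDLC = 0.25, TC = 0.25, TG = 0.25, HDLC = -0.25,
            HT = 0.25, SBP = 0.25, DBP = 0.25,
            BMI = -0.25, WEIGHT = -0.25)
  for (t in names(ad_r)) R["AD", t] <- R[t, "AD"] <- ad_r[[t]]
  within <- list(c("LDLC", "TC", 0.6), c("SBP", "DBP", 0.5),
                 c("BMI", "WEIGHT", 0.6), c("TG", "LDLC", 0.3),
                 c("TG", "TC", 0.3))
  for (p in within) R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  stopifnot(ev > 0)

  blocks <- list(
    list(traits = c("LDLC", "TC", "TG", "HDLC"),
         snps = snps[1:5],  conc = c(1, 1, 1, -1, -1)),
    list(traits = c("SBP", "DBP", "HT"),
         snps = snps[6:9],  conc = c(1, 1, -1, -1)),
    list(traits = c("BMI", "WEIGHT"),
         snps = snps[10:13], conc = c(1, 1, -1, -1))
  )
  ## anchor effects: alternating signs across the 13 SNPs
  anchor_sign <- rep_len(c(1, -1), 13L)
  beta <- data.frame(variant = snps, trait = "AD",
                     beta = beta_anchor * anchor_sign,
                     stringsAsFactors = FALSE)
  type_of <- stats::setNames(traits$type, traits$trait)
  for (blk in blocks) {
    for (i in seq_along(blk$snps)) {
      s <- blk$snps[i]
      a_sign <- anchor_sign[match(s, snps)]
      for (t in blk$traits) {
        size <- if (type_of[[t]] == "binary") beta_binary else beta_quant
        beta <- rbind(beta, data.frame(
          variant = s, trait = t,
          beta = blk$conc[i] * a_sign * size, stringsAsFactors = FALSE))
      }
    }
  }
  effects_spec(traits = traits, latent_cor = R, beta = beta,
               age_beta = c(AD = 1.0, HT = 0.8, SBP = 0.35, DBP = 0.35,
                            LDLC = 0.2, TC = 0.2, TG = 0.15, HDLC = -0.2,
                            BMI = -0.3, WEIGHT = -0.35, HEIGHT = -0.1,
                            CHD = 0.4),
               sex_beta = c(HEIGHT = -0.8, WEIGHT = -0.6, HDLC = 0.4),
               frailty_scale = 0)
}
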