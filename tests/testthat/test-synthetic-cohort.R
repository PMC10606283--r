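test_that("simulate_variants respects the MAF range and the seed", {
  v <- simulate_variants(1, maf_low = 0.25, maf_high = 0.25, seed = 1)
  expect_equal(v$true_maf, 0.25)
  expect_equal(nrow(v), 1L)

  a <- simulate_variants(1000, 0.005, 0.5, seed = 7)
  b <- simulate_variants(1000, 0.005, 0.5, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$true_maf >= 0.005 & a$true_maf <= 0.5))
  expect_true(all(a$pos >= 1))
  expect_true(all(a$ref != a$alt))

  # mean of Uniform(0.005, 0.5) is 0.2525 with sd (0.495/sqrt(12))/sqrt(m)
  big <- simulate_variants(10000, 0.005, 0.5, seed = 3)
  se <- (0.495 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(big$true_maf) - 0.2525), 3 * se)

  expect_error(simulate_variants(0, 0.1, 0.2, seed = 1), "count")
  expect_error(simulate_variants(10, 0.3, 0.2, seed = 1), "maf_low")
  expect_error(simulate_variants(10, 0, 0.2, seed = 1), "maf_low")
})

test_that("simulate_genotypes draws Hardy-Weinberg dosages with masked entries", {
  v <- simulate_variants(5, 0.1, 0.5, seed = 2)
  g0 <- simulate_genotypes(v, 100, missing_rate = 0, seed = 4)
  expect_false(anyNA(g0$dosages))
  expect_true(all(g0$dosages %in% 0:2))
  expect_equal(dim(g0$dosages), c(100L, 5L))

  # genotype frequencies at true_maf = 0.5: (0.25, 0.5, 0.25)
  v5 <- data.frame(id = "v1", chrom = "1", pos = 100L, ref = "A", alt = "G",
                   true_maf = 0.5)
  gg <- simulate_genotypes(v5, 20000, seed = 8)
  freq <- tabulate(gg$dosages + 1L, 3L) / 20000
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 20000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  # determinism and realized missingness
  m1 <- simulate_genotypes(v, 500, missing_rate = 0.05, seed = 9)
  m2 <- simulate_genotypes(v, 500, missing_rate = 0.05, seed = 9)
  expect_identical(m1$dosages, m2$dosages)
  expect_lt(abs(mean(is.na(m1$dosages)) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2500))

  expect_error(simulate_genotypes(v, 0, seed = 1), "count")
  expect_error(simulate_genotypes(v, 10, missing_rate = 1, seed = 1),
               "missing_rate")
})

test_that("null cohort hits target prevalences and latent correlations", {
  v <- simulate_variants(3, 0.2, 0.5, seed = 11)
  geno <- simulate_genotypes(v, 20000, seed = 12)
  spec <- effects_spec()   # no planted effects
  coh <- simulate_cohort(geno, spec, seed = 13)

  panel <- attr(coh, "traits")
  for (t in c("DM", "HT", "CHD")) {
    target <- panel$prevalence[panel$trait == t]
    expect_lt(abs(mean(coh[[t]]) - target),
              3 * sqrt(target * (1 - target) / 20000))
  }
  for (t in c("BMI", "SBP")) {
    expect_lt(abs(mean(coh[[t]]) - panel$mean[panel$trait == t]),
              3 * panel$sd[panel$trait == t] / sqrt(20000))
  }
  expect_true(all(coh$sex %in% 0:1))
  expect_true(all(coh$age >= 40 & coh$age <= 70))
  qt <- panel$trait[panel$type == "quantitative"]
  expect_true(all(as.matrix(coh[, qt]) >= 0))

  # strong specified latent correlation is realized (LDLC-TC at 0.95,
  # slightly reduced by the PSD projection of the default matrix)
  target_r <- spec$latent_cor["LDLC", "TC"]
  expect_lt(abs(cor(coh$LDLC, coh$TC) - target_r), 0.02)

  # two-trait spec with latent correlation 0.9
  traits2 <- trait_panel()[trait_panel()$trait %in% c("SBP", "DBP"), ]
  R2 <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(traits2$trait, traits2$trait))
  spec2 <- effects_spec(traits = traits2, latent_cor = R2)
  coh2 <- simulate_cohort(geno, spec2, seed = 14)
  expect_lt(abs(cor(coh2$SBP, coh2$DBP) - 0.9), 3 * (1 - 0.9^2) / sqrt(20000))
})

test_that("cohort generation is deterministic and validates its inputs", {
  v <- simulate_variants(4, 0.2, 0.5, seed = 21)
  geno <- simulate_genotypes(v, 300, seed = 22)
  spec <- effects_spec()
  expect_identical(simulate_cohort(geno, spec, seed = 5),
                   simulate_cohort(geno, spec, seed = 5))

  bad <- effects_spec(beta = data.frame(variant = "nope", trait = "BMI",
                                        beta = 0.2))
  expect_error(simulate_cohort(geno, bad, seed = 1), "absent")

  nonpsd <- diag(17)
  nonpsd[1, 2] <- nonpsd[2, 1] <- 1.5
  expect_error(effects_spec(latent_cor = nonpsd), "positive semi-definite")

  bad_prev <- trait_panel()
  bad_prev$prevalence[1] <- 0
  expect_error(effects_spec(traits = bad_prev), "prevalence")
})

test_that("a planted quantitative effect is recovered by the scan", {
  v <- simulate_variants(2, 0.3, 0.4, seed = 31)
  geno <- simulate_genotypes(v, 4000, seed = 32)
  spec <- effects_spec(beta = data.frame(variant = v$id[1], trait = "BMI",
                                         beta = 0.3))
  coh <- simulate_cohort(geno, spec, seed = 33)
  panel <- attr(coh, "traits")
  sd_bmi <- panel$sd[panel$trait == "BMI"]
  fit <- fit_linear_wald(coh$BMI, geno$dosages[, 1],
                         cbind(coh$sex, coh$age))
  # planted effect is in SD units; the fit reports trait units
  expect_lt(abs(fit$beta / sd_bmi - 0.3), 3 * fit$se / sd_bmi)
  expect_lt(fit$p, 1e-10)
})

test_that("planted_truth derives concordance signs, blocks and antagonism", {
  expect_equal(nrow(planted_truth(effects_spec())$pairs), 0L)

  traits <- trait_panel()[trait_panel()$trait %in% c("AD", "SBP", "BMI"), ]
  R <- diag(3)
  dimnames(R) <- list(traits$trait, traits$trait)
  R["AD", "SBP"] <- R["SBP", "AD"] <- 0.2
  R["AD", "BMI"] <- R["BMI", "AD"] <- 0.2
  beta <- data.frame(variant = c("v1", "v1", "v1"),
                     trait = c("AD", "SBP", "BMI"),
                     beta = c(0.5, 0.3, -0.3))
  tr <- planted_truth(effects_spec(traits = traits, latent_cor = R,
                                   beta = beta))
  p <- tr$pairs
  # aligned signs with positive correlation: non-antagonistic
  expect_false(p$antagonistic[p$trait == "SBP"])
  # opposite-direction effect against a positive correlation: antagonistic
  expect_true(p$antagonistic[p$trait == "BMI"])
  # different (variant, sign) support means different blocks
  expect_equal(length(unique(tr$blocks)), 2L)

  fx <- planted_fixture()
  expect_equal(length(unique(fx$truth$blocks)), 3L)
  expect_equal(nrow(fx$truth$pairs), 40L)
  expect_setequal(unique(fx$truth$pairs$variant), fx$snps)
})

test_that("null genotypes pass the HWE exact test at the expected rates", {
  vars <- simulate_variants(3000, 0.05, 0.5, seed = 5)
  geno <- simulate_genotypes(vars, 1000, seed = 6)
  qc <- variant_qc(geno)
  # calibration: >= 99% of null variants pass at alpha = 0.001
  expect_gte(mean(qc$hwe_p >= 1e-3), 0.99)
  # rejection rate at alpha = 0.05 within Monte-Carlo error of 0.05
  # (the exact test is slightly conservative by discreteness)
  expect_lt(abs(mean(qc$hwe_p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
})
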