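test_that("individual-level Pearson correlation matches the closed form", {
  x <- rnorm(20)
  expect_equal(pearson_individual(x, x)$r, 1)
  expect_equal(pearson_individual(x, -x)$r, -1)

  set.seed(41)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10)
  est <- pearson_individual(a, b)
  r_closed <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(est$r, r_closed, tolerance = 1e-12)
  tt <- r_closed * sqrt(8 / (1 - r_closed^2))
  expect_equal(est$p, 2 * pt(-abs(tt), 8), tolerance = 1e-12)
  expect_equal(est$n, 10L)

  # incomplete pairs are dropped
  a[1] <- NA
  expect_equal(pearson_individual(a, b)$n, 9L)

  expect_error(pearson_individual(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_individual(1:2, 2:1), "3 complete pairs")
})

test_that("summary-statistic correlation is reflexive, symmetric and guarded", {
  set.seed(43)
  tab <- function(beta, allele = "G") {
    data.frame(variant = sprintf("v%02d", seq_along(beta)),
               effect_allele = allele, beta = beta,
               se = runif(length(beta), 0.05, 0.2), status = "ok",
               stringsAsFactors = FALSE)
  }
  a <- tab(rnorm(30))
  expect_equal(pearson_summary(a, a)$r, 1)
  b <- tab(rnorm(30))
  expect_equal(pearson_summary(a, b)$r, pearson_summary(b, a)$r)
  expect_equal(pearson_summary(a, b)$basis, "summary_statistic")

  flipped <- b
  flipped$effect_allele <- "T"
  expect_error(pearson_summary(a, flipped), "orientation")
  expect_error(pearson_summary(a[1:2, ], b[1:2, ]), "3 shared")

  # beta mode correlates raw effects
  expect_equal(pearson_summary(a, b, method = "beta")$r,
               cor(a$beta, b$beta), tolerance = 1e-12)
})

test_that("summary and individual correlations can disagree in sign", {
  # shared genetics push two traits one way while the environmental
  # correlation pushes the other: the two estimates take opposite signs
  vars <- simulate_variants(40, 0.2, 0.5, seed = 51)
  traits <- trait_panel()[trait_panel()$trait %in% c("SBP", "DBP"), ]
  R <- matrix(c(1, -0.4, -0.4, 1), 2,
              dimnames = list(traits$trait, traits$trait))
  beta <- rbind(
    data.frame(variant = vars$id[1:10], trait = "SBP", beta = 0.15),
    data.frame(variant = vars$id[1:10], trait = "DBP", beta = 0.15)
  )
  spec <- effects_spec(traits = traits, latent_cor = R, beta = beta)
  geno <- simulate_genotypes(vars, 3000, seed = 52)
  coh <- simulate_cohort(geno, spec, seed = 53)
  ind <- pearson_individual(coh$SBP, coh$DBP)
  assoc <- run_ewas(coh, geno)
  summ <- pearson_summary(assoc[assoc$trait == "SBP", ],
                          assoc[assoc$trait == "DBP", ])
  expect_lt(ind$r, 0)
  expect_gt(summ$r, 0)
  expect_lt(ind$p, 0.05)
  expect_lt(summ$p, 0.05)
})

test_that("exact 2x2 test reproduces published case/control contrasts", {
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  # anchor cases/controls split by diabetes status
  expect_lt(abs(fisher_exact_2x2(53, 308, 11015, 176884) - 1.33e-9) / 1.33e-9,
            0.05)
  # anchor cases/controls split by heart-failure status
  expect_lt(abs(fisher_exact_2x2(20, 341, 3236, 184663) - 6.867e-6) / 6.867e-6,
            0.05)
  # hypertension contrast is far beyond double-print precision
  expect_lt(fisher_exact_2x2(189, 172, 45349, 142550), 2.2e-16)
  # frozen enumeration value
  expect_equal(fisher_exact_2x2(3, 7, 5, 5), 0.649916646820672,
               tolerance = 1e-12)

  expect_warning(p <- fisher_exact_2x2(0, 0, 4, 6), "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("exact 2x2 test agrees with enumeration and fisher.test", {
  set.seed(47)
  for (rep in 1:200) {
    tot <- sample(4:300, 1)
    cells <- as.vector(rmultinom(1, tot, runif(4, 0.05, 1)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, fisher2x2_enum_oracle(cells[1], cells[2],
                                            cells[3], cells[4]),
                 tolerance = 1e-10)
    expect_equal(got, fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("antagonism is misalignment of effect product and correlation", {
  # adverse anchor effect, protective trait effect, positive correlation
  expect_true(classify_antagonism(0.488, -0.05, 0.0248)$antagonistic)
  # opposite-direction effects aligned with a negative correlation
  expect_false(classify_antagonism(1.371, -0.2, -0.0066)$antagonistic)
  # full alignment
  expect_false(classify_antagonism(1, 1, 0.5)$antagonistic)

  # invariance under double sign flip; antisymmetry under single flips
  set.seed(53)
  ba <- rnorm(40); bt <- rnorm(40); r <- rnorm(40)
  keep <- ba != 0 & bt != 0 & r != 0
  ba <- ba[keep]; bt <- bt[keep]; r <- r[keep]
  expect_equal(classify_antagonism(-ba, -bt, r)$antagonistic,
               classify_antagonism(ba, bt, r)$antagonistic)
  expect_equal(classify_antagonism(-ba, bt, r)$antagonistic,
               !classify_antagonism(ba, bt, r)$antagonistic)
  expect_equal(classify_antagonism(ba, -bt, r)$antagonistic,
               !classify_antagonism(ba, bt, r)$antagonistic)

  # non-significant correlations are not evaluable and never antagonistic
  call <- classify_antagonism(1, -1, 0.01, r_p = 0.4)
  expect_false(call$evaluable)
  expect_false(call$antagonistic)
  expect_error(classify_antagonism(Inf, 1, 0.1), "finite")
})

test_that("antagonism summaries count pairs and clusters", {
  calls <- data.frame(
    trait = rep(c("T1", "T2", "T3", "T4"), c(6, 6, 5, 4)),
    antagonistic = rep(FALSE, 21),
    evaluable = TRUE
  )
  labels <- c(T1 = 1L, T2 = 1L, T3 = 2L, T4 = 3L)
  s0 <- summarize_antagonism(calls, labels)
  expect_equal(s0$overall$fraction, 0)

  calls$antagonistic[c(1:3, 7:9, 13)] <- TRUE  # 7 of 21
  s <- summarize_antagonism(calls, labels)
  expect_equal(s$overall$n, 21L)
  expect_equal(s$overall$n_antagonistic, 7L)
  expect_equal(s$overall$fraction, 1 / 3)
  expect_equal(s$clusters$n_with_antagonism, 2L)
  expect_equal(s$per_cluster$contains_antagonism, c(TRUE, TRUE, FALSE))

  expect_error(summarize_antagonism(calls, labels[1:2]), "unlabeled")
})
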