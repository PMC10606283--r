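test_that("p-value categories follow the five-level scale", {
  expect_equal(categorize_p(0.1), 0L)
  expect_equal(categorize_p(1e-5), 2L)
  expect_equal(categorize_p(1e-9), 4L)
  # boundaries: lower bound belongs to the category, 0.05 maps to 0
  expect_equal(categorize_p(c(0.05, 5e-4, 5e-6, 5e-8)), c(0L, 1L, 2L, 3L))
  expect_equal(categorize_p(1), 0L)
  expect_error(categorize_p(0), "p")
  expect_error(categorize_p(1.2), "p")
})

test_that("signed entries orient by effect-direction concordance", {
  # published rows: strongly protective lipid effect against an adverse
  # anchor effect -> -4; concordant adverse effects -> +4
  expect_equal(signed_entry(0.960, -5.450, 2.81e-20), -4L)
  expect_equal(signed_entry(0.393, 1.206, 1.09e-10), 4L)
  # category 0 annihilates the sign
  expect_equal(signed_entry(1.2, -3.4, 0.5), 0L)
  expect_error(signed_entry(0, 1, 0.01), "beta_ad")

  # allele-flip invariance: flipping both effects leaves the entry unchanged
  set.seed(13)
  ba <- rnorm(50); bt <- rnorm(50); p <- runif(50)
  ba[ba == 0] <- 0.1
  expect_equal(signed_entry(-ba, -bt, p), signed_entry(ba, bt, p))
})

test_that("index SNP selection picks the smallest p with deterministic ties", {
  assoc <- data.frame(
    variant = c("a", "b", "c", "d", "e"),
    pos = c(10L, 5L, 7L, 20L, 1L),
    p = c(1e-5, 1e-9, 1e-9, 2e-3, NA)
  )
  loci <- c(a = "L1", b = "L1", c = "L1", d = "L2", e = "L3")
  idx <- select_index_snps(assoc, loci)
  # L1: b and c tie at 1e-9, b wins on position; L3 has only a failed fit
  expect_setequal(idx, c("b", "d"))

  # brute-force comparison on random instances
  set.seed(29)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    a <- data.frame(variant = sprintf("v%02d", 1:k),
                    pos = sample(1000L, k),
                    p = signif(runif(k), 1))   # coarse p-values force ties
    lo <- stats::setNames(sample(c("A", "B"), k, replace = TRUE), a$variant)
    got <- select_index_snps(a, lo)
    want <- vapply(split(a, lo[a$variant]), function(d) {
      d <- d[order(d$p, d$pos, d$variant), ]
      d$variant[1]
    }, "")
    expect_setequal(got, unname(want))
  }
})

test_that("signed matrix applies SNP and phenotype selection rules", {
  snps <- c("s1", "s2", "s3")
  traits <- c("AD", "T1", "T2", "T3")
  grid <- expand.grid(variant = snps, trait = traits,
                      stringsAsFactors = FALSE)
  assoc <- data.frame(
    grid, chrom = "1", pos = 1L, effect_allele = "G", other_allele = "A",
    maf = 0.3, beta = 1, se = 0.1, p = 1e-9, n_used = 100L, status = "ok",
    stringsAsFactors = FALSE
  )
  # T3 is associated only through s1; T1/T2 qualify everywhere
  assoc$p[assoc$trait == "T3" & assoc$variant != "s1"] <- 0.9
  assoc$beta[assoc$trait == "T2"] <- -1     # discordant trait
  pleio <- run_pairwise_pleiotropy(assoc)
  A <- build_signed_matrix(assoc, pleio)
  expect_equal(dim(A), c(3L, 2L))
  expect_setequal(colnames(A), c("T1", "T2"))  # singleton T3 dropped
  expect_true(all(A[, "T1"] == 4L))
  expect_true(all(A[, "T2"] == -4L))

  # with min_trait_pairs = 1 the singleton column is kept
  A1 <- build_signed_matrix(assoc, pleio,
                            selection_rules(min_trait_pairs = 1L))
  expect_true("T3" %in% colnames(A1))
  expect_equal(sum(A1[, "T3"] != 0), 1L)

  # nothing to cluster when the anchor filter removes every SNP
  assoc2 <- assoc
  assoc2$p[assoc2$trait == "AD"] <- 0.5
  pleio2 <- run_pairwise_pleiotropy(assoc2)
  expect_error(build_signed_matrix(assoc2, pleio2), "nothing to cluster")
})

test_that("Ward linkage matches hand and brute-force oracles", {
  # two identical rows merge at height zero
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  tr <- ward_linkage(m, "rows")
  expect_equal(tr$height[1], 0)

  # 1-D items {0, 1, 10}: first merge at distance 1, then the
  # Lance-Williams update gives sqrt((2*100 + 2*81 - 1)/3)
  m2 <- matrix(c(0, 1, 10), ncol = 1,
               dimnames = list(c("x", "y", "z"), NULL))
  tr2 <- ward_linkage(m2, "rows")
  expect_equal(tr2$height, c(1, sqrt(361 / 3)), tolerance = 1e-12)

  # every greedy merge minimises the within-cluster variance increase
  set.seed(31)
  for (rep in 1:15) {
    k <- sample(4:7, 1)
    x <- matrix(rnorm(k * 3), k)
    rownames(x) <- sprintf("r%d", seq_len(k))
    tree <- ward_linkage(x, "rows")
    oracle <- ward_greedy_oracle(x)
    got <- hclust_merge_members(tree)
    expect_equal(got, lapply(oracle, `[[`, "members"))
    # ward.D2 heights are sqrt(2 * delta-SS) of the greedy merge
    expect_equal(tree$height,
                 sqrt(2 * vapply(oracle, `[[`, 0, "dss")),
                 tolerance = 1e-9)
    # no inversions
    expect_true(all(diff(tree$height) >= -1e-12))
  }

  expect_error(ward_linkage(matrix(c(1, NA), 1)), "undefined")
})

test_that("tree cuts produce stable connected-component labels", {
  x <- matrix(c(0, 0.1, 5, 5.1, 20), ncol = 1,
              dimnames = list(letters[1:5], NULL))
  tree <- ward_linkage(x, "rows")
  expect_equal(length(unique(cut_tree(tree, max(tree$height) + 1))), 1L)
  expect_equal(length(unique(cut_tree(tree, 0))), 5L)
  labs <- cut_tree(tree, 2)
  expect_equal(unname(labs[c("a", "b")]), c(1L, 1L))
  expect_equal(unname(labs[c("c", "d")]), c(2L, 2L))
  expect_equal(unname(labs["e"]), 3L)
  # labels are renumbered in order of first appearance
  expect_equal(unique(unname(labs)), seq_along(unique(labs)))

  # single-leaf tree
  tr1 <- ward_linkage(matrix(1, 1, 2, dimnames = list("only", NULL)), "rows")
  expect_equal(cut_tree(tr1, 5), c(only = 1L))
})

test_that("correlation-distance clustering handles twins, negations and constants", {
  set.seed(37)
  base <- rnorm(8)
  m <- cbind(A = base, B = base + rnorm(8, sd = 1e-8), C = rnorm(8),
             D = -base)
  rownames(m) <- sprintf("s%d", 1:8)
  cc <- correlation_cluster(m)
  # the duplicated column pair merges first, at (near) zero height
  members <- hclust_merge_members(cc$columns)
  first <- cc$columns$labels[members[[1]]]
  expect_setequal(first, c("A", "B"))
  expect_lt(cc$columns$height[1], 1e-6)

  # a column and its negation sit at distance 2: in a 3-column instance
  # they are never the first merge, joining only at the root
  m3 <- m[, c("A", "C", "D")]
  expect_equal((1 - cor(m3))["A", "D"], 2, tolerance = 1e-12)
  cc3 <- correlation_cluster(m3)$columns
  first3 <- cc3$labels[hclust_merge_members(cc3)[[1]]]
  expect_false(setequal(first3, c("A", "D")))

  mz <- cbind(m, E = rep(1, 8))
  expect_warning(correlation_cluster(mz), "zero-variance")
})

test_that("clustering is invariant to input permutation up to relabeling", {
  fx <- planted_fixture()
  fit <- planted_fit()
  A <- fit$matrix
  perm_r <- sample(nrow(A)); perm_c <- sample(ncol(A))
  B <- A[perm_r, perm_c]
  la <- cut_tree(ward_linkage(A, "columns"), 5)
  lb <- cut_tree(ward_linkage(B, "columns"), 5)
  expect_equal(ari(la[colnames(A)], lb[colnames(A)]), 1)
})
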