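# Shared fixtures and independent oracles used across test files.

# Independent enumeration oracle for the exact conditional Hardy-Weinberg
# test: direct factorial formula for the conditional probability of each
# heterozygote count, normalised numerically.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (nA == 0) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- hets * log(2) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - nA - hets) / 2 + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Enumeration oracle for the two-sided 2x2 exact test: hypergeometric point
# probabilities computed from binomial coefficients (no log-space tricks).
fisher2x2_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d
  support <- max(0, r1 - c2):min(r1, c1)
  lp <- lchoose(c1, support) + lchoose(c2, r1 - support) -
    lchoose(c1 + c2, r1)
  p <- exp(lp)
  obs <- p[match(a, support)]
  min(sum(p[p <= obs * (1 + 1e-7)]), 1)
}

# Greedy Ward oracle: at each step merge the pair of clusters whose union
# minimally increases total within-cluster sum of squares (brute force over
# all pairs). Returns the merge partitions and the increase at each step.
ward_greedy_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  steps <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        mi <- colMeans(x[clusters[[i]], , drop = FALSE])
        mj <- colMeans(x[clusters[[j]], , drop = FALSE])
        ni <- length(clusters[[i]]); nj <- length(clusters[[j]])
        dss <- ni * nj / (ni + nj) * sum((mi - mj)^2)
        if (is.null(best) || dss < best$dss) best <- list(i = i, j = j,
                                                          dss = dss)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    steps[[length(steps) + 1L]] <- list(members = merged, dss = best$dss)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  steps
}

# Leaf sets below each internal node of an hclust tree, in merge order.
hclust_merge_members <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    mem <- integer(0)
    for (s in tree$merge[k, ]) {
      mem <- c(mem, if (s < 0) -s else members[[s]])
    }
    members[[k]] <- sort(mem)
  }
  members
}

# Adjusted Rand index between two labelings (independent implementation so
# cluster-recovery checks do not depend on the package's own code paths).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small planted-demo fixture shared by recovery tests (cached per session).
planted_fixture <- local({
  cache <- NULL
  function(n = 4000L, m = 300L, seed = 101L) {
    if (!is.null(cache)) return(cache)
    vars <- simulate_variants(m, 0.005, 0.5, seed = seed)
    common <- vars$id[vars$true_maf >= 0.2][1:13]
    spec <- planted_demo_spec(common)
    geno <- simulate_genotypes(vars, n, missing_rate = 0.02, seed = seed + 1L)
    coh <- simulate_cohort(geno, spec, seed = seed + 2L)
    truth <- planted_truth(spec,
                           maf = stats::setNames(vars$true_maf, vars$id))
    cache <<- list(vars = vars, spec = spec, geno = geno, cohort = coh,
                   truth = truth, snps = common)
    cache
  }
})

# The corresponding fitted scan, also cached (pleio_scan is deterministic).
planted_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- pleio_scan(planted_fixture()$geno,
                                             planted_fixture()$cohort)
    cache
  }
})
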