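## Signed five-category association matrix and two-axis hierarchical
## clustering. The matrix entry for SNP i and phenotype j carries the sign of
## the effect-direction concordance with the anchor disease and a magnitude
## in 0..4 encoding the univariate p-value category; Ward clustering of rows
## (SNPs) and columns (phenotypes) on Euclidean distances is the main
## approach, with a correlation-distance pass for validation.

#' Five-level p-value category scale
#'
#' Categories: 4 for `p < 5e-8`, 3 for `5e-8 <= p < 5e-6`, 2 for
#' `5e-6 <= p < 5e-4`, 1 for `5e-4 <= p < 5e-2`, 0 otherwise. The boundary
#' `p = 0.05` maps to 0 (conservative toward "no evidence").
#'
#' @param breaks Strictly increasing thresholds separating categories 4|3,
#'   3|2, 2|1, 1|0.
#' @return A list of class `category_scale`.
#' @export
category_scale <- function(breaks = c(5e-8, 5e-6, 5e-4, 5e-2)) {
  stopifnot(length(breaks) == 4L, all(diff(breaks) > 0),
            all(breaks > 0 & breaks < 1))
  structure(list(breaks = breaks), class = "category_scale")
}

#' Categorise a univariate p-value into 0..4
#'
#' @param p P-values in `(0, 1]` (vectorised).
#' @param scale A [category_scale()].
#' @return Integer vector in `0:4`.
#' @export
#' @examples
#' categorize_p(c(0.1, 1e-5, 1e-9))  # 0, 2, 4
categorize_p <- function(p, scale = category_scale()) {
  check_p(p)
  ifelse(p >= scale$breaks[4], 0L,
         4L - findInterval(p, scale$breaks[1:3]))
}

#' Signed matrix entry for one SNP-phenotype pair
#'
#' The sign is the effect-direction concordance with the anchor disease,
#' `sign(beta_ad * beta_trait)` (equivalently: orient the allele so the
#' anchor effect is adverse and take the trait effect's sign); the magnitude
#' is the univariate p-value category of the trait association. Vectorised.
#'
#' @param beta_ad Anchor-trait effect (must be non-zero: a zero anchor effect
#'   leaves the allele orientation undefined).
#' @param beta_trait Trait effect.
#' @param p_trait Univariate trait p-value.
#' @param scale A [category_scale()].
#' @return Integer vector in `-4:4`.
#' @export
signed_entry <- function(beta_ad, beta_trait, p_trait,
                         scale = category_scale()) {
  if (any(!is.finite(beta_ad)) || any(beta_ad == 0)) {
    stop("'beta_ad' must be non-zero (allele orientation undefined)",
         call. = FALSE)
  }
  sign_int(beta_ad * beta_trait) * categorize_p(p_trait, scale)
}

#' Selection rules for the signed matrix
#'
#' @param p_ad_max Anchor-association threshold for a SNP to enter the matrix
#'   (default 5e-4).
#' @param pleio_p_max Combined-p threshold defining a "qualifying"
#'   pleiotropic pair (default 5e-6).
#' @param p_trait_max Univariate trait-p filter a qualifying pair must also
#'   satisfy (default 5e-2, matching the tier rules; without it, a SNP with
#'   an extremely small anchor p-value would qualify against every trait).
#' @param min_snp_pairs Minimum qualifying pairs for a SNP row (default 1).
#' @param min_trait_pairs Minimum qualifying pairs for a phenotype column
#'   (default 2; a phenotype represented by a single association is dropped).
#' @param height Dendrogram height cut used downstream (default 5).
#' @return A list of class `selection_rules`.
#' @export
selection_rules <- function(p_ad_max = 5e-4, pleio_p_max = 5e-6,
                            p_trait_max = 5e-2,
                            min_snp_pairs = 1L, min_trait_pairs = 2L,
                            height = 5) {
  check_fraction(c(p_ad_max, pleio_p_max, p_trait_max), "thresholds",
                 lo_open = TRUE, hi_open = TRUE)
  stopifnot(min_snp_pairs >= 1L, min_trait_pairs >= 1L, height >= 0)
  structure(list(p_ad_max = p_ad_max, pleio_p_max = pleio_p_max,
                 p_trait_max = p_trait_max,
                 min_snp_pairs = as.integer(min_snp_pairs),
                 min_trait_pairs = as.integer(min_trait_pairs),
                 height = height),
            class = "selection_rules")
}

#' Select one index SNP per locus
#'
#' Within each locus the variant with the smallest anchor-trait p-value is
#' kept; exact ties are broken by smaller position, then lexicographic id.
#'
#' @param assoc_ad Association records for the anchor trait (columns
#'   `variant`, `pos`, `p`).
#' @param loci Named vector or `data.frame(variant, locus)` assigning every
#'   variant in `assoc_ad` to exactly one locus.
#' @return Character vector of index-SNP ids (one per non-empty locus).
#' @export
select_index_snps <- function(assoc_ad, loci) {
  stopifnot(is.data.frame(assoc_ad),
            all(c("variant", "pos", "p") %in% names(assoc_ad)))
  if (is.data.frame(loci)) loci <- stats::setNames(loci$locus, loci$variant)
  if (!all(assoc_ad$variant %in% names(loci))) {
    stop("every variant must be assigned to a locus", call. = FALSE)
  }
  a <- assoc_ad[!is.na(assoc_ad$p), ]
  if (!nrow(a)) return(character(0))
  a$locus <- loci[a$variant]
  a <- a[order(a$locus, a$p, a$pos, a$variant), ]
  a$variant[!duplicated(a$locus)]
}

#' Build the signed SNP-by-phenotype category matrix
#'
#' Rows are SNPs whose anchor association satisfies `p_ad < p_ad_max` and
#' that carry at least `min_snp_pairs` qualifying pleiotropic pairs
#' (`p_fisher < pleio_p_max`); columns are non-anchor phenotypes with at
#' least `min_trait_pairs` qualifying pairs among the selected SNPs. Entries
#' are [signed_entry()] applied to the univariate trait statistics; cells
#' whose univariate fit failed are set to 0.
#'
#' @param assoc Association table from [run_ewas()].
#' @param pleio Pleiotropy table from [run_pairwise_pleiotropy()].
#' @param rules A [selection_rules()] object.
#' @param scale A [category_scale()].
#' @param anchor_trait Anchor trait name (default `"AD"`).
#' @param index_snps Optional character vector restricting candidate rows
#'   (e.g. from [select_index_snps()]).
#' @return Integer matrix with SNP ids as rownames and phenotype names as
#'   colnames.
#' @export
build_signed_matrix <- function(assoc, pleio, rules = selection_rules(),
                                scale = category_scale(),
                                anchor_trait = "AD", index_snps = NULL) {
  anchor <- assoc[assoc$trait == anchor_trait & assoc$status == "ok", ]
  if (!is.null(index_snps)) anchor <- anchor[anchor$variant %in% index_snps, ]
  anchor <- anchor[!is.na(anchor$p) & anchor$p < rules$p_ad_max, ]
  qual <- pleio[pleio$variant %in% anchor$variant &
                  pleio$p_fisher < rules$pleio_p_max &
                  pleio$p_trait < rules$p_trait_max, ]
  snp_counts <- table(qual$variant)
  snps <- names(snp_counts)[snp_counts >= rules$min_snp_pairs]
  trait_counts <- table(qual$trait[qual$variant %in% snps])
  phenos <- names(trait_counts)[trait_counts >= rules$min_trait_pairs]
  if (!length(snps) || !length(phenos)) {
    stop("nothing to cluster: no SNPs/phenotypes pass the selection rules",
         call. = FALSE)
  }
  snps <- anchor$variant[anchor$variant %in% snps]  # keep anchor order
  phenos <- sort(phenos)
  beta_ad <- stats::setNames(anchor$beta, anchor$variant)
  A <- matrix(0L, length(snps), length(phenos),
              dimnames = list(snps, phenos))
  sub <- assoc[assoc$variant %in% snps & assoc$trait %in% phenos, ]
  for (i in seq_len(nrow(sub))) {
    if (sub$status[i] != "ok" || is.na(sub$p[i])) next
    A[sub$variant[i], sub$trait[i]] <-
      signed_entry(beta_ad[[sub$variant[i]]], sub$beta[i], sub$p[i], scale)
  }
  A
}

#' Ward hierarchical clustering of matrix rows or columns
#'
#' Agglomerative clustering of the chosen axis on Euclidean distances under
#' Ward's minimum-variance criterion (the squared-distance Lance-Williams
#' update, `hclust` method `"ward.D2"`, whose merge heights are guaranteed
#' monotone). The legacy criterion operating on unsquared distances
#' (`"ward.D"`) is available behind the `method` flag.
#'
#' @param mat Numeric matrix without undefined entries.
#' @param axis `"rows"` or `"columns"`.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return An object of class `hclust`.
#' @export
ward_linkage <- function(mat, axis = c("rows", "columns"),
                         method = c("ward.D2", "ward.D")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (anyNA(mat)) stop("matrix contains undefined entries", call. = FALSE)
  x <- if (axis == "rows") mat else t(mat)
  if (nrow(x) == 1L) {  # trivial single-leaf tree
    return(structure(
      list(merge = matrix(integer(0), 0L, 2L), height = numeric(0),
           order = 1L, labels = rownames(x), method = method,
           dist.method = "euclidean"),
      class = "hclust"
    ))
  }
  stats::hclust(stats::dist(x), method = method)
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected components left after removing merges above the
#' cut; labels are renumbered in order of first appearance so they are stable
#' across platforms.
#'
#' @param tree An `hclust` object.
#' @param height Cut height (>= 0).
#' @return Named integer vector of cluster labels, one per leaf.
#' @export
cut_tree <- function(tree, height = 5) {
  stopifnot(inherits(tree, "hclust"), height >= 0)
  if (nrow(tree$merge) == 0L) {
    return(stats::setNames(1L, tree$labels))
  }
  labels <- stats::cutree(tree, h = height)
  stats::setNames(match(labels, unique(labels)), names(labels))
}

#' Correlation-distance validation clustering
#'
#' Ward clustering of both axes with `1 - Pearson correlation` between item
#' vectors as the distance. Zero-variance items cannot be correlated and are
#' excluded with a warning.
#'
#' @param mat Numeric matrix.
#' @param method Ward flavour, as in [ward_linkage()].
#' @return List with elements `rows` and `columns`, each an `hclust`.
#' @export
correlation_cluster <- function(mat, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  cluster_axis <- function(x, what) {
    v <- apply(x, 1L, stats::var)
    if (any(v == 0)) {
      warning(sprintf("excluding %d zero-variance %s", sum(v == 0), what))
      x <- x[v > 0, , drop = FALSE]
    }
    if (nrow(x) < 2L) {
      stop("need at least 2 variable items on the ", what, " axis",
           call. = FALSE)
    }
    stats::hclust(stats::as.dist(1 - stats::cor(t(x))), method = method)
  }
  list(rows = cluster_axis(mat, "rows"),
       columns = cluster_axis(t(mat), "columns"))
}
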