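## End-to-end anchor-centric pleiotropy analysis. `pleio_scan()` chains the
## stages -- variant QC, univariate scan, pair-wise Fisher combination,
## signed-matrix construction, two-axis Ward clustering with the
## correlation-distance validation pass, and antagonism classification --
## into one classed result object.

#' Anchor-centric pleiotropy scan
#'
#' Runs the full analysis on a genotype matrix and a phenotype table:
#'
#' 1. per-variant QC (MAF, call rate, Hardy-Weinberg exact test);
#' 2. univariate association scan of every QC-passing variant against every
#'    trait, additive coding, sex+age adjusted, Wald inference;
#' 3. pair-wise pleiotropy: Fisher's combined test of the anchor p-value with
#'    each other trait's p-value, with genome-wide / suggestive tiers;
#' 4. index-SNP selection (smallest anchor p per locus) and construction of
#'    the signed p-value-category SNP-by-phenotype matrix;
#' 5. Ward clustering of both matrix axes on Euclidean distances, plus a
#'    correlation-distance validation clustering, with a height cut giving
#'    the cluster labels;
#' 6. antagonistic-heterogeneity classification of the qualifying pairs
#'    against the individual-level anchor-trait correlations.
#'
#' Stages 4-6 require at least one qualifying SNP and two phenotypes; when
#' the selection rules leave nothing to cluster (e.g. on null data) the
#' object is returned with those components `NULL` and a note.
#'
#' @param genotypes A `genotype_matrix`.
#' @param cohort Phenotype table with `sex`, `age` and trait columns (trait
#'   panel in `attr(, "traits")`, see [simulate_cohort()]).
#' @param anchor Anchor trait name (default `"AD"`).
#' @param qc A [qc_thresholds()] object.
#' @param tiers A [tier_thresholds()] object.
#' @param rules A [selection_rules()] object (also carries the height cut).
#' @param scale A [category_scale()] object.
#' @param loci Optional variant-to-locus assignment (named vector or
#'   `data.frame(variant, locus)`); by default every variant is its own
#'   locus, i.e. no index-SNP thinning.
#' @param corr_alpha Significance gate on the anchor-trait correlation below
#'   which antagonism is evaluable (default 0.05).
#' @return An object of class `pleio_scan`: a list with components `qc`,
#'   `assoc`, `pleio`, `index_snps`, `matrix`, `snp_tree`, `pheno_tree`,
#'   `validation` (correlation-distance trees), `snp_clusters`,
#'   `pheno_clusters`, `correlations`, `antagonism`, `antagonism_summary`,
#'   `anchor`, `settings`, `note`.
#' @export
#' @examples
#' vars <- simulate_variants(40, 0.1, 0.5, seed = 1)
#' geno <- simulate_genotypes(vars, 300, seed = 2)
#' spec <- effects_spec()
#' cohort <- simulate_cohort(geno, spec, seed = 3)
#' fit <- pleio_scan(geno, cohort)
#' print(fit)
pleio_scan <- function(genotypes, cohort, anchor = "AD",
                       qc = qc_thresholds(), tiers = tier_thresholds(),
                       rules = selection_rules(), scale = category_scale(),
                       loci = NULL, corr_alpha = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  qc_report <- variant_qc(genotypes, qc)
  keep <- qc_report$id[qc_report$pass_all]
  if (!length(keep)) stop("no variants pass QC", call. = FALSE)
  gpass <- genotype_matrix(
    genotypes$variants[match(keep, genotypes$variants$id), ],
    genotypes$dosages[, keep, drop = FALSE]
  )
  assoc <- run_ewas(cohort, gpass)
  pleio <- run_pairwise_pleiotropy(assoc, anchor_trait = anchor,
                                   thresholds = tiers)
  anchor_assoc <- assoc[assoc$trait == anchor & assoc$status == "ok", ]
  index <- if (is.null(loci)) {
    anchor_assoc$variant       # one variant per locus by default
  } else {
    select_index_snps(anchor_assoc, loci)
  }
  out <- list(
    qc = qc_report, assoc = assoc, pleio = pleio, index_snps = index,
    matrix = NULL, snp_tree = NULL, pheno_tree = NULL, validation = NULL,
    snp_clusters = NULL, pheno_clusters = NULL, correlations = NULL,
    antagonism = NULL, antagonism_summary = NULL,
    anchor = anchor,
    settings = list(qc = qc, tiers = tiers, rules = rules, scale = scale,
                    corr_alpha = corr_alpha),
    note = NULL
  )
  A <- tryCatch(
    build_signed_matrix(assoc, pleio, rules, scale, anchor_trait = anchor,
                        index_snps = index),
    error = function(e) conditionMessage(e)
  )
  if (is.character(A)) {
    out$note <- A
    class(out) <- "pleio_scan"
    return(out)
  }
  out$matrix <- A
  out$snp_tree <- ward_linkage(A, "rows")
  out$pheno_tree <- ward_linkage(A, "columns")
  out$validation <- tryCatch(correlation_cluster(A),
                             error = function(e) conditionMessage(e))
  out$snp_clusters <- cut_tree(out$snp_tree, rules$height)
  out$pheno_clusters <- cut_tree(out$pheno_tree, rules$height)

  ## individual-level anchor-trait correlations for the matrix phenotypes
  out$correlations <- do.call(rbind, lapply(colnames(A), function(t) {
    est <- pearson_individual(cohort[[anchor]], cohort[[t]])
    cbind(trait = t, est, stringsAsFactors = FALSE)
  }))

  ## antagonism calls for the qualifying pairs inside the matrix
  qual <- out$pleio[out$pleio$p_fisher < rules$pleio_p_max &
                      out$pleio$p_trait < rules$p_trait_max &
                      out$pleio$variant %in% rownames(A) &
                      out$pleio$trait %in% colnames(A), ]
  if (nrow(qual)) {
    akey <- paste(out$assoc$variant, out$assoc$trait)
    beta_of <- function(v, t) out$assoc$beta[match(paste(v, t), akey)]
    r_of <- stats::setNames(out$correlations$r, out$correlations$trait)
    rp_of <- stats::setNames(out$correlations$p, out$correlations$trait)
    calls <- classify_antagonism(
      beta_ad = beta_of(qual$variant, rep(anchor, nrow(qual))),
      beta_trait = beta_of(qual$variant, qual$trait),
      r_ad_trait = r_of[qual$trait],
      r_p = rp_of[qual$trait],
      alpha = corr_alpha
    )
    out$antagonism <- cbind(qual[, c("variant", "trait")], calls)
    rownames(out$antagonism) <- NULL
    out$antagonism_summary <- summarize_antagonism(out$antagonism,
                                                   out$pheno_clusters)
  }
  class(out) <- "pleio_scan"
  out
}

#' @export
print.pleio_scan <- function(x, ...) {
  cat("Anchor-centric pleiotropy scan (anchor: ", x$anchor, ")\n", sep = "")
  cat(sprintf("  variants: %d scanned, %d pass QC\n",
              nrow(x$qc), sum(x$qc$pass_all)))
  cat(sprintf("  association records: %d; pleiotropic pairs: %d (GW: %d, suggestive: %d)\n",
              nrow(x$assoc), nrow(x$pleio),
              sum(x$pleio$tier == "GW"), sum(x$pleio$tier == "SUGGESTIVE")))
  if (is.null(x$matrix)) {
    cat("  signed matrix: none (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf("  signed matrix: %d SNPs x %d phenotypes; %d SNP / %d phenotype clusters at height %g\n",
                nrow(x$matrix), ncol(x$matrix),
                length(unique(x$snp_clusters)),
                length(unique(x$pheno_clusters)),
                x$settings$rules$height))
    if (!is.null(x$antagonism_summary)) {
      s <- x$antagonism_summary
      cat(sprintf("  antagonistic heterogeneity: %d of %d evaluable pairs (%.0f%%) in %d of %d clusters\n",
                  s$overall$n_antagonistic, s$overall$n,
                  100 * s$overall$fraction,
                  s$clusters$n_with_antagonism, s$clusters$n))
    }
  }
  invisible(x)
}

#' @export
summary.pleio_scan <- function(object, ...) {
  structure(
    list(
      anchor = object$anchor,
      n_variants = nrow(object$qc),
      n_pass_qc = sum(object$qc$pass_all),
      qc_fail = c(maf = sum(!object$qc$pass_maf),
                  callrate = sum(!object$qc$pass_callrate),
                  hwe = sum(!object$qc$pass_hwe)),
      tiers = table(object$pleio$tier),
      matrix_dim = if (!is.null(object$matrix)) dim(object$matrix),
      pheno_clusters = object$pheno_clusters,
      snp_clusters = object$snp_clusters,
      antagonism = object$antagonism_summary,
      note = object$note
    ),
    class = "summary.pleio_scan"
  )
}

#' @export
print.summary.pleio_scan <- function(x, ...) {
  cat("pleio_scan summary (anchor: ", x$anchor, ")\n", sep = "")
  cat(sprintf("  QC: %d / %d variants pass (fail maf=%d, callrate=%d, hwe=%d)\n",
              x$n_pass_qc, x$n_variants, x$qc_fail["maf"],
              x$qc_fail["callrate"], x$qc_fail["hwe"]))
  cat("  pleiotropy tiers:\n")
  print(x$tiers)
  if (!is.null(x$matrix_dim)) {
    cat(sprintf("  signed matrix: %d x %d\n", x$matrix_dim[1],
                x$matrix_dim[2]))
    cat("  phenotype clusters:\n")
    print(split(names(x$pheno_clusters), x$pheno_clusters))
  } else if (!is.null(x$note)) {
    cat("  note: ", x$note, "\n", sep = "")
  }
  if (!is.null(x$antagonism)) {
    cat(sprintf("  antagonistic pairs: %d / %d (%.0f%%)\n",
                x$antagonism$overall$n_antagonistic, x$antagonism$overall$n,
                100 * x$antagonism$overall$fraction))
  }
  invisible(x)
}

#' Plot a pleiotropy scan
#'
#' Draws the signed category matrix as an image with the two dendrograms,
#' or (with `which = "dendrogram"`) the phenotype dendrogram with the height
#' cut marked.
#'
#' @param x A `pleio_scan` object with a non-`NULL` matrix.
#' @param which `"matrix"` or `"dendrogram"`.
#' @param ... Passed to [graphics::image()] / [plot()].
#' @export
plot.pleio_scan <- function(x, which = c("matrix", "dendrogram"), ...) {
  which <- match.arg(which)
  if (is.null(x$matrix)) stop("nothing to plot: ", x$note, call. = FALSE)
  if (which == "dendrogram") {
    plot(x$pheno_tree, main = "Phenotype clustering (Ward, Euclidean)",
         xlab = "", sub = "", ...)
    graphics::abline(h = x$settings$rules$height, lty = 2, col = "grey40")
    return(invisible(x))
  }
  A <- x$matrix[x$snp_tree$order, x$pheno_tree$order, drop = FALSE]
  pal <- grDevices::hcl.colors(9, "Blue-Red 2")
  graphics::image(seq_len(ncol(A)), seq_len(nrow(A)), t(A),
                  zlim = c(-4, 4), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(A)), colnames(A), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(nrow(A)), rownames(A), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects paths (or in-memory objects), thresholds and the seed for a
#' deterministic end-to-end run.
#'
#' @param genotypes A `genotype_matrix`, or the path of a dosage TSV /
#'   `.vcf` file.
#' @param phenotypes A cohort `data.frame`, or the path of a phenotype TSV.
#' @param out_dir Output directory (created if missing).
#' @param anchor Anchor trait name.
#' @param loci Optional variant-to-locus map (named vector, `data.frame`, or
#'   path to a two-column TSV `variant locus`).
#' @param seed Seed recorded in all outputs.
#' @param qc,tiers,rules,scale Stage settings, see [pleio_scan()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, out_dir,
                            anchor = "AD", loci = NULL, seed = 1L,
                            qc = qc_thresholds(), tiers = tier_thresholds(),
                            rules = selection_rules(),
                            scale = category_scale()) {
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 out_dir = out_dir, anchor = anchor, loci = loci,
                 seed = seed, qc = qc, tiers = tiers, rules = rules,
                 scale = scale),
            class = "pipeline_config")
}

#' Run the full pipeline and persist every stage's output
#'
#' Executes QC, the association scan, pleiotropy, signed-matrix construction,
#' clustering and antagonism classification, writing each stage's table to
#' `out_dir` (TSV; dendrograms additionally as Newick and JSON) together with
#' a JSON run manifest carrying the seed, a hash of the configuration and the
#' package version. Outputs are a pure function of (inputs, config): a
#' re-run with the same config reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The `pleio_scan` object, invisibly; side effect: files under
#'   `out_dir` (`qc.tsv`, `assoc.tsv`, `pleio.tsv`, `a_matrix.tsv`,
#'   `snp_tree.newick`, `pheno_tree.newick`, `*_tree.json`, `clusters.tsv`,
#'   `antagonism.tsv`, `summary.json`, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  geno <- config$genotypes
  if (is.character(geno)) {
    geno <- if (grepl("\\.vcf$", geno)) read_vcf(geno) else
      read_genotypes_tsv(geno)
  }
  pheno <- config$phenotypes
  if (is.character(pheno)) pheno <- read_phenotypes_tsv(pheno)
  loci <- config$loci
  if (is.character(loci) && length(loci) == 1L && file.exists(loci)) {
    loci <- read_tsv_skip_comments(loci, "locus map")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- pleio_scan(geno, pheno, anchor = config$anchor, qc = config$qc,
                    tiers = config$tiers, rules = config$rules,
                    scale = config$scale, loci = loci)
  seed <- config$seed
  p <- function(f) file.path(config$out_dir, f)
  write_tsv_with_header(fit$qc, p("qc.tsv"), "qc report", seed)
  write_assoc_tsv(fit$assoc, p("assoc.tsv"), seed)
  write_pleio_tsv(fit$pleio, p("pleio.tsv"), seed)
  if (!is.null(fit$matrix)) {
    write_signed_matrix_tsv(fit$matrix, p("a_matrix.tsv"), seed)
    write_newick(fit$snp_tree, p("snp_tree.newick"))
    write_newick(fit$pheno_tree, p("pheno_tree.newick"))
    write_dendrogram_json(fit$snp_tree, p("snp_tree.json"))
    write_dendrogram_json(fit$pheno_tree, p("pheno_tree.json"))
    clusters <- rbind(
      data.frame(axis = "snp", item = names(fit$snp_clusters),
                 cluster = unname(fit$snp_clusters)),
      data.frame(axis = "phenotype", item = names(fit$pheno_clusters),
                 cluster = unname(fit$pheno_clusters))
    )
    write_tsv_with_header(clusters, p("clusters.tsv"), "cluster labels", seed)
    if (!is.null(fit$antagonism)) {
      write_tsv_with_header(fit$antagonism, p("antagonism.tsv"),
                            "antagonism calls", seed)
      jsonlite::write_json(fit$antagonism_summary, p("summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  ## hash the analysis settings only: input objects and paths vary across
  ## machines without changing what is computed
  cfg_string <- paste(
    utils::capture.output(utils::str(config[setdiff(names(config),
                                                    c("genotypes",
                                                      "phenotypes",
                                                      "out_dir"))])),
    collapse = "\n")
  manifest <- list(
    package = "pleioscan",
    version = as.character(utils::packageVersion("pleioscan")),
    seed = seed,
    anchor = config$anchor,
    config_hash = fnv1a32(cfg_string),
    n_variants = nrow(fit$qc),
    n_pass_qc = sum(fit$qc$pass_all),
    outputs = setdiff(list.files(config$out_dir), "manifest.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(fit)
}
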