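## Plain-text file formats: dosage TSV and VCF for genotypes, TSV for
## phenotypes, summary statistics, pleiotropy records and the signed matrix,
## Newick / JSON for dendrograms. Every writer stamps a comment header with
## the generating seed (when known) so a run can be traced; readers skip
## comment lines and validate structure, reporting the offending line.

seed_header <- function(kind, seed = NULL) {
  c(sprintf("# pleioscan %s", kind),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)))
}

write_tsv_with_header <- function(df, path, kind, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(seed_header(kind, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_skip_comments <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stop("malformed ", kind, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!nrow(df)) stop("empty ", kind, " file: ", path, call. = FALSE)
  df
}

#' Write / read a phenotype and covariate table
#'
#' TSV with one row per individual and a comment header recording the seed
#' and the trait panel (name and type), so the panel survives a round trip.
#'
#' @param cohort Phenotype table (see [simulate_cohort()]).
#' @param path File path.
#' @param seed Optional seed to record in the header.
#' @return `path` (writer) / the cohort `data.frame` with the trait panel
#'   attached (reader).
#' @export
write_phenotypes_tsv <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(seed_header("phenotypes", seed), con)
  panel <- attr(cohort, "traits")
  if (!is.null(panel)) {
    writeLines(sprintf("# trait %s %s", panel$trait, panel$type), con)
  }
  utils::write.table(cohort, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  lines <- readLines(path)
  tr <- grep("^# trait ", lines, value = TRUE)
  df <- read_tsv_skip_comments(path, "phenotype")
  if (length(tr)) {
    parts <- strsplit(sub("^# trait ", "", tr), " ", fixed = TRUE)
    panel <- trait_panel()
    found <- data.frame(trait = vapply(parts, `[`, "", 1L),
                        type = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
    bad <- !found$type %in% c("binary", "quantitative")
    if (any(bad)) {
      stop("unknown trait type at header line ",
           which(lines == tr[which(bad)[1]]), call. = FALSE)
    }
    panel <- panel[match(found$trait, panel$trait), ]
    panel$trait <- found$trait
    panel$type <- found$type
    attr(df, "traits") <- panel
  }
  df
}

#' Write / read a genotype dosage matrix as TSV
#'
#' One row per variant: the metadata columns `ID CHROM POS REF ALT TRUE_MAF`
#' followed by one dosage column per individual (`NA` for missing).
#'
#' @param genotypes A `genotype_matrix`.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_genotypes_tsv <- function(genotypes, path, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  df <- cbind(
    data.frame(ID = v$id, CHROM = v$chrom, POS = v$pos, REF = v$ref,
               ALT = v$alt,
               TRUE_MAF = if ("true_maf" %in% names(v)) v$true_maf else NA,
               stringsAsFactors = FALSE),
    as.data.frame(t(genotypes$dosages))
  )
  write_tsv_with_header(df, path, "genotypes", seed)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_tsv_skip_comments(path, "genotype")
  meta_cols <- c("ID", "CHROM", "POS", "REF", "ALT", "TRUE_MAF")
  if (!all(meta_cols %in% names(df))) {
    stop("malformed genotype file: expected columns ",
         paste(meta_cols, collapse = ", "), call. = FALSE)
  }
  if (ncol(df) <= length(meta_cols)) {
    stop("genotype file contains no individuals", call. = FALSE)
  }
  variants <- data.frame(id = df$ID, chrom = as.character(df$CHROM),
                         pos = df$POS, ref = df$REF, alt = df$ALT,
                         true_maf = df$TRUE_MAF, stringsAsFactors = FALSE)
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  colnames(dos) <- variants$id
  genotype_matrix(variants, dos)
}

#' Write / read genotypes as VCF
#'
#' Writes a minimal VCF 4.2 with GT fields: the ALT allele is the counted
#' (minor) allele, so dosages map to `0/0`, `0/1`, `1/1` and missing entries
#' to `./.`. Reading uses the `vcfR` parser and reconstructs the dosage
#' matrix.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path File path (uncompressed `.vcf`).
#' @param seed Optional seed recorded as a `##pleioscan_seed` header.
#' @export
write_vcf <- function(genotypes, path, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  dos <- genotypes$dosages
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(seed)) sprintf("##pleioscan_seed=%s", format(seed)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variants", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- map[t(gt)]
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, true_maf = NA_real_,
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, dos)
}

#' Write / read association summary statistics
#'
#' TSV with one row per (variant, trait). P-values are serialised in
#' scientific notation with 6 significant digits together with a `LOG10_P`
#' column, so extreme tails survive the round trip.
#'
#' @param assoc Association table from [run_ewas()].
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_assoc_tsv <- function(assoc, path, seed = NULL) {
  df <- data.frame(
    ID = assoc$variant, CHR = assoc$chrom, POS = assoc$pos,
    EFFECT_ALLELE = assoc$effect_allele, OTHER_ALLELE = assoc$other_allele,
    MAF = assoc$maf, TRAIT = assoc$trait,
    BETA = assoc$beta, SE = assoc$se,
    P = ifelse(is.na(assoc$p), NA, sprintf("%.6e", assoc$p)),
    LOG10_P = ifelse(is.na(assoc$p), NA, log10(assoc$p)),
    N = assoc$n_used, STATUS = assoc$status,
    stringsAsFactors = FALSE
  )
  write_tsv_with_header(df, path, "summary statistics", seed)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  df <- read_tsv_skip_comments(path, "summary statistics")
  data.frame(
    variant = df$ID, chrom = as.character(df$CHR), pos = df$POS,
    trait = df$TRAIT, effect_allele = df$EFFECT_ALLELE,
    other_allele = df$OTHER_ALLELE, maf = df$MAF,
    beta = df$BETA, se = df$SE, p = as.numeric(df$P),
    n_used = df$N, status = df$STATUS, stringsAsFactors = FALSE
  )
}

#' Write / read pleiotropy records
#'
#' @param pleio Table from [run_pairwise_pleiotropy()].
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_pleio_tsv <- function(pleio, path, seed = NULL) {
  df <- data.frame(
    ID = pleio$variant, TRAIT = pleio$trait,
    P_AD = sprintf("%.6e", pleio$p_ad),
    P_TRAIT = sprintf("%.6e", pleio$p_trait),
    CHI2 = pleio$chi2,
    P_FISHER = sprintf("%.6e", pleio$p_fisher),
    LOG10_P_FISHER = pleio$log10_p_fisher,
    TIER = pleio$tier, stringsAsFactors = FALSE
  )
  write_tsv_with_header(df, path, "pleiotropy", seed)
}

#' @rdname write_pleio_tsv
#' @export
read_pleio_tsv <- function(path) {
  df <- read_tsv_skip_comments(path, "pleiotropy")
  data.frame(
    variant = df$ID, trait = df$TRAIT, p_ad = as.numeric(df$P_AD),
    p_trait = as.numeric(df$P_TRAIT), chi2 = df$CHI2,
    p_fisher = as.numeric(df$P_FISHER),
    log10_p_fisher = df$LOG10_P_FISHER, tier = df$TIER,
    stringsAsFactors = FALSE
  )
}

#' Write / read the signed category matrix
#'
#' TSV with SNP ids in the first column (`ID`) and one integer column per
#' phenotype.
#'
#' @param A Integer matrix from [build_signed_matrix()].
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_signed_matrix_tsv <- function(A, path, seed = NULL) {
  df <- data.frame(ID = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, "signed matrix", seed)
}

#' @rdname write_signed_matrix_tsv
#' @export
read_signed_matrix_tsv <- function(path) {
  df <- read_tsv_skip_comments(path, "signed matrix")
  A <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(A) <- "integer"
  rownames(A) <- df$ID
  A
}

#' Export a dendrogram as Newick and as a JSON merge list
#'
#' Newick branch lengths carry the merge heights (via [ape::as.phylo()]);
#' the JSON form lists the merge matrix, heights and leaf labels.
#'
#' @param tree An `hclust` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
write_dendrogram_json <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  jsonlite::write_json(
    list(labels = tree$labels,
         merge = unname(apply(tree$merge, 1L, as.list)),
         height = tree$height),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
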