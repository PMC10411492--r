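#' Coverage table of per-sample, per-locus mean read depth
#'
#' @param depth numeric matrix, rows = loci, columns = samples (mean read
#'   depth, non-negative).
#' @param sex named character vector (`male`/`female`/`unknown`) per sample.
#' @param linkage named character vector (`A`/`X`) of reference linkage per
#'   locus.
#' @return object of class `coverage_table`.
#' @export
coverage_table <- function(depth, sex, linkage) {
  if (any(depth < 0, na.rm = TRUE)) stop("input error: negative depths")
  if (is.null(rownames(depth)) || is.null(colnames(depth)))
    stop("input error: depth matrix must have locus rownames and sample colnames")
  sex <- sex[colnames(depth)]
  linkage <- linkage[rownames(depth)]
  if (anyNA(sex)) stop("input error: missing sex labels for some samples")
  if (anyNA(linkage)) stop("input error: missing linkage labels for some loci")
  structure(list(depth = depth, sex = sex, linkage = linkage,
                 normalized = FALSE),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("<coverage_table> %d loci x %d samples (%d male, %d female)%s\n",
              nrow(x$depth), ncol(x$depth), sum(x$sex == "male"),
              sum(x$sex == "female"),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Library-size normalization of a coverage table
#'
#' Each sample's depths are divided by that sample's median depth over
#' autosomal loci, so the per-sample autosomal median becomes 1. Samples
#' with no positive autosomal depth are excluded with a warning.
#'
#' @param table a `coverage_table`.
#' @return normalized `coverage_table`.
#' @export
normalize_depths <- function(table) {
  auto <- table$linkage == "A"
  med <- apply(table$depth[auto, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  bad <- !is.finite(med) | med <= 0
  if (any(bad)) {
    warning("excluding sample(s) with zero autosomal depth: ",
            paste(colnames(table$depth)[bad], collapse = ", "))
    table$depth <- table$depth[, !bad, drop = FALSE]
    table$sex <- table$sex[!bad]
    med <- med[!bad]
  }
  table$depth <- sweep(table$depth, 2L, med, "/")
  table$normalized <- TRUE
  table
}

# per-locus median normalized depth within one sex
sex_median_depth <- function(table, which_sex) {
  cols <- table$sex == which_sex
  apply(table$depth[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
}

#' Depth-based test of X-linkage (males vs females, X vs autosomes)
#'
#' With loci as the unit of replication (per-locus per-sex median
#' normalized depth), one-sided rank-sum tests of (i) male depth on X loci
#' below female depth on X loci and (ii) male depth on X loci below male
#' depth on autosomal loci. Effect sizes are median log2 depth ratios. A
#' hemizygous X predicts effects near -1.
#'
#' @param table a `coverage_table` (normalized first when `normalized` is
#'   `FALSE`).
#' @param alpha significance level recorded in the result.
#' @return object of class `linkage_test` with per-comparison p-values and
#'   effect sizes.
#' @export
group_depth_test <- function(table, alpha = 0.05) {
  if (!table$normalized) table <- normalize_depths(table)
  if (sum(table$sex == "male") < 2L || sum(table$sex == "female") < 2L)
    stop("input error: need at least 2 samples per sex")
  male <- sex_median_depth(table, "male")
  female <- sex_median_depth(table, "female")
  x <- table$linkage == "X"
  t1 <- stats::wilcox.test(male[x], female[x], alternative = "less",
                           exact = FALSE)
  t2 <- stats::wilcox.test(male[x], male[!x], alternative = "less",
                           exact = FALSE)
  lr <- function(a, b) stats::median(log2(a / b), na.rm = TRUE)
  structure(list(
    male_x_vs_female_x = list(p = t1$p.value,
                              effect = lr(male[x], female[x])),
    male_x_vs_male_a = list(p = t2$p.value,
                            effect = stats::median(log2(male[x]), na.rm = TRUE) -
                                     stats::median(log2(male[!x]), na.rm = TRUE)),
    n_x = sum(x), n_a = sum(!x), alpha = alpha),
    class = "linkage_test")
}

#' @export
print.linkage_test <- function(x, ...) {
  cat(sprintf("<linkage_test> %d X loci vs %d autosomal loci\n", x$n_x, x$n_a),
      sprintf(" male X < female X : p = %.3g, effect = %.3f log2\n",
              x$male_x_vs_female_x$p, x$male_x_vs_female_x$effect),
      sprintf(" male X < male A   : p = %.3g, effect = %.3f log2\n",
              x$male_x_vs_male_a$p, x$male_x_vs_male_a$effect))
  invisible(x)
}

#' Per-locus X-linkage score and classification
#'
#' Score = log2 of the ratio of median male to median female normalized
#' depth at the locus: about -1 for X-linked loci (males hemizygous), about
#' 0 for autosomal loci. Loci at or below `threshold` are classified
#' `predicted_X`.
#'
#' @param table a `coverage_table` (normalized when needed).
#' @param threshold classification boundary on the log2 scale (default -0.5).
#' @return data frame: locus, score, predicted (`predicted_X`/`predicted_A`);
#'   score is `NA` when the female median depth is zero.
#' @export
per_locus_linkage_score <- function(table, threshold = -0.5) {
  if (!table$normalized) table <- normalize_depths(table)
  male <- sex_median_depth(table, "male")
  female <- sex_median_depth(table, "female")
  score <- ifelse(female > 0, log2(male / female), NA_real_)
  data.frame(locus = rownames(table$depth), score = score,
             predicted = ifelse(is.na(score), NA_character_,
                                ifelse(score <= threshold,
                                       "predicted_X", "predicted_A")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write a coverage table as TSV
#'
#' `<stem>.tsv` holds the depth matrix (first column `locus`, one column
#' per sample); `<stem>_sex.tsv` maps sample to sex; `<stem>_linkage.tsv`
#' maps locus to reference linkage.
#'
#' @param table a `coverage_table`.
#' @param stem path stem for the three files.
#' @export
write_coverage <- function(table, stem) {
  utils::write.table(data.frame(locus = rownames(table$depth), table$depth,
                                check.names = FALSE),
                     paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(table$sex), sex = table$sex),
                     paste0(stem, "_sex.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(locus = names(table$linkage),
                                linkage = table$linkage),
                     paste0(stem, "_linkage.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stem)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(stem) {
  d <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t",
                         check.names = FALSE)
  depth <- as.matrix(d[, -1, drop = FALSE])
  rownames(depth) <- d$locus
  sex <- utils::read.table(paste0(stem, "_sex.tsv"), header = TRUE, sep = "\t")
  link <- utils::read.table(paste0(stem, "_linkage.tsv"), header = TRUE,
                            sep = "\t")
  coverage_table(depth, stats::setNames(sex$sex, sex$sample),
                 stats::setNames(link$linkage, link$locus))
}
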