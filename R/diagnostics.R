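# Heteroskedasticity and leverage diagnostics: phenotype variance ratios
# across the repeating SNP's genotype classes, and the leverage increase the
# product term induces on sparse two-locus cells.

#' Genotypic variance ratios of a repeating SNP
#'
#' Computes the phenotype variance within each populated genotype class of
#' the repeating SNP, orders classes by size (largest first; ties broken by
#' dosage ascending), and reports the three pairwise variance ratios. Under
#' homoskedasticity all ratios are 1; a ratio_1_3 below 1 (largest class
#' less variable than the smallest) is the pattern associated with inflation
#' of the interaction-term lambda.
#'
#' @param x_rep repeating-SNP dosage vector (0/1/2, `NA` allowed).
#' @param y phenotype vector of matching length.
#' @return a `variance_ratio_report`: list with `class_dosages`,
#'   `class_sizes`, `class_variances` (size order, `n - 1` denominator,
#'   `NA` and flagged for classes of size < 2), `ratio_1_3`, `ratio_2_3`,
#'   `ratio_1_2` (ratios involving a flagged or absent class are `NA`).
#' @export
genotypic_variance_ratios <- function(x_rep, y) {
  ok <- !(is.na(x_rep) | is.na(y))
  x <- x_rep[ok]; yy <- y[ok]
  sizes <- tabulate(x + 1L, 3L)
  present <- which(sizes > 0L)
  if (length(present) < 2L || sum(sizes[present] >= 2L) < 2L)
    stop_lambdascan("input",
                    "need at least 2 populated genotype classes with >= 2 subjects")
  ord <- present[order(-sizes[present], present)]
  class_dosages <- ord - 1L
  class_sizes <- sizes[ord]
  class_variances <- vapply(ord, function(g) {
    if (sizes[g] < 2L) NA_real_ else stats::var(yy[x == g - 1L])
  }, numeric(1))
  ratio <- function(i, j) {
    if (length(ord) < max(i, j)) return(NA_real_)
    class_variances[i] / class_variances[j]
  }
  structure(list(class_dosages = class_dosages, class_sizes = class_sizes,
                 class_variances = class_variances,
                 ratio_1_3 = ratio(1, 3), ratio_2_3 = ratio(2, 3),
                 ratio_1_2 = ratio(1, 2)),
            class = "variance_ratio_report")
}

#' @export
print.variance_ratio_report <- function(x, ...) {
  cat("genotypic variance ratios (classes in size order):\n")
  cat(sprintf("  dosage %d: n=%d, var=%.4g\n", x$class_dosages,
              x$class_sizes, x$class_variances), sep = "")
  cat(sprintf("  ratio 1/3 = %.3g, 2/3 = %.3g, 1/2 = %.3g\n",
              x$ratio_1_3, x$ratio_2_3, x$ratio_1_2))
  invisible(x)
}

#' Per-cell maximum leverage: two-locus vs product-term model
#'
#' For each populated two-locus genotype cell, reports the maximum hat-value
#' among its subjects under the two-locus model (no interaction) and under
#' the product-term model. Adding the product column can only enlarge the
#' column space, so the product-term leverage is never smaller; the increase
#' concentrates in sparsely populated cells.
#'
#' @param x,z dosage vectors (repeating, non-repeating); `NA` allowed.
#' @param y phenotype vector.
#' @return data frame with one row per populated cell: `x_dosage`,
#'   `z_dosage`, `n`, `max_leverage_two_locus`, `max_leverage_product`.
#' @export
leverage_comparison <- function(x, z, y) {
  ok <- !(is.na(x) | is.na(z) | is.na(y))
  x <- x[ok]; z <- z[ok]; y <- y[ok]
  fit2 <- fit_ols(build_design("II", x, z), y)
  fit3 <- fit_ols(build_design("III", x, z), y)
  cell <- interaction(x, z, drop = TRUE)
  agg <- function(h) tapply(h, cell, max)
  lev2 <- agg(fit2$leverage); lev3 <- agg(fit3$leverage)
  key <- do.call(rbind, strsplit(names(lev2), ".", fixed = TRUE))
  data.frame(x_dosage = as.integer(key[, 1]), z_dosage = as.integer(key[, 2]),
             n = as.integer(table(cell)),
             max_leverage_two_locus = as.numeric(lev2),
             max_leverage_product = as.numeric(lev3))
}

#' Association between lambda and repeating-SNP heteroskedasticity
#'
#' Rank-correlates interaction-term lambda values with the largest-to-
#' smallest genotypic variance ratio across scans, and summarizes the
#' direction: median lambda among scans with ratio_1_3 below 1 versus above
#' 1. The expected pattern on heteroskedastic data is inflation (lambda > 1)
#' when the most-populated class is the least variable, deflation in the
#' mirrored case.
#'
#' @param lambda_values numeric vector of per-scan lambda values.
#' @param ratio_1_3 numeric vector of matching variance ratios.
#' @return list with `rho` (Spearman), `n`, `median_lambda_ratio_below_1`,
#'   `median_lambda_ratio_above_1`.
#' @export
heteroskedasticity_lambda_association <- function(lambda_values, ratio_1_3) {
  ok <- is.finite(lambda_values) & is.finite(ratio_1_3)
  lam <- lambda_values[ok]; rat <- ratio_1_3[ok]
  if (length(lam) < 10)
    stop_lambdascan("input", "need at least 10 scans with both quantities")
  med <- function(v) if (length(v) == 0) NA_real_ else stats::median(v)
  list(rho = stats::cor(lam, rat, method = "spearman"),
       n = length(lam),
       median_lambda_ratio_below_1 = med(lam[rat < 1]),
       median_lambda_ratio_above_1 = med(lam[rat > 1]))
}

#' Simulate phenotypes with genotype-class variance structure
#'
#' Generates traits that are mean-zero normal with a standard deviation
#' depending on a SNP's genotype class: `y_i ~ N(0, sd_by_class[g_i + 1])`.
#' This is the controlled heteroskedasticity used to study how genotypic
#' variance patterns drive interaction-term lambda; there is still no mean
#' effect of any SNP.
#'
#' @param x dosage vector (0/1/2) supplying the class structure.
#' @param sd_by_class length-3 positive numeric, SD for classes 0/1/2.
#' @param q number of traits.
#' @param seed integer master seed.
#' @return a `phenotype_table`.
#' @export
simulate_class_variance_phenotypes <- function(x, sd_by_class, q, seed) {
  stopifnot(length(sd_by_class) == 3, all(sd_by_class > 0), q >= 1)
  n <- length(x)
  sds <- sd_by_class[x + 1L]
  sds[is.na(sds)] <- 1
  vals <- matrix(NA_real_, n, q)
  for (j in seq_len(q)) {
    set.seed(derive_seed(seed, 400000L + j))
    vals[, j] <- stats::rnorm(n, sd = sds)
  }
  new_phenotype_table(vals)
}
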