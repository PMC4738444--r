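# SNP-by-genome interaction scan engine. One "repeating" SNP is paired with
# every genome ("non-repeating") SNP passing the MAF filter; each pair goes
# through complete-case subsetting, the minimum two-locus cell-count filter,
# model fitting and the configured test. Degenerate pairs become skip rows
# with a reason; they never abort a scan.

valid_tests <- c("beta3_1df", "joint_rep_2df", "joint_nonrep_2df",
                 "interaction_4df", "beta2_2locus", "beta1_main")
test_model <- c(beta3_1df = "III", joint_rep_2df = "III",
                joint_nonrep_2df = "III", interaction_4df = "IV",
                beta2_2locus = "II", beta1_main = "I")

#' Scan configuration
#'
#' Bundles the model, test, covariance estimator and filtering rules for a
#' SNP-by-genome scan.
#'
#' @param model_id `"I"`, `"II"`, `"III"` (default) or `"IV"`; must match
#'   `test_spec` (each test is defined on one model).
#' @param test_spec which test drives the scan: `"beta3_1df"` (default, the
#'   1-df product-term test), `"joint_rep_2df"`, `"joint_nonrep_2df"`,
#'   `"interaction_4df"`, `"beta2_2locus"`, or `"beta1_main"`.
#' @param estimator `"OLS"`, `"HC0"` or `"HC3"` coefficient covariance.
#'   HC estimators apply only to the single-coefficient t tests; the multi-df
#'   F tests are OLS-based.
#' @param maf_threshold retain non-repeating SNPs with sample MAF at or above
#'   this value (default 0.05).
#' @param min_cell_count drop subjects in populated two-locus genotype cells
#'   smaller than this (default: 0 for OLS, 5 for HC0/HC3 — the sparse-cell
#'   guard HC inference needs).
#' @param alpha_level nominal level for the per-scan observed alpha.
#' @param seed integer seed recorded with results.
#' @param lambda_denominator `"exact"` or `"printed"` (see
#'   [lambda_from_tstats()]).
#' @return a `scan_config` list.
#' @export
scan_config <- function(model_id = NULL, test_spec = "beta3_1df",
                        estimator = c("OLS", "HC0", "HC3"),
                        maf_threshold = 0.05, min_cell_count = NULL,
                        alpha_level = 0.05, seed = 1L,
                        lambda_denominator = c("exact", "printed")) {
  estimator <- match.arg(estimator)
  test_spec <- match.arg(test_spec, valid_tests)
  if (is.null(model_id)) model_id <- test_model[[test_spec]]
  model_id <- match.arg(as.character(model_id), c("I", "II", "III", "IV"))
  if (model_id != test_model[[test_spec]])
    stop_lambdascan("config", sprintf("test '%s' is defined on model %s",
                                      test_spec, test_model[[test_spec]]))
  if (estimator != "OLS" && grepl("^(joint|interaction)", test_spec))
    stop_lambdascan("config", "multi-df F tests are OLS-based only")
  if (maf_threshold < 0 || maf_threshold >= 0.5)
    stop_lambdascan("config", "maf_threshold must lie in [0, 0.5)")
  if (is.null(min_cell_count))
    min_cell_count <- if (estimator == "OLS") 0L else 5L
  if (min_cell_count < 0)
    stop_lambdascan("config", "min_cell_count must be non-negative")
  structure(list(model_id = model_id, test_spec = test_spec,
                 estimator = estimator, maf_threshold = maf_threshold,
                 min_cell_count = as.integer(min_cell_count),
                 alpha_level = alpha_level, seed = as.integer(seed),
                 lambda_denominator = match.arg(lambda_denominator)),
            class = "scan_config")
}

#' Recode a dosage vector to minor-allele counts
#'
#' If the allele counted by the 0/1/2 coding has frequency above 0.5 on the
#' non-missing entries, dosages are flipped (`g -> 2 - g`) so that 2 always
#' means two copies of the minor allele in the analyzed sample.
#'
#' @param dosages vector of 0/1/2 dosages, `NA` allowed.
#' @return list with `dosages` (possibly flipped), sample `maf` in
#'   \[0, 0.5\], and logical `flipped`.
#' @export
#' @examples
#' minor_allele_recode(c(2, 2, 1))  # flipped to c(0, 0, 1), maf 1/6
minor_allele_recode <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop_lambdascan("degenerate_input", "all dosages missing")
  freq2 <- sum(dosages[ok]) / (2 * sum(ok))
  flipped <- freq2 > 0.5
  if (flipped) dosages <- 2L - dosages
  list(dosages = dosages, maf = min(freq2, 1 - freq2), flipped = flipped)
}

# Recode every SNP on the analyzed sample and attach realized sample MAFs.
# Idempotent; run_study and scan_pairs call it once per genotype matrix.
recode_genotype_matrix <- function(gm) {
  if (isTRUE(attr(gm, "recoded"))) return(gm)
  dos <- gm$dosages
  maf <- numeric(ncol(dos))
  for (j in seq_len(ncol(dos))) {
    rc <- minor_allele_recode(dos[, j])
    dos[, j] <- rc$dosages
    maf[j] <- rc$maf
  }
  out <- new_genotype_matrix(dos, gm$snp_ids, maf, gm$repeating)
  attr(out, "recoded") <- TRUE
  out
}

#' Sample minor allele frequencies of a genotype matrix
#'
#' MAF computed from the analyzed sample (non-missing dosages), after
#' minor-allele recoding.
#'
#' @param gm a `genotype_matrix`.
#' @return named numeric vector of sample MAFs.
#' @export
sample_maf <- function(gm) {
  gm <- recode_genotype_matrix(gm)
  stats::setNames(gm$snp_maf, gm$snp_ids)
}

#' Filter SNPs by sample minor allele frequency
#'
#' Retains SNPs whose sample MAF is greater than or equal to `threshold`
#' (boundary inclusive), preserving order.
#'
#' @param genotypes a `genotype_matrix`.
#' @param threshold MAF threshold in \[0, 0.5).
#' @return the filtered `genotype_matrix` (possibly with zero SNPs).
#' @export
filter_maf <- function(genotypes, threshold) {
  gm <- recode_genotype_matrix(genotypes)
  keep <- gm$snp_maf >= threshold
  out <- new_genotype_matrix(gm$dosages[, keep, drop = FALSE],
                             gm$snp_ids[keep], gm$snp_maf[keep],
                             gm$repeating[keep])
  attr(out, "recoded") <- TRUE
  out
}

#' Two-locus genotype cell counts
#'
#' Tallies subjects into the 3 x 3 joint genotype table of a SNP pair.
#'
#' @param x,z complete-case dosage vectors of equal length (values 0/1/2).
#' @return 3 x 3 integer matrix; rows index `x`, columns index `z`, both
#'   labeled 0/1/2. The grand total equals the number of subjects.
#' @export
two_locus_cell_counts <- function(x, z) {
  stopifnot(length(x) == length(z))
  counts <- matrix(tabulate(3L * x + z + 1L, nbins = 9L), 3, 3, byrow = TRUE,
                   dimnames = list(x = 0:2, z = 0:2))
  counts
}

#' Drop subjects in sparse two-locus genotype cells
#'
#' Removes all subjects belonging to populated cells with fewer than
#' `min_count` members. Counts are computed once on the input (single pass):
#' cells are not re-evaluated after dropping, and empty cells impose no
#' constraint.
#'
#' @param x,z complete-case dosage vectors.
#' @param y phenotype vector of matching length.
#' @param min_count non-negative integer; 0 is the identity.
#' @return list with filtered `x`, `z`, `y`, the number of `dropped`
#'   subjects, and the pre-filter `cell_counts`.
#' @export
apply_min_cell_filter <- function(x, z, y, min_count) {
  stopifnot(length(x) == length(z), length(x) == length(y), min_count >= 0)
  counts <- two_locus_cell_counts(x, z)
  if (min_count <= 1L || all(counts[counts > 0] >= min_count))
    return(list(x = x, z = z, y = y, dropped = 0L, cell_counts = counts))
  cell <- 3L * x + z + 1L
  keep <- t(counts)[cell] >= min_count   # t(): counts is row-major in cell index
  list(x = x[keep], z = z[keep], y = y[keep], dropped = sum(!keep),
       cell_counts = counts)
}

# One pair: complete-case subset -> cell filter -> design -> fit -> test.
# Returns a list of row fields; skip rows carry a reason and NA statistics.
scan_one_pair <- function(x_full, z_full, y_full, config) {
  ok <- !(is.na(x_full) | is.na(z_full) | is.na(y_full))
  x <- x_full[ok]; z <- z_full[ok]; y <- y_full[ok]
  n_cc <- length(x)
  flt <- apply_min_cell_filter(x, z, y, config$min_cell_count)
  counts <- flt$cell_counts
  x <- flt$x; z <- flt$z; y <- flt$y
  n_used <- length(x)
  k <- model_k[[config$model_id]]
  row <- list(n_used = n_used, dropped = flt$dropped,
              cell_counts = counts, estimate = NA_real_, se = NA_real_,
              statistic = NA_real_, df_num = NA_integer_,
              df_den = NA_integer_, p_value = NA_real_,
              t_squared = NA_real_, skip_reason = "none")
  if (n_used <= k) { row$skip_reason <- "insufficient_cells"; return(row) }
  if (length(unique(z)) < 2L ||
      (config$model_id != "I" && length(unique(x)) < 2L)) {
    row$skip_reason <- "monomorphic"; return(row)
  }
  res <- tryCatch({
    design <- build_design(config$model_id, x, z)
    if (config$test_spec %in% c("beta3_1df", "beta2_2locus", "beta1_main")) {
      fit <- fit_ols(design, y)
      cov <- covariance_estimate(fit, config$estimator)
      coef_label <- switch(config$test_spec,
                           beta3_1df = "product",
                           beta2_2locus = "nonrep_additive",
                           beta1_main = "nonrep_additive")
      tst <- wald_t_test(fit, cov, coef_label)
      row$estimate <- tst$estimate; row$se <- tst$se
      row$t_squared <- tst$statistic^2
      tst
    } else {
      constrained <- switch(config$test_spec,
        joint_rep_2df = c("rep_additive", "product"),
        joint_nonrep_2df = c("nonrep_additive", "product"),
        interaction_4df = c("product_aa", "product_ad",
                            "product_da", "product_dd"))
      f_test(design, y, constrained)
    }
  }, lambdascan_singular_design = function(e) "singular",
     lambdascan_extreme_leverage = function(e) "singular",
     lambdascan_degenerate_test = function(e) "singular",
     lambdascan_insufficient_data = function(e) "insufficient_cells")
  if (is.character(res)) { row$skip_reason <- res; return(row) }
  row$statistic <- res$statistic
  row$df_num <- res$df_num
  row$df_den <- res$df_den
  row$p_value <- res$p_value
  row
}

#' SNP-by-genome interaction scan for one repeating SNP and one phenotype
#'
#' Pairs the repeating SNP with every non-repeating SNP whose sample MAF
#' passes the threshold (the repeating SNP's own column is excluded; SNPs
#' correlated with it are not). Each pair is filtered and fitted
#' independently; degenerate pairs become skip rows.
#'
#' @param genotypes a `genotype_matrix` (minor-allele recoding and sample
#'   MAFs are computed here if not already).
#' @param repeating_id SNP id held fixed across all pairs.
#' @param phenotype numeric vector, one value per subject.
#' @param config a [scan_config()].
#' @return a `scan_result` data frame, one row per candidate SNP, with the
#'   pair ids, subjects used, dropped count, 3 x 3 cell counts (`c00`...`c22`,
#'   row = repeating dosage), coefficient estimate and SE (t tests),
#'   statistic, degrees of freedom, P-value and `skip_reason`.
#' @export
scan_pairs <- function(genotypes, repeating_id, phenotype, config) {
  stopifnot(inherits(config, "scan_config"))
  gm <- recode_genotype_matrix(genotypes)
  idx_rep <- match(repeating_id, gm$snp_ids)
  if (is.na(idx_rep))
    stop_lambdascan("input", sprintf("repeating SNP '%s' not found", repeating_id))
  if (length(phenotype) != nrow(gm$dosages))
    stop_lambdascan("input", "phenotype length must match subject count")
  x_full <- gm$dosages[, idx_rep]
  if (length(unique(x_full[!is.na(x_full)])) < 2L)
    stop_lambdascan("monomorphic_repeating",
                    sprintf("repeating SNP '%s' is monomorphic", repeating_id))
  cand <- which(gm$snp_maf >= config$maf_threshold &
                  seq_along(gm$snp_ids) != idx_rep)
  m <- length(cand)
  n_used <- dropped <- df_num <- df_den <- integer(m)
  cells <- matrix(0L, m, 9L,
                  dimnames = list(NULL, c("c00", "c01", "c02", "c10", "c11",
                                          "c12", "c20", "c21", "c22")))
  estimate <- se <- statistic <- p_value <- t_squared <- numeric(m)
  skip_reason <- character(m)
  dos <- gm$dosages
  for (i in seq_len(m)) {
    r <- scan_one_pair(x_full, dos[, cand[i]], phenotype, config)
    n_used[i] <- r$n_used; dropped[i] <- r$dropped
    cells[i, ] <- as.integer(t(r$cell_counts))
    estimate[i] <- r$estimate; se[i] <- r$se
    statistic[i] <- r$statistic
    df_num[i] <- r$df_num; df_den[i] <- r$df_den
    p_value[i] <- r$p_value; t_squared[i] <- r$t_squared
    skip_reason[i] <- r$skip_reason
  }
  out <- data.frame(
    repeating_snp_id = rep(repeating_id, m),
    nonrepeating_snp_id = gm$snp_ids[cand],
    n_used = n_used, dropped = dropped, cells,
    estimate = estimate, se = se, statistic = statistic,
    df_num = df_num, df_den = df_den, p_value = p_value,
    t_squared = t_squared, skip_reason = skip_reason,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  attr(out, "repeating_maf") <- gm$snp_maf[idx_rep]
  class(out) <- c("scan_result", "data.frame")
  out
}

# Lambda for one scan's rows: t-based for 1-df t tests, P-value-based for
# F tests. Skipped rows are excluded from lambda and observed-alpha.
scan_lambda <- function(rows, config) {
  keep <- rows$skip_reason == "none"
  if (!any(keep)) return(list(lambda = NA_real_, source = NA_character_,
                              n_tests = 0L, n_skipped = sum(!keep),
                              observed_alpha = NA_real_))
  used <- rows[keep, ]
  if (config$test_spec %in% c("beta3_1df", "beta2_2locus", "beta1_main")) {
    lam <- lambda_from_tstats(used$statistic, config$lambda_denominator)
    src <- "t_squared"
  } else {
    lam <- lambda_from_pvalues(used$p_value, config$lambda_denominator)
    src <- "chisq_from_p"
  }
  list(lambda = lam, source = src, n_tests = nrow(used),
       n_skipped = sum(!keep),
       observed_alpha = observed_alpha(used$p_value, config$alpha_level))
}

#' Run a full interaction study
#'
#' Executes one SNP-by-genome scan per (repeating SNP, phenotype)
#' combination and summarizes each scan into a lambda record. A scan that
#' fails outright (e.g. monomorphic repeating SNP) is recorded with `NA`
#' lambda and an error note; it never aborts the study.
#'
#' @param genotypes a `genotype_matrix`.
#' @param repeating_ids character vector of repeating SNP ids; `NULL` uses
#'   the SNPs flagged repeating in `genotypes`.
#' @param phenotypes a `phenotype_table`.
#' @param config a [scan_config()].
#' @param keep_scans keep the full per-pair scan archives (default `TRUE`;
#'   set `FALSE` for large null-distribution runs).
#' @return an `interaction_study`: list with `lambda_records` (one row per
#'   scan: ids, repeating MAF, model/test/estimator, lambda and its source,
#'   n_tests, n_skipped, observed alpha, error note) and `scans` (named list
#'   of `scan_result` data frames, or `NULL`).
#' @export
run_study <- function(genotypes, repeating_ids = NULL, phenotypes, config,
                      keep_scans = TRUE) {
  stopifnot(inherits(phenotypes, "phenotype_table"),
            inherits(config, "scan_config"))
  gm <- recode_genotype_matrix(genotypes)
  if (is.null(repeating_ids)) repeating_ids <- gm$snp_ids[gm$repeating]
  if (length(repeating_ids) == 0)
    stop_lambdascan("config", "no repeating SNPs specified or flagged")
  traits <- phenotypes$trait_ids
  combos <- expand.grid(phenotype_id = traits, repeating_snp_id = repeating_ids,
                        stringsAsFactors = FALSE)[, 2:1]
  nrec <- nrow(combos)
  rec <- data.frame(
    repeating_snp_id = combos$repeating_snp_id,
    phenotype_id = combos$phenotype_id,
    repeating_maf = NA_real_, model_id = config$model_id,
    test_spec = config$test_spec, estimator = config$estimator,
    lambda = NA_real_, lambda_source = NA_character_,
    lambda_denominator = config$lambda_denominator,
    n_tests = NA_integer_, n_skipped = NA_integer_,
    observed_alpha = NA_real_, error = NA_character_,
    stringsAsFactors = FALSE
  )
  scans <- if (keep_scans) vector("list", nrec) else NULL
  maf_lookup <- stats::setNames(gm$snp_maf, gm$snp_ids)
  for (i in seq_len(nrec)) {
    rid <- rec$repeating_snp_id[i]
    y <- phenotypes$values[, rec$phenotype_id[i]]
    rec$repeating_maf[i] <- unname(maf_lookup[rid])
    rows <- tryCatch(scan_pairs(gm, rid, y, config),
                     lambdascan_error = function(e) e)
    if (inherits(rows, "condition")) {
      rec$error[i] <- conditionMessage(rows)
      next
    }
    s <- scan_lambda(rows, config)
    rec$lambda[i] <- s$lambda
    rec$lambda_source[i] <- s$source
    rec$n_tests[i] <- s$n_tests
    rec$n_skipped[i] <- s$n_skipped
    rec$observed_alpha[i] <- s$observed_alpha
    if (keep_scans) {
      scans[[i]] <- rows
      names(scans)[i] <- paste(rid, rec$phenotype_id[i], sep = ".")
    }
  }
  structure(list(lambda_records = rec, scans = scans, config = config),
            class = "interaction_study")
}

#' @export
print.interaction_study <- function(x, ...) {
  r <- x$lambda_records
  cat(sprintf("interaction_study: %d scans (model %s, %s, %s), lambda range [%.3f, %.3f]\n",
              nrow(r), x$config$model_id, x$config$test_spec,
              x$config$estimator,
              suppressWarnings(min(r$lambda, na.rm = TRUE)),
              suppressWarnings(max(r$lambda, na.rm = TRUE))))
  invisible(x)
}
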