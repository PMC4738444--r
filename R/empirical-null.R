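# Simulation-based empirical null distribution of the interaction-term
# lambda, and placement of an observed lambda within it. Because
# interaction-term test statistics within a scan are correlated (the product
# term shares its repeating component across pairs), lambda varies under the
# null far more than a main-effect lambda does; an observed value is
# interpreted by comparison to scans on matched null data, not against 1.
# Lambda is never used to rescale test statistics.

#' Build an empirical null distribution of lambda
#'
#' Simulates a null dataset of matched size (no SNP effects, no population
#' substructure), runs the full SNP-by-genome study, and collects the
#' per-scan lambda values. Fully reproducible under `seed`.
#'
#' @param n subjects.
#' @param genome_size non-repeating SNP count (values below 100 trigger a
#'   warning: the scan median becomes noisy).
#' @param maf_spectrum `maf_spectrum` for the genome SNPs.
#' @param repeating_grid `maf_spectrum` for the repeating SNPs (one scan set
#'   per point).
#' @param n_phenotypes traits per dataset.
#' @param config a [scan_config()].
#' @param seed integer master seed.
#' @return a `null_lambda_distribution`: list with `lambda_records` (per-scan
#'   lambda plus repeating MAF, phenotype, counts), `generating_config`
#'   (everything needed to regenerate the distribution), and `n_scans`.
#' @export
build_null_distribution <- function(n, genome_size, maf_spectrum,
                                    repeating_grid, n_phenotypes, config,
                                    seed) {
  stopifnot(inherits(config, "scan_config"))
  if (genome_size < 100)
    warning("genome_size < 100: per-scan lambda medians will be noisy")
  dat <- simulate_study_data(n, genome_size, maf_spectrum, repeating_grid,
                             n_phenotypes = n_phenotypes, seed = seed)
  study <- run_study(dat$genotypes, NULL, dat$phenotypes, config,
                     keep_scans = FALSE)
  rec <- study$lambda_records
  structure(list(
    lambda_records = rec,
    generating_config = list(n = n, genome_size = genome_size,
                             maf_spectrum = maf_spectrum,
                             repeating_grid = repeating_grid,
                             n_phenotypes = n_phenotypes,
                             scan_config = config, seed = as.integer(seed)),
    n_scans = nrow(rec)),
    class = "null_lambda_distribution")
}

#' @export
print.null_lambda_distribution <- function(x, ...) {
  lam <- x$lambda_records$lambda
  cat(sprintf("null_lambda_distribution: %d scans, lambda median %.3f, range [%.3f, %.3f]\n",
              x$n_scans, stats::median(lam, na.rm = TRUE),
              min(lam, na.rm = TRUE), max(lam, na.rm = TRUE)))
  invisible(x)
}

#' Locate an observed lambda in an empirical null distribution
#'
#' Reports the mid-rank percentile of the observed value among the null
#' lambda values and a two-sided empirical tail probability
#' `2 * min(r + 1, B - r + 1) / (B + 1)` (capped at 1), where `r` is the
#' number of null values strictly below the observed one — the standard
#' permutation-test convention. Optionally restricts the null values to
#' scans whose repeating-SNP MAF lies within a band of the observed SNP's
#' MAF, since lambda spread depends strongly on that MAF and an unmatched
#' comparison is anti-conservative at low MAF.
#'
#' @param observed a single lambda value, or one row of a `lambda_records`
#'   data frame (from which `repeating_maf` is taken).
#' @param null_dist a `null_lambda_distribution`.
#' @param maf_matching `"all"` (default) or `"nearest_band"`.
#' @param band half-width of the MAF band (default 0.05).
#' @param observed_maf repeating-SNP MAF of the observed scan (required for
#'   `"nearest_band"` when `observed` is a bare number).
#' @return list with `percentile`, `tail_prob`, `n_null`, `maf_matching`.
#'   No accept/reject verdict is attached: the distribution's spread is the
#'   interpretation.
#' @export
compare_lambda <- function(observed, null_dist,
                           maf_matching = c("all", "nearest_band"),
                           band = 0.05, observed_maf = NULL) {
  stopifnot(inherits(null_dist, "null_lambda_distribution"))
  maf_matching <- match.arg(maf_matching)
  if (is.data.frame(observed)) {
    if (is.null(observed_maf)) observed_maf <- observed$repeating_maf[1]
    observed <- observed$lambda[1]
  }
  if (!is.finite(observed))
    stop_lambdascan("input", "observed lambda must be a finite number")
  rec <- null_dist$lambda_records
  vals <- rec$lambda[is.finite(rec$lambda)]
  mafs <- rec$repeating_maf[is.finite(rec$lambda)]
  if (maf_matching == "nearest_band") {
    if (is.null(observed_maf))
      stop_lambdascan("input", "nearest_band matching requires observed_maf")
    keep <- abs(mafs - observed_maf) <= band
    vals <- vals[keep]
    if (length(vals) < 20)
      stop_lambdascan("input",
                      sprintf("only %d null values within +/-%.2g of MAF %.2g; simulate a larger null distribution",
                              length(vals), band, observed_maf))
  }
  B <- length(vals)
  if (B == 0) stop_lambdascan("input", "null distribution has no finite lambda values")
  r <- sum(vals < observed)
  ties <- sum(vals == observed)
  list(percentile = 100 * (r + 0.5 * ties) / B,
       tail_prob = min(1, 2 * min(r + 1, B - r + 1) / (B + 1)),
       n_null = B,
       maf_matching = maf_matching)
}
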