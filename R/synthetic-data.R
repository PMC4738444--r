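# Null-hypothesis dataset simulation: Hardy-Weinberg genotypes from a minor
# allele frequency (MAF) spectrum, and phenotypes that are either standard
# normal draws or independently permuted copies of supplied trait columns.
# No SNP effects, no linkage disequilibrium, no population substructure.

#' MAF spectrum over a regular grid
#'
#' Describes a set of minor allele frequencies as an inclusive arithmetic
#' sequence, e.g. `maf_grid(0.05, 0.5, 0.01)` is the 46-point spectrum used
#' for a broad panel of repeating SNPs.
#'
#' @param start,end grid endpoints, allele frequencies in (0, 0.5].
#' @param step positive grid increment.
#' @return an object of class `maf_spectrum`.
#' @seealso [maf_empirical()], [expand_maf_spectrum()]
#' @export
#' @examples
#' length(expand_maf_spectrum(maf_grid(0.05, 0.5, 0.01)))  # 46
maf_grid <- function(start, end, step) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop_lambdascan("config", "grid step must be a single positive number")
  if (!is.numeric(start) || !is.numeric(end) || start > end)
    stop_lambdascan("config", "grid start must not exceed grid end")
  if (start <= 0 || end > 0.5)
    stop_lambdascan("config", "grid frequencies must lie in (0, 0.5]")
  structure(list(mode = "grid", grid_start = start, grid_end = end,
                 grid_step = step, values = NULL),
            class = "maf_spectrum")
}

#' MAF spectrum from an empirical list of frequencies
#'
#' Wraps an observed allele-frequency distribution (for example, the MAFs of
#' a genotyped SNP panel) so that genome-scale SNP sets can be drawn from it
#' with replacement.
#'
#' @param values numeric vector of allele frequencies, all in (0, 0.5].
#' @return an object of class `maf_spectrum`.
#' @export
maf_empirical <- function(values) {
  if (length(values) == 0)
    stop_lambdascan("config", "empirical MAF spectrum requires a non-empty value list")
  if (!is.numeric(values) || anyNA(values) || any(values <= 0 | values > 0.5))
    stop_lambdascan("config", "empirical MAF values must lie in (0, 0.5]")
  structure(list(mode = "empirical", grid_start = NULL, grid_end = NULL,
                 grid_step = NULL, values = as.numeric(values)),
            class = "maf_spectrum")
}

#' @export
print.maf_spectrum <- function(x, ...) {
  if (x$mode == "grid")
    cat(sprintf("MAF spectrum: grid %.3g-%.3g step %.3g (%d points)\n",
                x$grid_start, x$grid_end, x$grid_step,
                length(expand_maf_spectrum(x))))
  else
    cat(sprintf("MAF spectrum: empirical, %d values in [%.3g, %.3g]\n",
                length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Packaged default MAF spectrum
#'
#' A deterministic, synthetic stand-in for a genotyping panel's MAF
#' distribution: `k` frequencies log-uniformly spaced over \[0.05, 0.5\], so
#' that low frequencies are over-represented the way they are in real SNP
#' panels. It is not derived from any real cohort.
#'
#' @param k number of spectrum points.
#' @return an empirical `maf_spectrum`.
#' @export
default_maf_spectrum <- function(k = 500) {
  u <- (seq_len(k) - 0.5) / k
  maf_empirical(0.05 * (0.5 / 0.05)^u)
}

#' Expand a MAF spectrum into a list of frequencies
#'
#' Grid mode returns every grid point exactly once (`m` is ignored); grid
#' points are built by integer index arithmetic so the endpoint is included
#' without floating-point step drift. Empirical mode samples `m` values
#' uniformly with replacement, reproducibly under `seed`.
#'
#' @param spec a `maf_spectrum`.
#' @param m number of frequencies to draw (empirical mode).
#' @param seed integer seed (empirical mode).
#' @return numeric vector of allele frequencies.
#' @export
expand_maf_spectrum <- function(spec, m = NULL, seed = NULL) {
  stopifnot(inherits(spec, "maf_spectrum"))
  if (spec$mode == "grid") {
    n_steps <- floor((spec$grid_end - spec$grid_start) / spec$grid_step + 1e-9)
    return(spec$grid_start + spec$grid_step * (0:n_steps))
  }
  if (is.null(m) || m < 1)
    stop_lambdascan("config", "empirical expansion requires m >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  spec$values[sample.int(length(spec$values), m, replace = TRUE)]
}

#' Hardy-Weinberg genotype frequencies
#'
#' For minor allele frequency `p`, the three genotype class frequencies are
#' ((1-p)^2, 2p(1-p), p^2) for 0, 1, 2 copies of the minor allele.
#'
#' @param maf allele frequency in \[0, 0.5\].
#' @return named numeric vector `(f0, f1, f2)` summing to 1.
#' @export
#' @examples
#' hwe_genotype_freqs(0.5)  # 0.25 0.50 0.25
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) || maf < 0 || maf > 0.5)
    stop_lambdascan("domain", "maf must be a single value in [0, 0.5]")
  c(f0 = (1 - maf)^2, f1 = 2 * maf * (1 - maf), f2 = maf^2)
}

#' Construct a genotype matrix
#'
#' Container for a subjects x SNPs minor-allele dosage matrix with per-SNP
#' metadata. Dosages must be 0, 1, 2 or `NA`.
#'
#' @param dosages numeric/integer matrix, subjects in rows.
#' @param snp_ids SNP identifiers (default: column names or `snp_` numbers).
#' @param snp_maf per-SNP minor allele frequency; `NA` values are replaced
#'   by sample MAFs computed after minor-allele recoding.
#' @param repeating logical flag(s) marking repeating SNPs.
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snp_ids = NULL, snp_maf = NULL,
                            repeating = FALSE) {
  dosages <- as.matrix(dosages)
  if (!all(is.na(dosages) | dosages %in% 0:2))
    stop_lambdascan("input", "dosages must be 0, 1, 2, or NA")
  m <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages) %||%
      sprintf("snp_%06d", seq_len(m))
  if (length(snp_ids) != m)
    stop_lambdascan("input", "snp_ids length must match the SNP count")
  gm <- new_genotype_matrix(dosages, snp_ids,
                            snp_maf %||% rep(NA_real_, m),
                            rep_len(repeating, m))
  if (anyNA(gm$snp_maf)) gm <- recode_genotype_matrix(gm)
  gm
}

new_genotype_matrix <- function(dosages, snp_ids, snp_maf, repeating) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  colnames(dosages) <- snp_ids
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 snp_maf = as.numeric(snp_maf),
                 repeating = as.logical(repeating)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d repeating), MAF [%.3g, %.3g]\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$repeating),
              min(x$snp_maf), max(x$snp_maf)))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each subject x SNP dosage is an independent draw from the three-genotype
#' distribution implied by that SNP's MAF under Hardy-Weinberg equilibrium.
#' Each SNP column uses its own derived substream, so any column can be
#' regenerated independently from the master seed. No missing values are
#' produced. SNPs whose realized sample MAF is 0 (possible at small n) are
#' retained; the scan engine skips them.
#'
#' @param n number of subjects (>= 1).
#' @param mafs numeric vector of generating allele frequencies in \[0, 0.5\].
#' @param seed integer master seed.
#' @param snp_ids optional SNP identifiers (default `snp_000001`, ...).
#' @param repeating logical scalar or vector flagging repeating SNPs.
#' @return a `genotype_matrix`; `snp_maf` holds the generating frequencies.
#' @export
simulate_genotypes <- function(n, mafs, seed, snp_ids = NULL, repeating = FALSE) {
  stopifnot(n >= 1, length(mafs) >= 1)
  if (any(mafs < 0 | mafs > 0.5))
    stop_lambdascan("domain", "all mafs must lie in [0, 0.5]")
  m <- length(mafs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%06d", seq_len(m))
  repeating <- rep_len(repeating, m)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    set.seed(derive_seed(seed, j))
    f <- hwe_genotype_freqs(mafs[j])
    dos[, j] <- sample.int(3L, n, replace = TRUE, prob = f) - 1L
  }
  new_genotype_matrix(dos, snp_ids, mafs, repeating)
}

#' Construct a phenotype table
#'
#' Container for a subjects x traits matrix of quantitative values (assumed
#' to be on an adjusted/standardized residual scale).
#'
#' @param values numeric matrix, subjects in rows; all values finite or `NA`.
#' @param trait_ids trait identifiers (default: column names or `trait_`
#'   numbers).
#' @param subject_ids subject identifiers (default: row names or `subj_`
#'   numbers).
#' @return a `phenotype_table`.
#' @export
phenotype_table <- function(values, trait_ids = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop_lambdascan("input", "phenotype values must be numeric")
  if (ncol(values) < 1)
    stop_lambdascan("input", "at least one trait column is required")
  new_phenotype_table(values, trait_ids, subject_ids)
}

new_phenotype_table <- function(values, trait_ids = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(trait_ids)) trait_ids <- colnames(values) %||%
      sprintf("trait_%02d", seq_len(ncol(values)))
  if (is.null(subject_ids)) subject_ids <- rownames(values) %||%
      sprintf("subj_%05d", seq_len(nrow(values)))
  dimnames(values) <- list(subject_ids, trait_ids)
  structure(list(values = values, trait_ids = trait_ids,
                 subject_ids = subject_ids),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects x %d traits\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Simulate standard-normal phenotypes
#'
#' Draws `n x q` independent standard-normal values; one derived substream
#' per trait column.
#'
#' @param n number of subjects (>= 2).
#' @param q number of traits (>= 1).
#' @param seed integer master seed.
#' @return a `phenotype_table`.
#' @export
simulate_phenotypes <- function(n, q, seed) {
  stopifnot(n >= 2, q >= 1)
  vals <- matrix(NA_real_, n, q)
  for (j in seq_len(q)) {
    set.seed(derive_seed(seed, 100000L + j))
    vals[, j] <- stats::rnorm(n)
  }
  new_phenotype_table(vals)
}

#' Independently permute each phenotype column
#'
#' Shuffles each trait column by its own uniform random permutation (distinct
#' substream per column), destroying any subject-level link between traits
#' and any genotype-phenotype association while keeping every marginal trait
#' distribution intact. This is how null phenotypes are built from real trait
#' columns.
#'
#' @param table a `phenotype_table`.
#' @param seed integer master seed.
#' @return a `phenotype_table` with identical column multisets.
#' @export
permute_phenotypes <- function(table, seed) {
  stopifnot(inherits(table, "phenotype_table"))
  n <- nrow(table$values)
  vals <- table$values
  for (j in seq_len(ncol(vals))) {
    set.seed(derive_seed(seed, 200000L + j))
    vals[, j] <- vals[sample.int(n), j]
  }
  new_phenotype_table(vals, table$trait_ids, table$subject_ids)
}

#' Simulate a complete null study dataset
#'
#' Builds the genotype and phenotype inputs for a SNP-by-genome interaction
#' study under the null: `genome_size` non-repeating SNPs with MAFs drawn
#' from `genome_spectrum` (with replacement when the spectrum is smaller than
#' the genome), plus one repeating SNP per point of `repeating_spectrum`, and
#' either standard-normal phenotypes or independently permuted copies of
#' `source_phenotypes`.
#'
#' @param n subjects.
#' @param genome_size number of non-repeating SNPs.
#' @param genome_spectrum `maf_spectrum` for the genome SNPs.
#' @param repeating_spectrum `maf_spectrum` for the repeating SNPs (grid mode
#'   recommended; every point yields one repeating SNP).
#' @param n_phenotypes number of traits (ignored in `"permute"` mode).
#' @param phenotype_mode `"normal"` or `"permute"`.
#' @param source_phenotypes `phenotype_table` to permute in `"permute"` mode.
#' @param seed integer master seed.
#' @return list with elements `genotypes` (`genotype_matrix`, repeating SNPs
#'   flagged and named `rep01`, ...) and `phenotypes` (`phenotype_table`).
#' @export
simulate_study_data <- function(n, genome_size, genome_spectrum,
                                repeating_spectrum, n_phenotypes = 9,
                                phenotype_mode = c("normal", "permute"),
                                source_phenotypes = NULL, seed = 1) {
  phenotype_mode <- match.arg(phenotype_mode)
  stopifnot(inherits(genome_spectrum, "maf_spectrum"),
            inherits(repeating_spectrum, "maf_spectrum"))
  genome_mafs <- if (genome_spectrum$mode == "grid") {
    pts <- expand_maf_spectrum(genome_spectrum)
    set.seed(derive_seed(seed, 300001L))
    pts[sample.int(length(pts), genome_size, replace = TRUE)]
  } else {
    expand_maf_spectrum(genome_spectrum, m = genome_size,
                        seed = derive_seed(seed, 300001L))
  }
  rep_mafs <- if (repeating_spectrum$mode == "grid")
    expand_maf_spectrum(repeating_spectrum)
  else repeating_spectrum$values
  mafs <- c(genome_mafs, rep_mafs)
  ids <- c(sprintf("snp_%06d", seq_len(genome_size)),
           sprintf("rep%02d", seq_along(rep_mafs)))
  genotypes <- simulate_genotypes(n, mafs, seed = derive_seed(seed, 300002L),
                                  snp_ids = ids,
                                  repeating = c(rep(FALSE, genome_size),
                                                rep(TRUE, length(rep_mafs))))
  phenotypes <- if (phenotype_mode == "normal") {
    simulate_phenotypes(n, n_phenotypes, seed = derive_seed(seed, 300003L))
  } else {
    if (is.null(source_phenotypes))
      stop_lambdascan("config", "permute mode requires source_phenotypes")
    if (nrow(source_phenotypes$values) != n)
      stop_lambdascan("config", "source_phenotypes subject count must equal n")
    permute_phenotypes(source_phenotypes, seed = derive_seed(seed, 300003L))
  }
  list(genotypes = genotypes, phenotypes = phenotypes)
}
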