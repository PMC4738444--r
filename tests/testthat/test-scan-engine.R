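test_that("minor-allele recoding flips major-coded SNPs and reports sample MAF", {
  r1 <- minor_allele_recode(c(0, 0, 1))
  expect_equal(r1$dosages, c(0, 0, 1))
  expect_equal(r1$maf, 1 / 6)
  expect_false(r1$flipped)
  r2 <- minor_allele_recode(c(2, 2, 1))
  expect_equal(r2$dosages, c(0, 0, 1))
  expect_equal(r2$maf, 1 / 6)
  expect_true(r2$flipped)
  # genotype counts 295/537/221 imply MAF (537 + 2*221)/(2*1053)
  g <- rep(0:2, c(295, 537, 221))
  expect_equal(minor_allele_recode(g)$maf, (537 + 2 * 221) / (2 * 1053))
  expect_equal(round(minor_allele_recode(g)$maf, 2), 0.46)
  expect_error(minor_allele_recode(c(NA, NA)),
               class = "lambdascan_degenerate_input")
})

test_that("MAF filtering is boundary-inclusive and order-preserving", {
  dos <- cbind(a = c(rep(0, 99), 1),            # maf 0.005
               b = c(rep(0, 98), 1, 1),         # maf 0.01
               c = rep(c(0, 1, 2, 1), 25))      # maf 0.25... polymorphic
  gm <- genotype_matrix(dos)
  expect_equal(filter_maf(gm, 0)$snp_ids, c("a", "b", "c"))
  expect_equal(filter_maf(gm, 0.01)$snp_ids, c("b", "c"))
  # simulated grid spectrum >= 0.05 survives a 0.05 threshold almost fully:
  # only SNPs generated at the boundary can dip below it by sampling noise
  mafs <- expand_maf_spectrum(maf_grid(0.05, 0.5, 0.01))
  gm2 <- simulate_genotypes(1053, mafs, seed = 3)
  kept_ids <- filter_maf(gm2, 0.05)$snp_ids
  expect_gte(length(kept_ids) / 46, 0.95)
  safe <- gm2$snp_ids[mafs >= 0.08]   # > 4 sampling SEs above the threshold
  expect_true(all(safe %in% kept_ids))
})

test_that("two-locus cell counts tally the joint genotype table", {
  counts <- two_locus_cell_counts(c(0, 0, 1, 2), c(0, 1, 0, 2))
  expect_equal(counts["0", "0"], 1)
  expect_equal(counts["0", "1"], 1)
  expect_equal(counts["1", "0"], 1)
  expect_equal(counts["2", "2"], 1)
  expect_equal(sum(counts), 4)
  # independent SNPs: counts near the product-multinomial expectation
  set.seed(4)
  n <- 2e4
  fx <- hwe_genotype_freqs(0.3); fz <- hwe_genotype_freqs(0.2)
  x <- sample(0:2, n, TRUE, prob = fx); z <- sample(0:2, n, TRUE, prob = fz)
  exp_counts <- n * outer(fx, fz)
  obs <- two_locus_cell_counts(x, z)
  se <- sqrt(exp_counts * (1 - exp_counts / n))
  expect_true(all(abs(obs - exp_counts) <= 3.5 * se))
  expect_equal(sum(obs), n)
})

test_that("the minimum cell filter drops exactly the sparse-cell subjects, single pass", {
  counts <- matrix(0L, 3, 3)
  counts[1, 1] <- 40; counts[2, 1] <- 10; counts[1, 2] <- 4; counts[3, 3] <- 6
  gp <- genotypes_from_cells(counts)
  y <- seq_along(gp$x)
  flt <- apply_min_cell_filter(gp$x, gp$z, y, 5)
  expect_equal(flt$dropped, 4)
  expect_equal(length(flt$x), 56)
  expect_true(all(two_locus_cell_counts(flt$x, flt$z)[c(1, 2, 9)] ==
                    c(40, 10, 6)))
  # min_count 0 and all-cells-populated-enough are identities
  id0 <- apply_min_cell_filter(gp$x, gp$z, y, 0)
  expect_equal(id0$dropped, 0)
  expect_identical(id0$x, gp$x)
  counts2 <- matrix(5L, 3, 3)
  gp2 <- genotypes_from_cells(counts2)
  expect_equal(apply_min_cell_filter(gp2$x, gp2$z, seq_len(45), 5)$dropped, 0)
  # single pass: cells are not re-evaluated after dropping
  # (dropping never empties a surviving cell, because counts are fixed once)
  counts3 <- matrix(0L, 3, 3)
  counts3[1, 1] <- 3; counts3[2, 2] <- 6; counts3[3, 3] <- 7
  gp3 <- genotypes_from_cells(counts3)
  flt3 <- apply_min_cell_filter(gp3$x, gp3$z, seq_len(16), 5)
  expect_equal(flt3$dropped, 3)
  expect_equal(sum(two_locus_cell_counts(flt3$x, flt3$z)), 13)
})

test_that("scan_config enforces test/model/estimator compatibility and HC defaults", {
  cfg <- scan_config()
  expect_equal(cfg$model_id, "III")
  expect_equal(cfg$min_cell_count, 0L)            # OLS default
  expect_equal(scan_config(estimator = "HC3")$min_cell_count, 5L)
  expect_equal(scan_config(test_spec = "interaction_4df")$model_id, "IV")
  expect_error(scan_config(model_id = "II", test_spec = "beta3_1df"),
               class = "lambdascan_config")
  expect_error(scan_config(test_spec = "interaction_4df", estimator = "HC3"),
               class = "lambdascan_config")
  expect_error(scan_config(maf_threshold = 0.6), class = "lambdascan_config")
})

test_that("scan rows cover every candidate SNP with conservation and determinism", {
  dat <- small_study(n = 300, genome = 80, seed = 15)
  cfg <- scan_config(estimator = "OLS", maf_threshold = 0.05, seed = 15)
  rows <- scan_pairs(dat$genotypes, "rep01", dat$phenotypes$values[, 1], cfg)
  gm <- filter_maf(dat$genotypes, 0.05)
  expect_equal(nrow(rows), sum(gm$snp_ids != "rep01"))
  expect_false("rep01" %in% rows$nonrepeating_snp_id)
  # conservation: cell totals = n_used + dropped
  cell_sums <- rowSums(as.matrix(rows[, sprintf("c%d%d", rep(0:2, each = 3),
                                                rep(0:2, 3))]))
  expect_equal(cell_sums, rows$n_used + rows$dropped, ignore_attr = TRUE)
  # byte-identical rerun
  rows2 <- scan_pairs(dat$genotypes, "rep01", dat$phenotypes$values[, 1], cfg)
  expect_identical(rows, rows2)
  expect_true(all(rows$p_value[rows$skip_reason == "none"] >= 0 &
                    rows$p_value[rows$skip_reason == "none"] <= 1))
})

test_that("degenerate pairs are skipped with reasons, never aborting the scan", {
  # z monomorphic after the cell filter: its minor allele lives in a sparse cell
  x <- rep(c(0, 1), c(30, 10))
  z <- c(rep(0, 36), 1, 1, 1, 1)
  z[37:40] <- 1            # all four z-carriers sit in the x=1 cells
  x[37:40] <- 1
  dos <- cbind(rep_snp = x, mono_after = z,
               fine = rep(c(0, 1, 2, 1), 10))
  gm <- genotype_matrix(dos, repeating = c(TRUE, FALSE, FALSE))
  cfg <- scan_config(estimator = "HC0", maf_threshold = 0, min_cell_count = 5,
                     seed = 1)
  set.seed(2)
  rows <- scan_pairs(gm, "rep_snp", rnorm(40), cfg)
  expect_equal(nrow(rows), 2)
  r <- rows[rows$nonrepeating_snp_id == "mono_after", ]
  expect_equal(r$skip_reason, "monomorphic")
  expect_true(is.na(r$statistic))
  # monomorphic repeating SNP is a whole-scan error
  gm_mono <- genotype_matrix(cbind(m = rep(0, 40), o = rep(c(0, 1), 20)))
  expect_error(scan_pairs(gm_mono, "m", rnorm(40), cfg),
               class = "lambdascan_monomorphic_repeating")
})

test_that("null-data scan keeps the observed alpha near the nominal level", {
  dat <- simulate_study_data(1053, 600, default_maf_spectrum(200),
                             maf_grid(0.25, 0.25, 0.1), n_phenotypes = 1,
                             seed = 77)
  cfg <- scan_config(estimator = "OLS", min_cell_count = 0, seed = 77)
  rows <- scan_pairs(dat$genotypes, "rep01", dat$phenotypes$values[, 1], cfg)
  keep <- rows$skip_reason == "none"
  alpha <- observed_alpha(rows$p_value[keep])
  expect_gt(alpha, 0.03)
  expect_lt(alpha, 0.09)
})

test_that("run_study yields one lambda record per scan with cardinality contracts", {
  dat <- small_study(n = 250, genome = 50, seed = 33)
  cfg <- scan_config(seed = 33)
  st <- run_study(dat$genotypes, "rep01",
                  phenotype_table(dat$phenotypes$values[, 1, drop = FALSE]),
                  cfg)
  expect_equal(nrow(st$lambda_records), 1)
  expect_lte(st$lambda_records$n_tests, 51)
  st2 <- run_study(dat$genotypes, NULL, dat$phenotypes, cfg,
                   keep_scans = FALSE)
  expect_equal(nrow(st2$lambda_records), 2 * 2)   # 2 repeating x 2 traits
  expect_null(st2$scans)
  expect_true(all(is.finite(st2$lambda_records$lambda)))
  # a failing scan is recorded, not fatal
  dos <- dat$genotypes$dosages
  dos[, "rep01"] <- 0L
  gm_bad <- genotype_matrix(dos, repeating = dat$genotypes$repeating)
  st3 <- run_study(gm_bad, c("rep01", "rep02"), dat$phenotypes, cfg)
  bad <- st3$lambda_records[st3$lambda_records$repeating_snp_id == "rep01", ]
  expect_true(all(is.na(bad$lambda)))
  expect_true(all(!is.na(bad$error)))
  good <- st3$lambda_records[st3$lambda_records$repeating_snp_id == "rep02", ]
  expect_true(all(is.finite(good$lambda)))
})

test_that("two-locus scan statistics for the genome SNP track the main-effect scan", {
  # with an independent repeating SNP in the model, per-pair t statistics for
  # the genome SNP barely move
  dat <- simulate_study_data(800, 250, default_maf_spectrum(100),
                             maf_grid(0.3, 0.3, 0.1), n_phenotypes = 1,
                             seed = 55)
  y <- dat$phenotypes$values[, 1]
  t2 <- scan_pairs(dat$genotypes, "rep01", y,
                   scan_config(test_spec = "beta2_2locus", seed = 55))
  t1 <- scan_pairs(dat$genotypes, "rep01", y,
                   scan_config(test_spec = "beta1_main", seed = 55))
  keep <- t2$skip_reason == "none" & t1$skip_reason == "none"
  expect_gt(cor(t2$statistic[keep], t1$statistic[keep]), 0.99)
})

test_that("aggregated null P-values are uniform at large n", {
  dat <- simulate_study_data(1e4, 300, default_maf_spectrum(150),
                             maf_grid(0.2, 0.2, 0.1), n_phenotypes = 1,
                             seed = 91)
  rows <- scan_pairs(dat$genotypes, "rep01", dat$phenotypes$values[, 1],
                     scan_config(seed = 91))
  p <- rows$p_value[rows$skip_reason == "none"]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("missing genotypes are handled per pair as complete cases", {
  dat <- small_study(n = 300, genome = 30, seed = 44)
  dos <- dat$genotypes$dosages
  dos[1:25, 3] <- NA            # knock out 25 subjects for one genome SNP
  gm <- genotype_matrix(dos, repeating = dat$genotypes$repeating)
  cfg <- scan_config(maf_threshold = 0, seed = 44)
  rows <- scan_pairs(gm, "rep01", dat$phenotypes$values[, 1], cfg)
  r <- rows[rows$nonrepeating_snp_id == colnames(dos)[3], ]
  expect_equal(r$n_used + r$dropped, 275)
  other <- rows[rows$nonrepeating_snp_id != colnames(dos)[3], ]
  expect_true(all(other$n_used + other$dropped == 300))
})
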