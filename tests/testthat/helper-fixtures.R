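# Shared fixture builders. All randomness is seeded at the call site.

# Random full-rank design + response for oracle comparisons.
random_instance <- function(n, k, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
  colnames(X) <- c("intercept", paste0("x", seq_len(k - 1)))
  design <- structure(list(X = X, labels = colnames(X), model_id = "III"),
                      class = "design_matrix")
  list(design = design, y = rnorm(n))
}

# Genotype pair with a prescribed two-locus cell layout. `counts` is a 3x3
# matrix [x+1, z+1]; subjects are emitted cell by cell.
genotypes_from_cells <- function(counts) {
  x <- integer(0); z <- integer(0)
  for (i in 0:2) for (j in 0:2) {
    m <- counts[i + 1, j + 1]
    x <- c(x, rep.int(i, m)); z <- c(z, rep.int(j, m))
  }
  list(x = x, z = z)
}

# Small null study dataset for scan-level tests.
small_study <- function(n = 400, genome = 120, n_rep = 2, q = 2, seed = 11) {
  simulate_study_data(n, genome, default_maf_spectrum(100),
                      maf_grid(0.15, 0.35, 0.35 - 0.15),
                      n_phenotypes = q, seed = seed)
}

# Literal matrix-formula oracles, kept deliberately naive.
oracle_ols_beta <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y
oracle_sandwich <- function(X, w) {
  bread <- solve(t(X) %*% X)
  bread %*% (t(X) %*% diag(w) %*% X) %*% bread
}
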