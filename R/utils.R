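# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' Counter-based derivation: each (master seed, stream index) pair maps to a
#' fixed 32-bit seed, so individual SNP columns or trait columns can be
#' regenerated without replaying the whole stream. All arithmetic stays in
#' double precision well below 2^53, and the result stays below 2^31.
#'
#' @param master integer master seed.
#' @param stream non-negative integer stream counter.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master, stream) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(stream) * 8191 + 1) %% 2147483629)
}

# Structured error constructor: every recoverable failure in the scan path
# signals a classed condition so the scan engine can convert it to a skip.
stop_lambdascan <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("lambdascan_", class), "lambdascan_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# File header comment recording provenance (tool version, seed, config hash);
# readers skip lines starting with '#'.
provenance_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("lambdascan"))
  hash <- if (is.null(config)) "none" else config_hash(config)
  sprintf("# lambdascan %s; seed=%s; config=%s", ver,
          if (is.null(seed)) "none" else seed, hash)
}

# Order-sensitive 32-bit FNV-1a style hash of a deparsed object; provenance
# only, not cryptographic.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2147483647), b) * 16777619) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}
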