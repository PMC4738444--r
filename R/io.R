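# Text interchange formats. The native genotype format is a tab-delimited
# dosage matrix: provenance comment lines starting with '#', then a header
# of `subject_id` followed by SNP ids, one row per subject, dosages 0/1/2 or
# NA. A companion metadata TSV carries snp_id, maf, repeating flag. VCF
# import is a convenience path that reads the GT field only.

#' Write a genotype matrix as tab-delimited text
#'
#' @param gm a `genotype_matrix`.
#' @param path output file for the dosage matrix.
#' @param meta_path output file for SNP metadata (default `path` +
#'   `".meta.tsv"`).
#' @param seed optional master seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(gm, path, meta_path = paste0(path, ".meta.tsv"),
                                  seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- provenance_header(seed = seed, config = gm$snp_ids)
  df <- data.frame(subject_id = rownames(gm$dosages) %||%
                     sprintf("subj_%05d", seq_len(nrow(gm$dosages))),
                   gm$dosages, check.names = FALSE)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  meta <- data.frame(snp_id = gm$snp_ids, maf = gm$snp_maf,
                     repeating = gm$repeating)
  writeLines(hdr, meta_path)
  suppressWarnings(utils::write.table(meta, meta_path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' Read a genotype matrix
#'
#' @param path dosage TSV (written by [write_genotype_matrix()]) or a VCF
#'   file.
#' @param format `"dosage_tsv"` (default) or `"vcf"`.
#' @param meta_path optional metadata TSV; when absent, MAFs are computed
#'   from the sample and no SNP is flagged repeating.
#' @return a `genotype_matrix`. For VCF input, diploid GT fields are mapped
#'   by counting the alternate allele (0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2,
#'   any missing allele -> NA; phased separators accepted); multi-allelic
#'   records are skipped, with the skip count in attribute
#'   `n_multiallelic_skipped` and a message.
#' @export
read_genotype_matrix <- function(path, format = c("dosage_tsv", "vcf"),
                                 meta_path = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotype_vcf(path))
  if (!file.exists(path)) stop_lambdascan("input", paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop_lambdascan("input", "dosage file must start with a subject_id column")
  dos <- as.matrix(df[, -1, drop = FALSE])
  if (!all(is.na(dos) | dos %in% 0:2))
    stop_lambdascan("input", "dosage values must be 0, 1, 2, or NA")
  storage.mode(dos) <- "integer"
  rownames(dos) <- df$subject_id
  snp_ids <- colnames(dos)
  maf <- rep(NA_real_, ncol(dos)); repeating <- rep(FALSE, ncol(dos))
  if (is.null(meta_path) && file.exists(paste0(path, ".meta.tsv")))
    meta_path <- paste0(path, ".meta.tsv")
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              comment.char = "#", stringsAsFactors = FALSE)
    idx <- match(snp_ids, meta$snp_id)
    maf <- meta$maf[idx]
    repeating <- isTRUE_vec(meta$repeating[idx])
  }
  gm <- new_genotype_matrix(dos, snp_ids, maf, repeating)
  if (anyNA(maf)) gm <- recode_genotype_matrix(gm)
  gm
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_lambdascan("config", "VCF import requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  n_skip <- sum(multi)
  if (n_skip > 0) {
    message(sprintf("skipping %d multi-allelic record(s)", n_skip))
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyNA(ids))
    ids <- sprintf("var_%06d", seq_len(nrow(gt)))
  dose_one <- function(g) {
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) != 2 || any(a == ".") || any(is.na(a))) NA_integer_
      else sum(a == "1")
    }, integer(1))
  }
  dos <- apply(gt, 1, dose_one)           # subjects x variants
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  rownames(dos) <- colnames(gt)
  gm <- new_genotype_matrix(dos, ids, rep(NA_real_, length(ids)),
                            rep(FALSE, length(ids)))
  gm <- recode_genotype_matrix(gm)
  attr(gm, "n_multiallelic_skipped") <- n_skip
  gm
}

#' Write a phenotype table as tab-delimited text
#'
#' @param pt a `phenotype_table`.
#' @param path output file; first column `subject_id`, then one column per
#'   trait.
#' @param seed optional master seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(pt, path, seed = NULL) {
  stopifnot(inherits(pt, "phenotype_table"))
  df <- data.frame(subject_id = pt$subject_ids, pt$values, check.names = FALSE)
  writeLines(provenance_header(seed = seed, config = pt$trait_ids), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a phenotype table, optionally aligned to a genotype matrix
#'
#' @param path delimited text with a header, a `subject_id` first column and
#'   numeric trait columns.
#' @param genotypes optional `genotype_matrix`; when supplied, phenotype rows
#'   are reordered to the genotype subject order by id, subjects absent from
#'   either side are reported via a message and excluded, and the returned
#'   table carries attribute `dropped_subjects`.
#' @return a `phenotype_table`.
#' @export
read_phenotype_table <- function(path, genotypes = NULL) {
  if (!file.exists(path)) stop_lambdascan("input", paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop_lambdascan("input", "phenotype file must start with a subject_id column")
  if (any(!nzchar(names(df))))
    stop_lambdascan("input", "empty trait column header")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))) &
                   !is.na(df[, -1, drop = FALSE]), arr.ind = TRUE)
    stop_lambdascan("input",
                    sprintf("non-numeric phenotype value at row %d, trait column %d",
                            bad[1, 1], bad[1, 2]))
  }
  rownames(vals) <- df$subject_id
  pt <- new_phenotype_table(vals, colnames(vals), df$subject_id)
  if (is.null(genotypes)) return(pt)
  geno_ids <- rownames(genotypes$dosages)
  if (is.null(geno_ids))
    stop_lambdascan("input", "genotype matrix has no subject ids to align by")
  common <- intersect(geno_ids, pt$subject_ids)
  if (length(common) == 0)
    stop_lambdascan("input", "no overlapping subjects between phenotypes and genotypes")
  dropped <- setdiff(union(geno_ids, pt$subject_ids), common)
  if (length(dropped) > 0)
    message(sprintf("%d subject(s) absent from one side excluded: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  ordered <- geno_ids[geno_ids %in% common]
  out <- new_phenotype_table(pt$values[ordered, , drop = FALSE],
                             pt$trait_ids, ordered)
  attr(out, "dropped_subjects") <- dropped
  out
}

#' Write scan rows or lambda records as TSV
#'
#' @param x a `scan_result` or `lambda_records` data frame.
#' @param path output file.
#' @param seed optional master seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, seed = NULL) {
  writeLines(provenance_header(seed = seed, config = names(x)), path)
  suppressWarnings(utils::write.table(as.data.frame(x), path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
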