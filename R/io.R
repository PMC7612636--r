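# Plain-text interchange: genotype dosage TSV with a variant sidecar,
# minimal VCF, phenotype and summary-statistics TSV (GWAS-SSF-style column
# names), and YAML serialization for PIVS models and causal verdicts.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a genotype matrix as dosage TSV plus variant sidecar
#'
#' The dosage file has one row per sample (first column `sample_id`, then
#' one column per variant id); the sidecar lists id, chrom, pos,
#' effect_allele, other_allele and eaf.
#'
#' @param gm a `genotype_matrix`.
#' @param dosage_path,variant_path output paths.
#' @export
write_genotypes <- function(gm, dosage_path, variant_path) {
  d <- data.frame(sample_id = rownames(gm$dosages), gm$dosages,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, dosage_path)
  v <- gm$variants[, c("id", "chrom", "pos", "effect_allele", "other_allele",
                       "eaf")]
  write_tsv(v, variant_path)
}

#' Read a genotype matrix from dosage TSV plus variant sidecar
#' @param dosage_path,variant_path paths written by [write_genotypes()].
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(dosage_path, variant_path) {
  d <- read_tsv(dosage_path)
  v <- read_tsv(variant_path)
  v$chrom <- as.character(v$chrom)
  D <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(D) <- "integer"
  rownames(D) <- d$sample_id
  if (!identical(colnames(D), v$id)) stop("dosage columns do not match sidecar")
  new_genotype_matrix(D, v)
}

#' Write a minimal VCF (GT field only) for a genotype matrix
#'
#' Dosage 0/1/2 of the effect allele maps to genotypes 0/0, 0/1 and 1/1
#' with the other allele as REF and the effect allele as ALT; missing
#' dosages become `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$dosages)),
                     collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  v <- gm$variants
  for (j in seq_len(nrow(v))) {
    dos <- gm$dosages[, j]
    calls <- ifelse(is.na(dos), "./.", gt[dos + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$other_allele[j],
                       v$effect_allele[j], ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read summary statistics TSV
#'
#' Columns (bit-exact): variant_id, chromosome, base_pair_location,
#' effect_allele, other_allele, effect_allele_frequency, beta,
#' standard_error, p_value, n.
#'
#' @param ss a `summary_stats` data frame.
#' @param path file path.
#' @export
write_summary_stats <- function(ss, path) {
  cols <- c("variant_id", "chromosome", "base_pair_location", "effect_allele",
            "other_allele", "effect_allele_frequency", "beta",
            "standard_error", "p_value", "n")
  write_tsv(as.data.frame(ss)[, cols], path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  out <- read_tsv(path)
  out$chromosome <- as.character(out$chromosome)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read a phenotype (trait table) TSV
#' @param tt data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(tt, path) write_tsv(tt, path)

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) read_tsv(path)

#' Serialize a PIVS model to YAML
#' @param model a `pivs_model`.
#' @param path file path.
#' @export
write_pivs_model <- function(model, path) {
  obj <- list(trait = model$trait, trait_sd = model$trait_sd,
              thresholds = model$thresholds,
              instruments = lapply(seq_len(nrow(model$instruments)),
                                   function(i) as.list(model$instruments[i, ])))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_pivs_model
#' @export
read_pivs_model <- function(path) {
  obj <- yaml::read_yaml(path)
  ins <- do.call(rbind, lapply(obj$instruments, as.data.frame))
  structure(list(trait = obj$trait, instruments = ins,
                 thresholds = obj$thresholds, trait_sd = obj$trait_sd),
            class = "pivs_model")
}

#' Serialize a causal verdict (with per-method results) to YAML
#' @param verdict a `causal_verdict`.
#' @param path file path.
#' @export
write_verdict <- function(verdict, path) {
  strip <- function(r) if (is.null(r)) NULL else
    list(method = r$method, estimate = r$estimate, se = r$se, p = r$p,
         n_instruments = r$n_instruments)
  obj <- list(classification = verdict$classification,
              direction = verdict$direction,
              main = strip(verdict$main),
              sensitivity = lapply(verdict$sensitivity, strip),
              rule = verdict$rule)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Write an MR report TSV (one row per method)
#' @param verdict a `causal_verdict`.
#' @param path file path.
#' @export
write_mr_report <- function(verdict, path) {
  res <- c(list(verdict$main), verdict$sensitivity)
  res <- Filter(Negate(is.null), res)
  rep <- do.call(rbind, lapply(res, function(r)
    data.frame(method = r$method, estimate = r$estimate, se = r$se, p = r$p,
               n_instruments = r$n_instruments, stringsAsFactors = FALSE)))
  rep$classification <- verdict$classification
  write_tsv(rep, path)
  invisible(path)
}
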