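# Polygenic instrumental variable scores (PIVS): instrument selection by
# clumping, joint weight estimation on the SD-1-scaled trait, per-sample
# scoring with mean imputation, variance explained, leave-one-SNP-out
# refits, and the PheWAS with FDR control and the leave-one-SNP-out
# sensitivity rule.

#' Select PIVS candidate variants by clumping
#'
#' Delegates to [clump()] with the PIVS construction thresholds
#' (p < 1e-6, r2 < 0.1 within 1000 kb) and returns the index variants.
#'
#' @param ss exposure `summary_stats`.
#' @param ld_reference a `genotype_matrix`.
#' @param p_thresh,r2_thresh,window_kb clumping parameters.
#' @return character vector of candidate (index) variant ids.
#' @export
select_pivs_candidates <- function(ss, ld_reference, p_thresh = 1e-6,
                                   r2_thresh = 0.1, window_kb = 1000) {
  cl <- clump(ss, ld_reference, p_thresh = p_thresh, r2_thresh = r2_thresh,
              window_kb = window_kb)
  attr(cl, "index_variants")
}

#' Fit a polygenic instrumental variable score model
#'
#' The trait is scaled to standard deviation 1, then regressed jointly on
#' the dosages of all candidate variants plus covariates; the per-candidate
#' coefficients become the instrument weights, so a unit change in the score
#' represents one trait standard deviation. Scoring allele frequencies (for
#' later mean imputation) are taken from the construction cohort.
#'
#' @param gm construction-cohort `genotype_matrix`.
#' @param trait numeric trait vector.
#' @param covariates covariate data frame (ancestry components, age, sex and
#'   any categorical placeholders as indicator columns).
#' @param candidates candidate variant ids from [select_pivs_candidates()].
#' @param trait_name label.
#' @return a `pivs_model`: list with trait, instruments (data frame id,
#'   chrom, pos, effect_allele, other_allele, eaf, weight), thresholds and
#'   the construction trait SD.
#' @export
fit_pivs <- function(gm, trait, covariates = NULL, candidates,
                     trait_name = "trait") {
  if (!length(candidates)) stop("no candidate variants: cannot fit a PIVS")
  j <- match(candidates, gm$variants$id)
  if (anyNA(j)) stop("candidates absent from genotypes: ",
                     paste(candidates[is.na(j)], collapse = ", "))
  n <- nrow(gm$dosages)
  if (n <= length(candidates) + (if (is.null(covariates)) 0 else ncol(covariates)) + 1)
    stop("too few samples for the number of candidates and covariates")
  trait_sd <- stats::sd(trait)
  y <- trait / trait_sd
  X <- impute_dosages(gm$dosages[, j, drop = FALSE])
  storage.mode(X) <- "double"
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- candidates[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)] - 1L)]
    stop("collinear candidate dosages: ", paste(dropped, collapse = ", "))
  }
  C <- build_covariate_matrix(covariates, n)
  fit <- stats::lm.fit(cbind(C, X), y)
  w <- fit$coefficients[ncol(C) + seq_len(ncol(X))]
  instruments <- data.frame(
    id = candidates,
    chrom = gm$variants$chrom[j],
    pos = gm$variants$pos[j],
    effect_allele = gm$variants$effect_allele[j],
    other_allele = gm$variants$other_allele[j],
    eaf = colMeans(X) / 2,
    weight = unname(w),
    stringsAsFactors = FALSE
  )
  structure(list(trait = trait_name, instruments = instruments,
                 thresholds = list(p_thresh = 1e-6, r2_thresh = 0.1,
                                   window_kb = 1000),
                 trait_sd = trait_sd),
            class = "pivs_model")
}

#' @exportS3Method base::print
print.pivs_model <- function(x, ...) {
  cat(sprintf("<pivs_model> %s: %d instruments (unit = 1 trait SD)\n",
              x$trait, nrow(x$instruments)))
  invisible(x)
}

#' Compute per-sample PIVS scores
#'
#' Score = sum over instruments of weight x dosage, with missing dosages
#' mean-imputed as twice the model's scoring allele frequency. Alleles are
#' harmonized to the model's effect allele: genotypes whose effect/other
#' alleles are swapped contribute `2 - dosage`.
#'
#' @param model a `pivs_model`.
#' @param gm a `genotype_matrix` containing every instrument.
#' @return named numeric vector of scores (one per sample).
#' @export
score_pivs <- function(model, gm) {
  ins <- model$instruments
  j <- match(ins$id, gm$variants$id)
  if (anyNA(j))
    stop("instruments absent from genotypes: ",
         paste(ins$id[is.na(j)], collapse = ", "))
  D <- gm$dosages[, j, drop = FALSE]
  storage.mode(D) <- "double"
  ga <- gm$variants[j, ]
  same <- ga$effect_allele == ins$effect_allele &
    ga$other_allele == ins$other_allele
  flip <- ga$effect_allele == ins$other_allele &
    ga$other_allele == ins$effect_allele
  if (any(!same & !flip))
    stop("allele mismatch for instruments: ",
         paste(ins$id[!same & !flip], collapse = ", "))
  D[, flip] <- 2 - D[, flip]
  for (k in seq_len(ncol(D))) {
    miss <- is.na(D[, k])
    if (any(miss)) D[miss, k] <- 2 * ins$eaf[k]
  }
  drop(D %*% ins$weight)
}

#' Variance explained by a PIVS
#'
#' R-squared from the single-variable linear regression of the trait on the
#' score.
#'
#' @param scores numeric score vector.
#' @param trait numeric trait vector.
#' @return R^2 in `[0, 1]`.
#' @export
pivs_r2 <- function(scores, trait) {
  if (stats::sd(scores) == 0 || stats::sd(trait) == 0)
    stop("score and trait must be non-constant")
  stats::cor(scores, trait)^2
}

#' Leave-one-SNP-out PIVS models
#'
#' Refits (not merely reweights) the PIVS without each instrument in turn.
#'
#' @inheritParams fit_pivs
#' @param model the fitted full `pivs_model`.
#' @return named list of k `pivs_model`s, one per left-out instrument.
#' @export
loso_models <- function(model, gm, trait, covariates = NULL) {
  ids <- model$instruments$id
  if (length(ids) < 2)
    stop("leave-one-SNP-out is undefined for a single-instrument model")
  out <- lapply(seq_along(ids), function(k)
    fit_pivs(gm, trait, covariates, candidates = ids[-k],
             trait_name = model$trait))
  names(out) <- ids
  out
}

phewas_one <- function(score, y, Ccov, type) {
  keep <- !is.na(y)
  score <- score[keep]
  y <- y[keep]
  Ccov <- Ccov[keep, , drop = FALSE]
  fit <- if (type == "binary") logistic_scan(matrix(score), y, Ccov, refine_p = 1)
         else linear_scan(matrix(score), std1(y), Ccov)
  c(fit$beta, fit$standard_error, fit$p_value)
}

#' Phenome-wide association scan of PIVS scores
#'
#' Quantitative outcomes are standardized in the evaluation sample and
#' regressed on the score plus covariates (estimate = outcome SD per unit
#' score, i.e. per 1 SD of the diastolic trait); binary outcomes use
#' logistic regression (log-odds per unit score). Benjamini-Hochberg
#' adjustment is applied within each score's phenotype family. Outcomes with
#' zero variance are skipped and reported.
#'
#' @param scores named list of score vectors (one per diastolic trait) or a
#'   single numeric vector.
#' @param phenotypes data frame of outcomes (binary columns must be 0/1).
#' @param covariates covariate data frame.
#' @param fdr_alpha FDR level.
#' @return a `phewas_result` data frame: pivs_trait, phenotype, type,
#'   estimate, standard_error, p_value, p_adj, significant; skipped outcomes
#'   in `attr(, "skipped")`.
#' @export
run_phewas <- function(scores, phenotypes, covariates = NULL,
                       fdr_alpha = 0.05) {
  if (!is.list(scores)) scores <- list(pivs = scores)
  n <- nrow(phenotypes)
  Ccov <- build_covariate_matrix(covariates, n)
  skipped <- character(0)
  rows <- list()
  for (sc_name in names(scores)) {
    s <- scores[[sc_name]]
    for (ph in names(phenotypes)) {
      y <- phenotypes[[ph]]
      if (stats::sd(y, na.rm = TRUE) == 0) {
        skipped <- union(skipped, ph)
        next
      }
      type <- if (all(y %in% c(0, 1, NA))) "binary" else "quantitative"
      est <- phewas_one(s, y, Ccov, type)
      rows[[length(rows) + 1L]] <- data.frame(
        pivs_trait = sc_name, phenotype = ph, type = type,
        estimate = est[1], standard_error = est[2], p_value = est[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (sc_name in unique(out$pivs_trait)) {
    sel <- out$pivs_trait == sc_name
    out$p_adj[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out$significant <- out$p_adj < fdr_alpha
  attr(out, "skipped") <- skipped
  class(out) <- c("phewas_result", "data.frame")
  out
}

#' Leave-one-SNP-out sensitivity flags for PheWAS associations
#'
#' For each significant (trait, phenotype) association, re-runs the
#' association with every leave-one-SNP-out score; the flag passes only when
#' every re-analysis remains significant after Benjamini-Hochberg adjustment
#' computed across the k leave-one-out p-values of that (trait, phenotype)
#' combination. This vetoes associations driven by a single variant.
#'
#' @param results a `phewas_result` from [run_phewas()].
#' @param loso_scores named list: per pivs trait, a list of k score vectors.
#' @param phenotypes,covariates as in [run_phewas()].
#' @param fdr_alpha FDR level for the leave-one-out rule.
#' @return `results` with a logical `loso_pass` column (NA where the main
#'   association was not significant or no leave-one-out set exists).
#' @export
loso_sensitivity <- function(results, loso_scores, phenotypes,
                             covariates = NULL, fdr_alpha = 0.05) {
  n <- nrow(phenotypes)
  Ccov <- build_covariate_matrix(covariates, n)
  results$loso_pass <- NA
  for (i in seq_len(nrow(results))) {
    if (!isTRUE(results$significant[i])) next
    sets <- loso_scores[[results$pivs_trait[i]]]
    if (is.null(sets)) next
    y <- phenotypes[[results$phenotype[i]]]
    p_loso <- vapply(sets, function(s)
      phewas_one(s, y, Ccov, results$type[i])[3], numeric(1))
    p_adj <- stats::p.adjust(p_loso, method = "BH")
    results$loso_pass[i] <- all(p_adj < fdr_alpha)
  }
  results
}
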