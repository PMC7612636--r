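# Synthetic cohort generation: genotypes with block LD, polygenic traits with
# covariate effects, liability-threshold endpoints, cine geometry with planted
# diastolic phenotypes, loss-of-function carriers, and cohort splitting.
# Every generator is a pure function of its arguments including the seed.

#' Simulate a genotype matrix with block linkage disequilibrium
#'
#' Genotypes are produced from a latent Gaussian copula: two haplotype layers
#' of standard normal variables with an exchangeable correlation
#' `within_block_r` inside each block (independent across blocks) are
#' thresholded at the allele-frequency quantile of each variant and summed to
#' a dosage in \{0, 1, 2\}. The thresholding attenuates the allelic
#' correlation somewhat relative to the latent correlation, as for any
#' discretized copula; pairwise dosage r2 is approximately
#' `within_block_r^2` within a block and approximately zero across blocks.
#'
#' Blocks are laid out along `n_chrom` chromosomes with 1 kb spacing within a
#' block and a `block_gap_bp` gap between blocks, so that a clumping or
#' LD-score window of 1000 kb never spans two blocks.
#'
#' @param n_samples number of individuals (>= 2).
#' @param n_blocks,block_size number and size of LD blocks; the panel has
#'   `n_blocks * block_size` variants.
#' @param within_block_r latent exchangeable correlation inside a block, in
#'   `[0, 1)`; a length-2 vector is treated as a range from which each
#'   block's correlation is drawn uniformly (varying LD across blocks, as in
#'   real genomes).
#' @param maf_range range of effect-allele frequencies, a subset of (0, 0.5].
#' @param missing_rate fraction of dosages set missing at random.
#' @param n_chrom number of chromosomes the blocks are spread over.
#' @param block_gap_bp base-pair gap separating consecutive blocks.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return an object of class `genotype_matrix`: a list with `dosages`
#'   (samples x variants integer matrix, possibly with NAs) and `variants`
#'   (data frame: id, chrom, pos, effect_allele, other_allele, eaf).
#' @export
simulate_ld_genotypes <- function(n_samples, n_blocks = 50, block_size = 10,
                                  within_block_r = 0.8,
                                  maf_range = c(0.05, 0.5),
                                  missing_rate = 0, n_chrom = 22,
                                  block_gap_bp = 2e6, seed = 1) {
  if (n_samples < 2 || n_blocks < 1 || block_size < 1)
    stop("n_samples, n_blocks and block_size must be positive (n_samples >= 2)")
  if (any(within_block_r < 0) || any(within_block_r >= 1) ||
      !length(within_block_r) %in% 1:2)
    stop("within_block_r must lie in [0, 1)")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      diff(maf_range) < 0)
    stop("maf_range must be an increasing range inside (0, 0.5]")
  m <- n_blocks * block_size
  withr::with_seed(child_seed(seed, 1L), {
    eaf <- stats::runif(m, maf_range[1], maf_range[2])
    thr <- stats::qnorm(1 - eaf)
    block_of <- rep(seq_len(n_blocks), each = block_size)
    r_block <- if (length(within_block_r) == 2)
      stats::runif(n_blocks, within_block_r[1], within_block_r[2])
    else rep(within_block_r, n_blocks)
    # block-wise latent draws keep the peak memory footprint small
    D <- matrix(0L, n_samples, m)
    for (hap in 1:2) {
      for (b in seq_len(n_blocks)) {
        cols <- which(block_of == b)
        r <- r_block[b]
        z <- sqrt(r) * stats::rnorm(n_samples) +
          sqrt(1 - r) * matrix(stats::rnorm(n_samples * length(cols)),
                               n_samples, length(cols))
        D[, cols] <- D[, cols] + (z > rep(thr[cols], each = n_samples))
      }
    }
    storage.mode(D) <- "integer"
    # non-complementary allele pairs: strand-unambiguous like imputed panels
    pairs <- cbind(c("A", "A", "C", "C", "G", "G", "T", "T"),
                   c("C", "G", "A", "T", "A", "T", "C", "G"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    chrom_of_block <- ((seq_len(n_blocks) - 1L) %% n_chrom) + 1L
    idx_on_chrom <- stats::ave(seq_len(n_blocks), chrom_of_block,
                               FUN = seq_along)
    pos <- (idx_on_chrom[block_of] - 1L) * block_gap_bp +
      (seq_len(m) - (block_of - 1L) * block_size) * 1000
    variants <- data.frame(
      id = sprintf("rs%06d", seq_len(m)),
      chrom = as.character(chrom_of_block[block_of]),
      pos = as.integer(pos),
      effect_allele = pairs[pick, 1],
      other_allele = pairs[pick, 2],
      eaf = eaf,
      block = block_of,
      block_r = r_block[block_of],
      stringsAsFactors = FALSE
    )
    if (missing_rate > 0) {
      miss <- stats::runif(length(D)) < missing_rate
      D[miss] <- NA_integer_
    }
    dimnames(D) <- list(sprintf("ID%05d", seq_len(n_samples)), variants$id)
    new_genotype_matrix(D, variants)
  })
}

new_genotype_matrix <- function(dosages, variants) {
  stopifnot(ncol(dosages) == nrow(variants))
  rg <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (is.finite(rg[1]) &&
      (rg[1] < 0 || rg[2] > 2 || any(rg != floor(rg))))
    stop("dosages must be in {0, 1, 2} or missing")
  if (anyDuplicated(rownames(dosages))) stop("sample ids must be unique")
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%d chromosome(s))\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#' @param gm a `genotype_matrix`.
#' @param samples,variants row names / variant ids (or indices) to keep.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  D <- gm$dosages
  v <- gm$variants
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, v$id) else variants
    if (anyNA(j)) stop("unknown variant ids: ",
                       paste(variants[is.na(j)], collapse = ", "))
    D <- D[, j, drop = FALSE]
    v <- v[j, , drop = FALSE]
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, rownames(gm$dosages)) else samples
    if (anyNA(i)) stop("unknown sample ids")
    D <- D[i, , drop = FALSE]
  }
  rownames(v) <- NULL
  new_genotype_matrix(D, v)
}

#' Simulate baseline covariates for a cohort
#'
#' Draws demographic, anthropometric and haemodynamic covariates with
#' means and dispersions typical of an imaging biobank population
#' (age ~ 64 +/- 8 y, BSA ~ 1.9 m2, SBP ~ 138 mmHg, resting pulse ~ 70 bpm,
#' diabetes prevalence ~ 6%), plus ten standard-normal ancestry components.
#'
#' @param n number of individuals.
#' @param seed integer seed.
#' @return data frame with columns sample_id, age, sex, height, weight, bmi,
#'   sbp, dbp, pulse, diabetes, pc1..pc10.
#' @export
simulate_covariates <- function(n, seed = 1) {
  withr::with_seed(child_seed(seed, 2L), {
    sex <- stats::rbinom(n, 1, 0.48)
    height <- stats::rnorm(n, 1.69 + 0.07 * sex, 0.07)
    bmi <- pmax(16, stats::rnorm(n, 26.5, 4.4))
    weight <- bmi * height^2
    cov <- data.frame(
      sample_id = sprintf("ID%05d", seq_len(n)),
      age = pmin(85, pmax(40, stats::rnorm(n, 63.6, 7.6))),
      sex = sex,
      height = height,
      weight = weight,
      bmi = bmi,
      sbp = stats::rnorm(n, 138.2, 18.3),
      dbp = stats::rnorm(n, 78.6, 9.9),
      pulse = stats::rnorm(n, 70, 12),
      diabetes = stats::rbinom(n, 1, 0.062),
      stringsAsFactors = FALSE
    )
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    cbind(cov, as.data.frame(pcs))
  })
}

# Draw per-variant effects for k traits sharing one causal set, with an
# effect-size correlation matrix inducing the genetic correlation.
draw_shared_effects <- function(n_causal, rg) {
  k <- nrow(rg)
  L <- chol(rg)
  matrix(stats::rnorm(n_causal * k), n_causal, k) %*% L
}

# Scale genetic values and residuals so that var(g) / var(g + e) equals the
# target exactly in-sample (residual orthogonalized against g first).
calibrate_h2 <- function(g_raw, h2, n) {
  e <- stats::rnorm(n)
  if (h2 >= 1) return(list(g = std1(g_raw) * 1, e = rep(0, n)))
  if (h2 <= 0 || stats::sd(g_raw) == 0) {
    return(list(g = rep(0, n), e = std1(e)))
  }
  g <- std1(g_raw) * sqrt(h2)
  e <- e - g * (stats::cov(e, g) / stats::var(g))
  e <- std1(e) * sqrt(1 - h2)
  list(g = g, e = e)
}

#' Simulate polygenic quantitative traits on a genotype matrix
#'
#' Traits share one causal-variant set; per-variant effects on the
#' standardized dosage scale are drawn from a multivariate Gaussian whose
#' correlation matrix `rg_structure` induces the genetic correlation between
#' traits. Genetic values are rescaled so the realized sample heritability
#' (variance of the genetic value over variance of genetic value plus
#' residual) equals `h2_target` exactly; the residual is orthogonalized
#' against the genetic value in-sample, so trait = covariate part + genetic
#' value + residual holds term by term.
#'
#' @param gm a `genotype_matrix`.
#' @param n_causal number of causal variants (<= number of variants).
#' @param h2_target per-trait heritability in `[0, 1]` (recycled).
#' @param covariate_effects optional named list (one element per trait) of
#'   named coefficients applied to standardized covariate columns.
#' @param rg_structure trait-by-trait effect correlation matrix (identity by
#'   default).
#' @param trait_names names for the trait columns.
#' @param covariates optional covariate data frame (simulated when NULL).
#' @param seed integer seed.
#' @return list with `traits` (a trait table data frame) and `truth` (a
#'   ground-truth list: causal effects, realized h2 and genetic correlation,
#'   genetic values and residuals).
#' @export
simulate_traits <- function(gm, n_causal, h2_target,
                            covariate_effects = NULL, rg_structure = NULL,
                            trait_names = NULL, covariates = NULL, seed = 1) {
  m <- ncol(gm$dosages)
  n <- nrow(gm$dosages)
  if (n_causal > m) stop("n_causal exceeds the number of variants")
  k <- max(length(h2_target), length(trait_names %||% h2_target))
  h2 <- rep_len(h2_target, k)
  if (any(h2 < 0 | h2 > 1)) stop("h2_target must lie in [0, 1]")
  trait_names <- trait_names %||% paste0("trait", seq_len(k))
  rg <- rg_structure %||% diag(k)
  if (!isTRUE(all.equal(dim(rg), c(k, k)))) stop("rg_structure has wrong size")
  if (is.null(covariates)) covariates <- simulate_covariates(n, seed)
  withr::with_seed(child_seed(seed, 3L), {
    causal_idx <- sort(sample.int(m, n_causal))
    A <- draw_shared_effects(n_causal, rg)          # standardized-dosage scale
    # standardized-dosage product accumulated in chunks to bound peak memory
    G_raw <- matrix(0, n, k)
    sds <- numeric(n_causal)
    chunk <- 500L
    for (j0 in seq(1L, n_causal, by = chunk)) {
      jj <- j0:min(j0 + chunk - 1L, n_causal)
      Xc <- impute_dosages(gm$dosages[, causal_idx[jj], drop = FALSE])
      storage.mode(Xc) <- "double"
      s <- col_sds(Xc)
      s[s == 0] <- 1
      sds[jj] <- s
      G_raw <- G_raw + scale(Xc, center = TRUE, scale = s) %*%
        A[jj, , drop = FALSE]
    }
    G <- E <- matrix(0, n, k)
    for (j in seq_len(k)) {
      g_raw <- G_raw[, j]
      cal <- calibrate_h2(g_raw, h2[j], n)
      # rescale stored effects so that the standardized causal dosages times
      # beta_std reproduce the genetic value exactly (up to centering)
      A[, j] <- if (h2[j] > 0 && stats::sd(g_raw) > 0)
        A[, j] * sqrt(h2[j]) / stats::sd(g_raw) else 0
      G[, j] <- cal$g
      E[, j] <- cal$e
    }
    tt <- covariates
    cov_part <- matrix(0, n, k)
    for (j in seq_len(k)) {
      eff <- numeric(0)
      if (!is.null(covariate_effects)) {
        if (!is.null(names(covariate_effects))) {
          if (trait_names[j] %in% names(covariate_effects))
            eff <- covariate_effects[[trait_names[j]]]
        } else if (j <= length(covariate_effects)) {
          eff <- covariate_effects[[j]] %||% numeric(0)
        }
      }
      for (nm in names(eff)) {
        cov_part[, j] <- cov_part[, j] + eff[[nm]] * std1(covariates[[nm]])
      }
      tt[[trait_names[j]]] <- cov_part[, j] + G[, j] + E[, j]
    }
    truth <- list(
      causal = data.frame(
        variant_id = rep(gm$variants$id[causal_idx], k),
        trait = rep(trait_names, each = n_causal),
        beta_std = as.vector(A),
        beta_dosage = as.vector(sweep(A, 1, sds, "/")),
        stringsAsFactors = FALSE
      ),
      h2 = stats::setNames(h2, trait_names),
      rg_target = rg,
      rg_realized = if (k > 1 && all(h2 > 0)) stats::cor(G) else NULL,
      genetic_values = `colnames<-`(G, trait_names),
      residuals = `colnames<-`(E, trait_names),
      covariate_part = `colnames<-`(cov_part, trait_names),
      trait_names = trait_names
    )
    list(traits = tt, truth = truth)
  })
}

#' Simulate binary endpoints from a liability threshold model
#'
#' The latent liability is a weighted sum of standardized trait columns plus
#' Gaussian noise; a subject is an (ever-) case when liability exceeds the
#' empirical quantile matching `prevalence`. Cases are split into a
#' baseline-disease flag and an incident (follow-up conversion) flag.
#'
#' @param tt trait table data frame.
#' @param liability_weights named list, one element per endpoint: named
#'   numeric vector of weights on columns of `tt`.
#' @param prevalence named numeric vector of ever-case prevalences in (0, 1).
#' @param noise_sd standard deviation of the liability noise (0 allowed).
#' @param baseline_fraction fraction of cases prevalent at baseline.
#' @param seed integer seed.
#' @return `tt` with three extra columns per endpoint: `<name>` (ever),
#'   `<name>_baseline` and `<name>_incident`; liability details in
#'   `attr(, "endpoint_truth")`.
#' @export
simulate_binary_endpoints <- function(tt, liability_weights, prevalence,
                                      noise_sd = 1, baseline_fraction = 0.3,
                                      seed = 1) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)")
  n <- nrow(tt)
  truth <- list()
  withr::with_seed(child_seed(seed, 4L), {
    for (ep in names(liability_weights)) {
      w <- liability_weights[[ep]]
      L <- rep(0, n)
      for (nm in names(w)) L <- L + w[[nm]] * std1(tt[[nm]])
      L <- L + stats::rnorm(n, 0, noise_sd)
      thr <- stats::quantile(L, 1 - prevalence[[ep]], names = FALSE, type = 7)
      ever <- as.integer(L > thr)
      baseline <- as.integer(ever == 1L &
                               stats::runif(n) < baseline_fraction)
      tt[[ep]] <- ever
      tt[[paste0(ep, "_baseline")]] <- baseline
      tt[[paste0(ep, "_incident")]] <- as.integer(ever == 1L & baseline == 0L)
      truth[[ep]] <- list(threshold = thr, weights = w, noise_sd = noise_sd)
    }
  })
  attr(tt, "endpoint_truth") <- truth
  tt
}

#' Split sample ids into imaging and non-imaging cohorts
#'
#' @param sample_ids character vector of ids.
#' @param imaging_fraction fraction assigned to the imaging cohort, in (0, 1).
#' @param seed integer seed.
#' @return list with `imaging` and `nonimaging` id vectors; a disjoint,
#'   exhaustive partition of the input.
#' @export
split_cohorts <- function(sample_ids, imaging_fraction, seed = 1) {
  if (imaging_fraction <= 0 || imaging_fraction >= 1)
    stop("imaging_fraction must lie strictly inside (0, 1)")
  n <- length(sample_ids)
  withr::with_seed(child_seed(seed, 5L), {
    n_img <- round(n * imaging_fraction)
    img <- sort(sample.int(n, n_img))
  })
  list(imaging = sample_ids[img], nonimaging = sample_ids[-img])
}

#' Simulate loss-of-function carrier indicators with planted trait effects
#'
#' @param n_samples number of individuals.
#' @param genes character vector of gene names.
#' @param carrier_freq per-gene carrier probability in (0, 1), recycled.
#' @param effect_per_gene named numeric vector of trait increments (in trait
#'   SD) for carriers; genes absent from it have no effect.
#' @param seed integer seed.
#' @return list with `carriers` (samples x genes 0/1 matrix),
#'   `trait_increment` (per-sample vector) and `truth` (effect genes).
#' @export
simulate_lof_carriers <- function(n_samples, genes, carrier_freq = 0.005,
                                  effect_per_gene = numeric(0), seed = 1) {
  if (any(carrier_freq <= 0 | carrier_freq >= 1))
    stop("carrier_freq must lie strictly inside (0, 1)")
  g <- length(genes)
  freq <- rep_len(carrier_freq, g)
  withr::with_seed(child_seed(seed, 6L), {
    C <- matrix(stats::rbinom(n_samples * g, 1, rep(freq, each = n_samples)),
                n_samples, g, dimnames = list(NULL, genes))
  })
  eff <- stats::setNames(rep(0, g), genes)
  eff[names(effect_per_gene)] <- effect_per_gene
  list(carriers = C,
       trait_increment = drop(C %*% eff),
       truth = list(effects = eff, carrier_freq = freq))
}
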