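# Variant QC, covariate-adjusted association scans, LD utilities, greedy
# clumping, LD-score regression for heritability and genetic correlation,
# and gene-level loss-of-function burden association.

# log P(n_het = h | n, n_effect_alleles) for the exact conditional HWE
# distribution (Wigginton-style), vectorized over h.
hwe_log_prob <- function(h, n, nA) {
  na <- 2L * n - nA
  nAA <- (nA - h) / 2
  naa <- (na - h) / 2
  lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(naa + 1) +
    h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the two-sided p-value sums the probabilities of all heterozygote counts no
#' more probable than the observed one (no mid-p correction). Monomorphic
#' variants return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return two-sided exact p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n - nA
  if (nA == 0 || na == 0) return(1)
  h_grid <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  lp <- hwe_log_prob(h_grid, n, nA)
  lp <- lp - max(lp)
  p_obs <- lp[match(n_Aa, h_grid)]
  min(1, sum(exp(lp[lp <= p_obs + 1e-12])) / sum(exp(lp)))
}

genotype_counts <- function(D, chunk = 200L) {
  m <- ncol(D)
  out <- matrix(0L, m, 3, dimnames = list(NULL, c("n_AA", "n_Aa", "n_aa")))
  for (j0 in seq(1L, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, m)
    Dj <- D[, jj, drop = FALSE]
    n1 <- colSums(Dj == 1L, na.rm = TRUE)
    n2 <- colSums(Dj == 2L, na.rm = TRUE)
    n_obs <- colSums(!is.na(Dj))
    out[jj, ] <- cbind(n2, n1, n_obs - n1 - n2)
  }
  out
}

# Batched exact HWE p-values: one concatenated conditional distribution over
# all variants, evaluated with vectorized lgamma and summed per variant.
hwe_test_batch <- function(counts) {
  n <- rowSums(counts)
  nA <- 2L * counts[, "n_AA"] + counts[, "n_Aa"]
  na <- 2L * n - nA
  p <- rep(1, nrow(counts))
  todo <- which(nA > 0 & na > 0)
  if (!length(todo)) return(p)
  lens <- (pmin(nA, na)[todo] - (nA[todo] %% 2L)) %/% 2L + 1L
  var_of <- rep.int(todo, lens)
  h <- unlist(lapply(todo, function(j)
    seq.int(nA[j] %% 2L, pmin(nA, na)[j], by = 2L)), use.names = FALSE)
  lp <- hwe_log_prob(h, n[var_of], nA[var_of])
  grp <- match(var_of, todo)                     # 1..length(todo)
  mx <- vapply(split(lp, grp), max, numeric(1))
  lp <- lp - mx[grp]
  pr <- exp(lp)
  is_obs <- h == counts[var_of, "n_Aa"]
  obs_lp <- numeric(length(todo))
  obs_lp[grp[is_obs]] <- lp[is_obs]
  le <- lp <= obs_lp[grp] + 1e-12
  num <- rowsum(pr * le, grp)
  den <- rowsum(pr, grp)
  p[todo] <- pmin(1, num[, 1] / den[, 1])
  p
}

#' Variant quality control filter
#'
#' Retains variants with minor allele frequency >= `maf_min` and exact
#' Hardy-Weinberg p-value >= `hwe_p_min` (i.e. removes HWE p < `hwe_p_min`
#' and MAF < `maf_min`), reporting per-variant reasons. For a
#' `genotype_matrix` both filters apply; for a summary-statistics table only
#' the frequency filter can be evaluated.
#'
#' @param x a `genotype_matrix` or `summary_stats` data frame.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum exact HWE p-value.
#' @return list with `retained` (filtered object) and `report` (data frame:
#'   variant_id, maf, hwe_p, keep, reason).
#' @export
qc_filter <- function(x, maf_min = 0.005, hwe_p_min = 0.05) {
  if (inherits(x, "genotype_matrix")) {
    cnt <- genotype_counts(x$dosages)
    n_obs <- rowSums(cnt)
    eaf <- (2 * cnt[, "n_AA"] + cnt[, "n_Aa"]) / (2 * n_obs)
    maf <- pmin(eaf, 1 - eaf)
    hwe_p <- hwe_test_batch(cnt)
    keep <- maf >= maf_min & hwe_p >= hwe_p_min
    reason <- rep(NA_character_, length(keep))
    reason[maf < maf_min] <- "MAF"
    reason[hwe_p < hwe_p_min] <-
      ifelse(maf[hwe_p < hwe_p_min] < maf_min, "MAF;HWE", "HWE")
    report <- data.frame(variant_id = x$variants$id, maf = maf, hwe_p = hwe_p,
                         keep = keep, reason = reason,
                         stringsAsFactors = FALSE, row.names = NULL)
    retained <- subset_genotypes(x, variants = which(keep))
  } else {
    eaf <- x$effect_allele_frequency
    maf <- pmin(eaf, 1 - eaf)
    keep <- maf >= maf_min
    report <- data.frame(variant_id = x$variant_id, maf = maf,
                         hwe_p = NA_real_, keep = keep,
                         reason = ifelse(keep, NA_character_, "MAF"),
                         stringsAsFactors = FALSE)
    retained <- x[keep, , drop = FALSE]
  }
  list(retained = retained, report = report)
}

# Residualize the columns of X against [1, C] via the thin QR of the
# covariate block.
residualize <- function(X, C) {
  qrC <- qr(C)
  X - qr.Q(qrC) %*% (t(qr.Q(qrC)) %*% X)
}

build_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  C <- cbind(`(Intercept)` = 1, C)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
  C
}

# Vectorized covariate-adjusted linear scan: per column of X, the slope from
# regressing y on [1, C, x] (Frisch-Waugh partialling). `y` may be a matrix
# with one column per trait; a list of per-trait data frames is returned.
# Variants are processed in chunks so peak memory stays bounded for
# biobank-scale panels.
linear_scan_multi <- function(X, Y, C, chunk = 500L) {
  n <- nrow(Y)
  m <- ncol(X)
  qrC <- qr(C)
  Q <- qr.Q(qrC)
  Yr <- Y - Q %*% crossprod(Q, Y)
  sxx <- numeric(m)
  sxy <- matrix(0, m, ncol(Y))
  for (j0 in seq(1L, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, m)
    Xc <- X[, jj, drop = FALSE]
    storage.mode(Xc) <- "double"
    Xc <- Xc - Q %*% crossprod(Q, Xc)
    sxx[jj] <- colSums(Xc^2)
    sxy[jj, ] <- crossprod(Xc, Yr)
  }
  bad <- sxx <= 1e-10
  df <- n - ncol(C) - 1L
  lapply(seq_len(ncol(Y)), function(tj) {
    beta <- sxy[, tj] / sxx
    beta[bad] <- NA_real_
    rss <- pmax(sum(Yr[, tj]^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / df / sxx)
    se[!is.finite(se) | se <= 0] <- NA_real_
    p <- 2 * stats::pt(-abs(beta / se), df)
    data.frame(beta = beta, standard_error = se, p_value = p)
  })
}

linear_scan <- function(X, y, C) {
  linear_scan_multi(X, matrix(y), C)[[1]]
}

# Full per-variant logistic IRLS, warm-started from the covariate-only null
# model. Returns NA on separation or non-convergence.
logistic_refit <- function(X, y, C, null_coef, max_iter = 25, tol = 1e-8) {
  beta0 <- c(null_coef, 0)
  p_idx <- ncol(C) + 1L
  M <- cbind(C, 0)
  out <- matrix(NA_real_, ncol(X), 2)
  for (j in seq_len(ncol(X))) {
    M[, p_idx] <- X[, j]
    b <- beta0
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(M %*% b)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      if (any(!is.finite(w)) || max(abs(b)) > 1e3) break
      XtW <- t(M * w)
      H <- XtW %*% M
      score <- drop(crossprod(M, y - mu))
      step <- tryCatch(solve(H, score), error = function(e) NULL)
      if (is.null(step)) break
      b <- b + step
      if (max(abs(step)) < tol) { ok <- TRUE; break }
    }
    if (ok) {
      eta <- drop(M %*% b)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      H <- t(M * w) %*% M
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && is.finite(V[p_idx, p_idx]) && V[p_idx, p_idx] > 0)
        out[j, ] <- c(b[p_idx], sqrt(V[p_idx, p_idx]))
    }
  }
  beta <- out[, 1]; se <- out[, 2]
  data.frame(beta = beta, standard_error = se,
             p_value = 2 * stats::pnorm(-abs(beta / se)))
}

# Hybrid logistic association scan: a vectorized efficient-score estimate
# from the covariate-only null model for every variant (beta = U / I,
# se = 1 / sqrt(I), with genotypes residualized against the covariates under
# the null weights), then a full IRLS refit for variants whose score p-value
# falls below `refine_p`, so instrument-grade effect sizes are exact while
# the genome-wide scan stays linear-algebra bound.
logistic_scan <- function(X, y, C, refine_p = 1e-4, chunk = 500L) {
  null_fit <- stats::glm.fit(C, y, family = stats::binomial())
  mu0 <- null_fit$fitted.values
  w0 <- mu0 * (1 - mu0)
  CW <- C * w0
  H0 <- crossprod(C, CW)
  m <- ncol(X)
  U <- I <- numeric(m)
  for (j0 in seq(1L, m, by = chunk)) {
    jj <- j0:min(j0 + chunk - 1L, m)
    Xc <- X[, jj, drop = FALSE]
    storage.mode(Xc) <- "double"
    Xc <- Xc - C %*% solve(H0, crossprod(CW, Xc))
    U[jj] <- crossprod(Xc, y - mu0)
    I[jj] <- colSums(w0 * Xc^2)
  }
  beta <- ifelse(I > 1e-10, U / I, NA_real_)
  se <- ifelse(I > 1e-10, 1 / sqrt(I), NA_real_)
  p <- 2 * stats::pnorm(-abs(beta / se))
  hot <- which(!is.na(p) & p < refine_p)
  if (length(hot)) {
    ref <- logistic_refit(X[, hot, drop = FALSE], y, C,
                          null_fit$coefficients)
    ok <- is.finite(ref$beta)
    beta[hot[ok]] <- ref$beta[ok]
    se[hot[ok]] <- ref$standard_error[ok]
    p[hot[ok]] <- ref$p_value[ok]
  }
  data.frame(beta = beta, standard_error = se, p_value = p)
}

#' Covariate-adjusted genome-wide association scan
#'
#' Regresses the trait on each variant's dosage with covariate adjustment;
#' missing dosages are mean-imputed per variant. Quantitative traits use
#' ordinary least squares (vectorized via partialling out the covariates);
#' binary traits use per-variant logistic regression (log-odds effect).
#' Variants whose logistic fit separates or fails are flagged missing.
#'
#' @param gm a `genotype_matrix`.
#' @param trait numeric response (binary 0/1 for `family = "logistic"`).
#' @param covariates data frame or matrix of covariates (an intercept is
#'   always included; collinear columns are dropped).
#' @param family "linear" or "logistic".
#' @param trait_name label stored with the results.
#' @return a `summary_stats` data frame with GWAS-SSF-style columns:
#'   variant_id, chromosome, base_pair_location, effect_allele, other_allele,
#'   effect_allele_frequency, beta, standard_error, p_value, n.
#' @export
run_association <- function(gm, trait, covariates = NULL,
                            family = c("linear", "logistic"),
                            trait_name = "trait") {
  family <- match.arg(family)
  n <- nrow(gm$dosages)
  multi <- is.matrix(trait) || is.data.frame(trait)
  Y <- if (multi) as.matrix(as.data.frame(trait)) else matrix(as.numeric(trait))
  if (nrow(Y) != n) stop("trait length does not match the genotype matrix")
  if (any(apply(Y, 2, stats::sd) == 0)) stop("trait is constant")
  if (family == "logistic") {
    if (multi) stop("logistic scans take one trait at a time")
    if (!all(Y %in% c(0, 1))) stop("logistic family requires a 0/1 trait")
  }
  C <- build_covariate_matrix(covariates, n)
  X <- impute_dosages(gm$dosages)
  res_list <- if (family == "linear") linear_scan_multi(X, Y, C)
              else list(logistic_scan(X, Y[, 1], C))
  eaf <- colMeans(X) / 2
  trait_names <- if (multi) colnames(Y) %||% paste0(trait_name, seq_len(ncol(Y)))
                 else trait_name
  out_list <- lapply(seq_along(res_list), function(tj) {
    res <- res_list[[tj]]
    out <- data.frame(
      variant_id = gm$variants$id,
      chromosome = gm$variants$chrom,
      base_pair_location = gm$variants$pos,
      effect_allele = gm$variants$effect_allele,
      other_allele = gm$variants$other_allele,
      effect_allele_frequency = eaf,
      beta = res$beta,
      standard_error = res$standard_error,
      p_value = res$p_value,
      n = n,
      stringsAsFactors = FALSE
    )
    attr(out, "trait") <- trait_names[tj]
    attr(out, "family") <- family
    class(out) <- c("summary_stats", "data.frame")
    out
  })
  if (multi) stats::setNames(out_list, trait_names) else out_list[[1]]
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared pairwise-complete sample correlation of the dosages of two
#' variants. Monomorphic variants give a flagged missing value.
#'
#' @param gm a `genotype_matrix`.
#' @param variant_i,variant_j variant ids or column indices.
#' @return r^2 in `[0, 1]`, or `NA` for a monomorphic variant.
#' @export
ld_r2 <- function(gm, variant_i, variant_j) {
  ij <- vapply(list(variant_i, variant_j), function(v)
    if (is.character(v)) match(v, gm$variants$id) else as.integer(v),
    integer(1))
  if (anyNA(ij)) stop("unknown variant id")
  x <- gm$dosages[, ij[1]]
  y <- gm$dosages[, ij[2]]
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
    return(structure(NA_real_, reason = "monomorphic variant"))
  stats::cor(x, y, use = "pairwise.complete.obs")^2
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the smallest-p unassigned variant with
#' `p < p_thresh` as an index and assigns to its clump every unassigned
#' variant on the same chromosome within `window_kb` whose LD r-squared with
#' the index is at least `r2_thresh`. Ties in p are broken by (chromosome,
#' position, id). Variants absent from the LD reference are treated as
#' unlinked and logged.
#'
#' @param ss a `summary_stats` data frame.
#' @param ld_reference a `genotype_matrix` supplying LD.
#' @param p_thresh index p-value threshold.
#' @param r2_thresh LD threshold for clump membership.
#' @param window_kb physical window (kb) around the index.
#' @return data frame with columns index (variant id), member, r2 (one row
#'   per clump member; indices appear with member == index and r2 = 1);
#'   attribute `index_variants` lists the index ids in selection order.
#' @export
clump <- function(ss, ld_reference, p_thresh = 1e-6, r2_thresh = 0.1,
                  window_kb = 1000) {
  ord <- order(ss$p_value, ss$chromosome, ss$base_pair_location, ss$variant_id)
  ref_idx <- match(ss$variant_id, ld_reference$variants$id)
  missing_ref <- ss$variant_id[is.na(ref_idx)]
  if (length(missing_ref))
    warning("variants absent from the LD reference treated as unlinked: ",
            paste(utils::head(missing_ref, 5), collapse = ", "),
            if (length(missing_ref) > 5) ", ...")
  D <- ld_reference$dosages
  assigned <- rep(FALSE, nrow(ss))
  rows <- list()
  index_ids <- character(0)
  for (i in ord) {
    if (assigned[i] || is.na(ss$p_value[i]) || ss$p_value[i] >= p_thresh) next
    assigned[i] <- TRUE
    index_ids <- c(index_ids, ss$variant_id[i])
    rows[[length(rows) + 1L]] <- data.frame(
      index = ss$variant_id[i], member = ss$variant_id[i], r2 = 1,
      stringsAsFactors = FALSE)
    cand <- which(!assigned &
                    ss$chromosome == ss$chromosome[i] &
                    abs(ss$base_pair_location - ss$base_pair_location[i]) <=
                      window_kb * 1000)
    if (!length(cand) || is.na(ref_idx[i])) next
    xi <- D[, ref_idx[i]]
    for (jj in cand) {
      if (is.na(ref_idx[jj])) next
      r2 <- stats::cor(xi, D[, ref_idx[jj]], use = "pairwise.complete.obs")^2
      if (is.finite(r2) && r2 >= r2_thresh) {
        assigned[jj] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          index = ss$variant_id[i], member = ss$variant_id[jj], r2 = r2,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(index = character(0), member = character(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "index_variants") <- index_ids
  attr(out, "unlinked") <- missing_ref
  out
}

#' Window-based LD scores
#'
#' For each variant j, the LD score is the sum of r-squared with every
#' variant within `window_kb` on the same chromosome, including itself
#' (so every score is at least 1).
#'
#' @param x a `genotype_matrix`, or a square LD correlation-squared matrix
#'   (then `positions` and `chrom` describe the variants).
#' @param window_kb window half-width in kb.
#' @param positions,chrom required when `x` is a matrix.
#' @return data frame with columns variant_id, chromosome,
#'   base_pair_location, ell.
#' @export
ld_scores <- function(x, window_kb = 1000, positions = NULL, chrom = NULL) {
  if (inherits(x, "genotype_matrix")) {
    n <- nrow(x$dosages)
    v <- x$variants
    ell <- numeric(nrow(v))
    # standardize one chromosome at a time to bound peak memory
    for (ch in unique(v$chrom)) {
      j_ch <- which(v$chrom == ch)
      j_ch <- j_ch[order(v$pos[j_ch])]
      D <- impute_dosages(x$dosages[, j_ch, drop = FALSE])
      storage.mode(D) <- "double"
      sds <- col_sds(D)
      mono <- sds == 0                     # monomorphic: r2 with others = 0
      sds[mono] <- Inf
      Z <- scale(D, center = TRUE, scale = sds)
      pos <- v$pos[j_ch]
      lo <- 1L
      hi <- 1L
      for (k in seq_along(j_ch)) {
        while (pos[k] - pos[lo] > window_kb * 1000) lo <- lo + 1L
        while (hi < length(j_ch) && pos[hi + 1L] - pos[k] <= window_kb * 1000)
          hi <- hi + 1L
        r <- drop(crossprod(Z[, k], Z[, lo:hi, drop = FALSE])) / (n - 1)
        ell[j_ch[k]] <- sum(r^2, na.rm = TRUE) + (if (mono[k]) 1 else 0)
      }
    }
    data.frame(variant_id = v$id, chromosome = v$chrom,
               base_pair_location = v$pos, ell = pmax(ell, 1),
               stringsAsFactors = FALSE)
  } else {
    if (is.null(positions)) stop("positions required for a matrix input")
    m <- nrow(x)
    chrom <- chrom %||% rep("1", m)
    ell <- vapply(seq_len(m), function(j) {
      in_win <- chrom == chrom[j] &
        abs(positions - positions[j]) <= window_kb * 1000
      sum(x[j, in_win])
    }, numeric(1))
    data.frame(variant_id = rownames(x) %||% sprintf("v%d", seq_len(m)),
               chromosome = chrom, base_pair_location = positions,
               ell = pmax(ell, 1), stringsAsFactors = FALSE)
  }
}

ldsc_wls <- function(yy, ell, w) {
  W <- sum(w)
  mx <- sum(w * ell) / W
  my <- sum(w * yy) / W
  slope <- sum(w * (ell - mx) * (yy - my)) / sum(w * (ell - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

jackknife_blocks <- function(m, n_blocks) {
  split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))
}

#' LD-score regression heritability
#'
#' Weighted regression of per-variant association chi-squared statistics on
#' LD scores with a free intercept; the slope times m / n estimates the SNP
#' heritability. Weights are 1 / max(ell, 1) in a single step; the standard
#' error comes from a delete-one block jackknife over contiguous blocks in
#' (chromosome, position) order.
#'
#' @param ss a `summary_stats` data frame.
#' @param scores LD-score data frame from [ld_scores()].
#' @param n GWAS sample size (defaults to the median of `ss$n`).
#' @param m number of variants in the heritability denominator.
#' @param n_blocks jackknife blocks.
#' @return a `heritability_estimate`: list with h2, se, intercept,
#'   intercept_se, method.
#' @export
ldsc_h2 <- function(ss, scores, n = NULL, m = NULL, n_blocks = 20) {
  dat <- merge(as.data.frame(ss)[, c("variant_id", "chromosome",
                                     "base_pair_location", "beta",
                                     "standard_error", "n")],
               scores[, c("variant_id", "ell")], by = "variant_id")
  dat <- dat[order(dat$chromosome, dat$base_pair_location, dat$variant_id), ]
  dat <- dat[is.finite(dat$beta) & is.finite(dat$standard_error), ]
  n <- n %||% stats::median(dat$n)
  m <- m %||% nrow(dat)
  if (nrow(dat) < n_blocks) stop("fewer variants than jackknife blocks")
  chi2 <- (dat$beta / dat$standard_error)^2
  ell <- pmax(dat$ell, 1)
  w <- 1 / ell
  # second pass: include the chi-squared variance term implied by the
  # first-pass heritability (standard LDSC weighting)
  h2_1 <- max(0, unname(ldsc_wls(chi2, dat$ell, w)["slope"]) * m / n)
  w <- 1 / (ell * (1 + n * h2_1 * ell / m)^2)
  fit <- ldsc_wls(chi2, dat$ell, w)
  h2 <- unname(fit["slope"]) * m / n
  blocks <- jackknife_blocks(nrow(dat), n_blocks)
  jk <- vapply(blocks, function(b) {
    f <- ldsc_wls(chi2[-b], dat$ell[-b], w[-b])
    c(f["slope"] * m / n, f["intercept"])
  }, numeric(2))
  B <- length(blocks)
  se <- sqrt((B - 1) / B * sum((jk[1, ] - mean(jk[1, ]))^2))
  int_se <- sqrt((B - 1) / B * sum((jk[2, ] - mean(jk[2, ]))^2))
  structure(list(h2 = h2, se = se, intercept = unname(fit["intercept"]),
                 intercept_se = int_se, n = n, m = m,
                 method = "ldsc-1step-weighted"),
            class = "heritability_estimate")
}

#' @exportS3Method base::print
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("LDSC h2 = %.4f (SE %.4f), intercept = %.3f (SE %.3f)\n",
              x$h2, x$se, x$intercept, x$intercept_se))
  invisible(x)
}

#' LD-score regression genetic correlation
#'
#' Regresses the product of per-variant z-scores of two traits on LD scores;
#' the slope times m / sqrt(n_a * n_b) estimates the genetic covariance,
#' normalized by the two LDSC heritabilities to a genetic correlation.
#' Returns a flagged missing estimate when either heritability is
#' non-positive; estimates with |rg| > 1.25 carry a `clipped` flag.
#'
#' @param ss_a,ss_b `summary_stats` on a shared variant universe.
#' @param scores LD scores.
#' @param n_a,n_b study sample sizes.
#' @param m variant count in the denominator.
#' @param n_blocks jackknife blocks.
#' @return list with rg, se, gcov, h2_a, h2_b, clipped.
#' @export
ldsc_rg <- function(ss_a, ss_b, scores, n_a = NULL, n_b = NULL, m = NULL,
                    n_blocks = 20) {
  a <- as.data.frame(ss_a)
  b <- as.data.frame(ss_b)
  dat <- merge(merge(a[, c("variant_id", "chromosome", "base_pair_location",
                           "beta", "standard_error", "n")],
                     b[, c("variant_id", "beta", "standard_error", "n")],
                     by = "variant_id", suffixes = c("_a", "_b")),
               scores[, c("variant_id", "ell")], by = "variant_id")
  dat <- dat[order(dat$chromosome, dat$base_pair_location, dat$variant_id), ]
  ok <- is.finite(dat$beta_a) & is.finite(dat$beta_b) &
    is.finite(dat$standard_error_a) & is.finite(dat$standard_error_b)
  dat <- dat[ok, ]
  n_a <- n_a %||% stats::median(dat$n_a)
  n_b <- n_b %||% stats::median(dat$n_b)
  m <- m %||% nrow(dat)
  za <- dat$beta_a / dat$standard_error_a
  zb <- dat$beta_b / dat$standard_error_b
  ell <- pmax(dat$ell, 1)
  w1 <- 1 / ell
  # second-pass weights from first-pass heritabilities (standard LDSC)
  h2a_1 <- max(0, unname(ldsc_wls(za^2, dat$ell, w1)["slope"]) * m / n_a)
  h2b_1 <- max(0, unname(ldsc_wls(zb^2, dat$ell, w1)["slope"]) * m / n_b)
  wa <- 1 / (ell * (1 + n_a * h2a_1 * ell / m)^2)
  wb <- 1 / (ell * (1 + n_b * h2b_1 * ell / m)^2)
  wab <- 1 / (ell * (1 + n_a * h2a_1 * ell / m) * (1 + n_b * h2b_1 * ell / m))
  est_all <- function(keep) {
    fa <- ldsc_wls(za[keep]^2, dat$ell[keep], wa[keep])
    fb <- ldsc_wls(zb[keep]^2, dat$ell[keep], wb[keep])
    fab <- ldsc_wls((za * zb)[keep], dat$ell[keep], wab[keep])
    h2a <- fa["slope"] * m / n_a
    h2b <- fb["slope"] * m / n_b
    gcov <- fab["slope"] * m / sqrt(n_a * n_b)
    c(h2a = unname(h2a), h2b = unname(h2b), gcov = unname(gcov),
      rg = unname(gcov / sqrt(h2a * h2b)))
  }
  full <- est_all(rep(TRUE, nrow(dat)))
  if (!is.finite(full["rg"]) || full["h2a"] <= 0 || full["h2b"] <= 0) {
    return(list(rg = structure(NA_real_, reason = "non-positive heritability"),
                se = NA_real_, gcov = unname(full["gcov"]),
                h2_a = unname(full["h2a"]), h2_b = unname(full["h2b"]),
                clipped = FALSE))
  }
  blocks <- jackknife_blocks(nrow(dat), n_blocks)
  jk <- vapply(blocks, function(bl) {
    keep <- rep(TRUE, nrow(dat)); keep[bl] <- FALSE
    est_all(keep)["rg"]
  }, numeric(1))
  jk <- jk[is.finite(jk)]
  B <- length(jk)
  se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  list(rg = unname(full["rg"]), se = se, gcov = unname(full["gcov"]),
       h2_a = unname(full["h2a"]), h2_b = unname(full["h2b"]),
       clipped = abs(full["rg"]) > 1.25)
}

#' Collapse loss-of-function variant flags to gene carrier indicators
#'
#' A sample is a carrier of a gene when it carries at least one qualifying
#' (MAF < `maf_max`) loss-of-function variant mapped to that gene.
#'
#' @param variant_flags samples x variants 0/1 (or dosage) matrix with
#'   variant ids as column names.
#' @param gene_map data frame with columns variant_id, gene and maf; every
#'   flagged variant must map to exactly one gene.
#' @param maf_max qualifying minor-allele-frequency ceiling.
#' @return a `lof_carrier_matrix`: list with `carriers` (samples x genes 0/1)
#'   and `carrier_count` per gene.
#' @export
lof_collapse <- function(variant_flags, gene_map, maf_max = 0.05) {
  vids <- colnames(variant_flags)
  unmapped <- setdiff(vids, gene_map$variant_id)
  if (length(unmapped))
    stop("variants not mapped to a gene: ", paste(unmapped, collapse = ", "))
  gm <- gene_map[match(vids, gene_map$variant_id), ]
  if (anyDuplicated(gene_map$variant_id))
    stop("each variant must map to exactly one gene")
  qual <- gm$maf < maf_max
  genes <- unique(gm$gene)
  C <- matrix(0L, nrow(variant_flags), length(genes),
              dimnames = list(rownames(variant_flags), genes))
  for (g in genes) {
    cols <- which(gm$gene == g & qual)
    if (length(cols))
      C[, g] <- as.integer(rowSums(variant_flags[, cols, drop = FALSE] > 0) > 0)
  }
  structure(list(carriers = C, carrier_count = colSums(C)),
            class = "lof_carrier_matrix")
}

#' Gene-level loss-of-function burden association
#'
#' Linear regression of each trait on the gene carrier indicator with
#' covariate adjustment. Genes with fewer than `min_carriers` carriers are
#' excluded before testing; Benjamini-Hochberg adjustment is applied across
#' the traits within each gene.
#'
#' @param carriers a `lof_carrier_matrix` (or plain 0/1 matrix).
#' @param traits data frame of quantitative traits (the three diastolic
#'   traits in the intended design).
#' @param covariates covariate data frame (sex, age and ancestry components
#'   in the intended design).
#' @param min_carriers minimum carrier count for a gene to be tested.
#' @param fdr_alpha significance level on the adjusted p-values.
#' @return data frame: gene, trait, n_carriers, beta, standard_error,
#'   p_value, p_adj, significant; excluded genes in `attr(, "excluded")`.
#' @export
lof_association <- function(carriers, traits, covariates = NULL,
                            min_carriers = 2, fdr_alpha = 0.05) {
  C_mat <- if (inherits(carriers, "lof_carrier_matrix")) carriers$carriers
           else carriers
  counts <- colSums(C_mat)
  excluded <- colnames(C_mat)[counts < min_carriers]
  keep <- counts >= min_carriers
  C_mat <- C_mat[, keep, drop = FALSE]
  Ccov <- build_covariate_matrix(covariates, nrow(C_mat))
  out <- list()
  for (tr in names(traits)) {
    res <- linear_scan(`storage.mode<-`(C_mat, "double"), traits[[tr]], Ccov)
    out[[tr]] <- data.frame(gene = colnames(C_mat), trait = tr,
                            n_carriers = counts[keep],
                            beta = res$beta,
                            standard_error = res$standard_error,
                            p_value = res$p_value,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  for (g in unique(res$gene)) {
    sel <- res$gene == g
    res$p_adj[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
  }
  res$significant <- res$p_adj < fdr_alpha
  attr(res, "excluded") <- excluded
  rownames(res) <- NULL
  res
}
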