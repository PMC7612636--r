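# Two-sample bidirectional Mendelian randomization: harmonization,
# instrument selection and filtering, IVW / weighted median / MR-Egger /
# MR-PRESSO estimators, the "potential causal" decision rule, and the
# incident-event epidemiological comparison.

new_mr_result <- function(method, estimate, se, p, n_instruments,
                          extra = list()) {
  structure(c(list(method = method, estimate = estimate, se = se, p = p,
                   n_instruments = n_instruments), extra),
            class = "mr_result")
}

#' @exportS3Method base::print
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %-16s estimate = %8.4f (SE %.4f), p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Restricts to the intersection of variant ids; outcome records whose
#' effect/other alleles are swapped relative to the exposure have their beta
#' negated and allele frequency complemented; strand-complement matches are
#' resolved through the allele complement map; palindromic (A/T or C/G)
#' variants are dropped when the allele frequency is within
#' `palindrome_eaf_window` of 0.5 in either study; irreconcilable allele
#' pairs are dropped. Every drop is logged with a reason.
#'
#' @param exposure_ss,outcome_ss `summary_stats` data frames.
#' @param palindrome_eaf_window half-width of the ambiguous-frequency zone
#'   around 0.5 for palindromic variants.
#' @return an `mr_input` data frame (one row per instrumentable variant)
#'   with columns variant_id, chrom, pos, effect_allele, other_allele, eaf,
#'   beta_exp, se_exp, p_exp, n_exp, beta_out, se_out, p_out, n_out; the drop
#'   log in `attr(, "log")`.
#' @export
harmonize <- function(exposure_ss, outcome_ss, palindrome_eaf_window = 0.08) {
  e <- as.data.frame(exposure_ss)
  o <- as.data.frame(outcome_ss)
  common <- intersect(e$variant_id, o$variant_id)
  log <- list()
  add_log <- function(ids, reason) {
    if (length(ids)) log[[length(log) + 1L]] <<-
        data.frame(variant_id = ids, reason = reason, stringsAsFactors = FALSE)
  }
  add_log(setdiff(e$variant_id, common), "absent from outcome study")
  e <- e[match(common, e$variant_id), ]
  o <- o[match(common, o$variant_id), ]
  comp <- DNA_COMPLEMENT
  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swap <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  strand <- comp[e$effect_allele] == o$effect_allele &
    comp[e$other_allele] == o$other_allele
  strand_swap <- comp[e$effect_allele] == o$other_allele &
    comp[e$other_allele] == o$effect_allele
  pal <- is_palindromic(e$effect_allele, e$other_allele)
  # palindromic variants: same/swap and strand/strand_swap are indistinguishable
  ambiguous <- pal & (pmin(e$effect_allele_frequency,
                           1 - e$effect_allele_frequency) >
                        0.5 - palindrome_eaf_window |
                      pmin(o$effect_allele_frequency,
                           1 - o$effect_allele_frequency) >
                        0.5 - palindrome_eaf_window)
  irreconcilable <- !(same | swap | strand | strand_swap)
  flip <- (swap | strand_swap) & !pal
  keep <- !ambiguous & !irreconcilable
  # palindromic but unambiguous: align by frequency
  pal_keep <- pal & keep
  freq_flip <- pal_keep &
    sign(e$effect_allele_frequency - 0.5) !=
      sign(o$effect_allele_frequency - 0.5)
  flip <- flip | freq_flip
  add_log(e$variant_id[ambiguous], "ambiguous palindromic variant")
  add_log(e$variant_id[irreconcilable & !ambiguous], "irreconcilable alleles")
  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$effect_allele_frequency,
                    o$effect_allele_frequency)
  out <- data.frame(
    variant_id = e$variant_id,
    chrom = e$chromosome,
    pos = e$base_pair_location,
    effect_allele = e$effect_allele,
    other_allele = e$other_allele,
    eaf = e$effect_allele_frequency,
    eaf_out = eaf_out,
    beta_exp = e$beta, se_exp = e$standard_error, p_exp = e$p_value,
    n_exp = e$n,
    beta_out = beta_out, se_out = o$standard_error, p_out = o$p_value,
    n_out = o$n,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(0), reason = character(0))
  class(out) <- c("mr_input", "data.frame")
  out
}

#' Select and harmonize MR instruments
#'
#' Restricts the exposure statistics to the variants shared with the outcome
#' study, clumps them (p < `p_thresh`, r2 < `r2_thresh` within `window_kb`),
#' and harmonizes the index variants against the outcome study.
#'
#' @inheritParams harmonize
#' @param ld_reference `genotype_matrix` for clumping LD.
#' @param p_thresh,r2_thresh,window_kb clumping parameters.
#' @return an `mr_input` of index instruments.
#' @export
select_instruments <- function(exposure_ss, outcome_ss, ld_reference,
                               p_thresh = 1e-6, r2_thresh = 0.1,
                               window_kb = 1000,
                               palindrome_eaf_window = 0.08) {
  shared <- intersect(exposure_ss$variant_id, outcome_ss$variant_id)
  ss <- exposure_ss[exposure_ss$variant_id %in% shared, , drop = FALSE]
  cl <- clump(ss, ld_reference, p_thresh = p_thresh, r2_thresh = r2_thresh,
              window_kb = window_kb)
  idx <- attr(cl, "index_variants")
  if (!length(idx)) stop("no valid instruments: no variant passes p < ",
                         format(p_thresh))
  mr <- harmonize(ss[ss$variant_id %in% idx, , drop = FALSE], outcome_ss,
                  palindrome_eaf_window = palindrome_eaf_window)
  if (!nrow(mr)) stop("no valid instruments after harmonization")
  mr
}

#' Remove instruments associated with measured confounders
#'
#' Drops instruments whose association p-value with any confounder study is
#' below `p_thresh`. Instruments without coverage in a confounder study are
#' retained with a warning.
#'
#' @param mr an `mr_input`.
#' @param confounder_ss list of `summary_stats` for the confounder traits.
#' @param p_thresh confounder-association threshold.
#' @return filtered `mr_input`; drops appended to `attr(, "log")`.
#' @export
confounder_filter <- function(mr, confounder_ss, p_thresh = 1e-5) {
  if (!length(confounder_ss)) return(mr)
  drop <- rep(FALSE, nrow(mr))
  uncovered <- rep(FALSE, nrow(mr))
  for (cs in confounder_ss) {
    i <- match(mr$variant_id, cs$variant_id)
    uncovered <- uncovered | is.na(i)
    p <- cs$p_value[i]
    drop <- drop | (!is.na(p) & p < p_thresh)
  }
  if (any(uncovered & !drop))
    warning(sum(uncovered & !drop),
            " instrument(s) lack confounder coverage; retained")
  out <- mr[!drop, , drop = FALSE]
  log <- attr(mr, "log")
  if (any(drop))
    log <- rbind(log, data.frame(variant_id = mr$variant_id[drop],
                                 reason = "confounder-associated"))
  attr(out, "log") <- log
  class(out) <- class(mr)
  out
}

# Variance in a trait explained by one variant, from summary statistics:
# 2 p (1-p) beta^2 on the SD-1 trait scale; for log-odds effects the
# logistic-liability approximation divides by an extra pi^2/3 latent variance.
steiger_r2 <- function(beta, eaf, binary = FALSE) {
  v <- 2 * eaf * (1 - eaf) * beta^2
  if (binary) v / (v + pi^2 / 3) else v
}

#' Steiger directionality filter
#'
#' Removes instruments that explain significantly more variance in the
#' outcome than in the exposure (likely reverse causation): per instrument,
#' r2 with each trait is approximated as 2 eaf (1 - eaf) beta^2 (SD scale;
#' log-odds effects use the logistic-liability approximation), and an
#' instrument is dropped when r2_out > r2_exp and the Steiger z-test on the
#' Fisher-transformed correlations is significant at `alpha`.
#'
#' @param mr an `mr_input` with n_exp and n_out.
#' @param alpha significance level of the directionality test.
#' @param exposure_binary,outcome_binary whether effects are log-odds.
#' @return filtered `mr_input` with drops logged.
#' @export
steiger_filter <- function(mr, alpha = 0.05, exposure_binary = FALSE,
                           outcome_binary = FALSE) {
  if (any(is.na(mr$n_exp)) || any(is.na(mr$n_out)))
    stop("Steiger filtering requires per-study sample sizes")
  r2_exp <- steiger_r2(mr$beta_exp, mr$eaf, exposure_binary)
  r2_out <- steiger_r2(mr$beta_out, mr$eaf_out, outcome_binary)
  r_exp <- sqrt(pmin(r2_exp, 0.999))
  r_out <- sqrt(pmin(r2_out, 0.999))
  z <- (atanh(r_exp) - atanh(r_out)) /
    sqrt(1 / (mr$n_exp - 3) + 1 / (mr$n_out - 3))
  p <- 2 * stats::pnorm(-abs(z))
  drop <- r2_out > r2_exp & p < alpha
  out <- mr[!drop, , drop = FALSE]
  log <- attr(mr, "log")
  if (any(drop))
    log <- rbind(log, data.frame(variant_id = mr$variant_id[drop],
                                 reason = "steiger-reverse-direction"))
  attr(out, "log") <- log
  attr(out, "steiger") <- data.frame(variant_id = mr$variant_id,
                                     r2_exp = r2_exp, r2_out = r2_out,
                                     z = z, p = p)
  class(out) <- class(mr)
  out
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights 1/se_out^2; equivalently the weighted average of
#' per-instrument Wald ratios. The standard error is inflated
#' multiplicatively by sqrt(Q / (k - 1)) when Cochran's Q indicates
#' overdispersion. A single instrument reduces to the Wald ratio.
#'
#' @param mr an `mr_input` with at least 1 instrument.
#' @return an `mr_result` with heterogeneity Q and its p-value.
#' @export
mr_ivw <- function(mr) {
  k <- nrow(mr)
  if (k < 1) stop("IVW requires at least one instrument")
  w <- 1 / mr$se_out^2
  est <- sum(w * mr$beta_exp * mr$beta_out) / sum(w * mr$beta_exp^2)
  se <- sqrt(1 / sum(w * mr$beta_exp^2))
  Q <- sum(w * (mr$beta_out - est * mr$beta_exp)^2)
  q_p <- if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_
  if (k > 1 && Q / (k - 1) > 1) se <- se * sqrt(Q / (k - 1))
  new_mr_result("ivw", est, se, 2 * stats::pnorm(-abs(est / se)), k,
                list(Q = Q, Q_p = q_p))
}

weighted_median_est <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, rule = 2)$y
}

#' Weighted median MR estimate
#'
#' Weighted median of per-instrument Wald ratios with inverse-variance
#' weights from the delta-method ratio variance; consistent when at least
#' half the weight comes from valid instruments. The standard error is a
#' parametric bootstrap over the summary statistics.
#'
#' @param mr an `mr_input` with at least 3 instruments.
#' @param boot_reps bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(mr, boot_reps = 1000, seed = 1) {
  k <- nrow(mr)
  if (k < 3) stop("weighted median requires at least 3 instruments")
  ratios <- mr$beta_out / mr$beta_exp
  var_r <- mr$se_out^2 / mr$beta_exp^2 +
    mr$beta_out^2 * mr$se_exp^2 / mr$beta_exp^4
  w <- 1 / var_r
  est <- weighted_median_est(ratios, w)
  boots <- withr::with_seed(child_seed(seed, 8L), {
    vapply(seq_len(boot_reps), function(b) {
      bx <- stats::rnorm(k, mr$beta_exp, mr$se_exp)
      by <- stats::rnorm(k, mr$beta_out, mr$se_out)
      rr <- by / bx
      vv <- mr$se_out^2 / bx^2 + by^2 * mr$se_exp^2 / bx^4
      weighted_median_est(rr, 1 / vv)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  p <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else as.numeric(est == 0)
  new_mr_result("weighted_median", est, se, max(p, .Machine$double.xmin), k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_out^2) after orienting all exposure betas
#' non-negative; the slope estimates the causal effect and the intercept
#' tests directional pleiotropy. Standard errors carry a multiplicative
#' random-effects inflation (floored at 1) and inference uses the
#' t-distribution with k - 2 degrees of freedom.
#'
#' @param mr an `mr_input` with at least 3 instruments and spread in
#'   |beta_exp|.
#' @return an `mr_result` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(mr) {
  k <- nrow(mr)
  if (k < 3) stop("MR-Egger requires at least 3 instruments")
  s <- sign(mr$beta_exp)
  s[s == 0] <- 1
  bx <- abs(mr$beta_exp)
  by <- mr$beta_out * s
  if (stats::sd(bx) == 0)
    stop("all exposure effects identical: Egger slope unidentifiable")
  w <- 1 / mr$se_out^2
  W <- sum(w); mx <- sum(w * bx) / W; my <- sum(w * by) / W
  sxx <- sum(w * (bx - mx)^2)
  slope <- sum(w * (bx - mx) * (by - my)) / sxx
  intercept <- my - slope * mx
  resid <- by - intercept - slope * bx
  sigma2 <- max(1, sum(w * resid^2) / (k - 2))
  slope_se <- sqrt(sigma2 / sxx)
  int_se <- sqrt(sigma2 * (1 / W + mx^2 / sxx))
  slope_p <- 2 * stats::pt(-abs(slope / slope_se), k - 2)
  int_p <- 2 * stats::pt(-abs(intercept / int_se), k - 2)
  new_mr_result("egger", slope, slope_se, slope_p, k,
                list(intercept = intercept, intercept_se = int_se,
                     intercept_p = int_p))
}

#' MR-PRESSO style global pleiotropy and outlier test
#'
#' The observed residual sum of squares from leave-one-out IVW fits is
#' compared with `n_sim` parametric simulations under no pleiotropy to give
#' a global test; per-instrument outlier p-values come from the same
#' simulations and instruments exceeding the Bonferroni-adjusted
#' `outlier_alpha` are removed. The reported estimate is the outlier-
#' corrected IVW; a distortion p-value compares the raw-vs-corrected shift
#' with the shift from removing random instrument subsets of the same size.
#'
#' @param mr an `mr_input` with at least 4 instruments.
#' @param n_sim simulation count (>= 100).
#' @param outlier_alpha outlier significance level (Bonferroni-adjusted
#'   across instruments).
#' @param seed integer seed.
#' @return an `mr_result` with `global_p`, `outliers` (variant ids),
#'   `distortion_p` and `raw` (the uncorrected IVW `mr_result`).
#' @export
mr_presso <- function(mr, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  k <- nrow(mr)
  if (k < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (1 / (n_sim + 1) > outlier_alpha / k)
    warning("n_sim too small to resolve outlier p-values at the ",
            "Bonferroni-adjusted level ", format(outlier_alpha / k),
            "; no outlier can be flagged")
  w <- 1 / mr$se_out^2
  loo_est <- vapply(seq_len(k), function(j) {
    sum(w[-j] * mr$beta_exp[-j] * mr$beta_out[-j]) /
      sum(w[-j] * mr$beta_exp[-j]^2)
  }, numeric(1))
  obs_res2 <- (mr$beta_out - loo_est * mr$beta_exp)^2
  rss_obs <- sum(w * obs_res2)
  sims <- withr::with_seed(child_seed(seed, 9L), {
    bx <- matrix(stats::rnorm(k * n_sim, mr$beta_exp, mr$se_exp), k)
    by <- matrix(stats::rnorm(k * n_sim, loo_est * mr$beta_exp, mr$se_out), k)
    res2 <- (by - loo_est * bx)^2
    list(rss = colSums(w * res2), res2 = res2)
  })
  global_p <- (sum(sims$rss >= rss_obs) + 1) / (n_sim + 1)
  out_p <- (rowSums(sims$res2 >= obs_res2) + 1) / (n_sim + 1)
  outliers <- which(out_p < outlier_alpha / k)
  raw <- mr_ivw(mr)
  if (length(outliers) && length(outliers) < k - 1) {
    corrected <- mr_ivw(mr[-outliers, , drop = FALSE])
    d_obs <- raw$estimate - corrected$estimate
    d_sim <- withr::with_seed(child_seed(seed, 10L), {
      vapply(seq_len(min(n_sim, 500)), function(b) {
        drop_b <- sample.int(k, length(outliers))
        raw$estimate - mr_ivw(mr[-drop_b, , drop = FALSE])$estimate
      }, numeric(1))
    })
    distortion_p <- (sum(abs(d_sim) >= abs(d_obs)) + 1) /
      (length(d_sim) + 1)
  } else {
    corrected <- raw
    distortion_p <- NA_real_
  }
  new_mr_result("presso", corrected$estimate, corrected$se, corrected$p,
                corrected$n_instruments,
                list(global_p = global_p, outlier_p = out_p,
                     outliers = mr$variant_id[outliers],
                     distortion_p = distortion_p, raw = raw))
}

#' Classify a causal relationship from MR results
#'
#' The association is "potential_causal" when the main (IVW) analysis has
#' p < `main_alpha`, at least `min_support` sensitivity analyses are at
#' least suggestive (p < `sens_alpha`) with the same effect direction as the
#' main analysis, and no sensitivity analysis is suggestive with the
#' opposite direction; "inconsistent" when the main analysis passes but a
#' suggestive opposite-direction sensitivity result exists; otherwise
#' "not_causal".
#'
#' @param main the IVW `mr_result`.
#' @param sensitivity list of sensitivity `mr_result`s (>= 2 expected).
#' @param main_alpha,sens_alpha,min_support rule thresholds.
#' @return a `causal_verdict`: list with classification, direction,
#'   main and per-method sensitivity summaries.
#' @export
classify_causal <- function(main, sensitivity, main_alpha = 0.01,
                            sens_alpha = 0.05, min_support = 2) {
  if (missing(main) || is.null(main)) stop("main (IVW) result is required")
  dir <- sign(main$estimate)
  sens_p <- vapply(sensitivity, `[[`, numeric(1), "p")
  sens_sign <- sign(vapply(sensitivity, `[[`, numeric(1), "estimate"))
  suggestive <- sens_p < sens_alpha
  support <- sum(suggestive & sens_sign == dir, na.rm = TRUE)
  conflict <- any(suggestive & sens_sign != dir, na.rm = TRUE)
  classification <- if (main$p >= main_alpha) "not_causal"
    else if (conflict) "inconsistent"
    else if (support >= min_support) "potential_causal"
    else "not_causal"
  structure(list(classification = classification,
                 direction = dir,
                 main = main,
                 sensitivity = sensitivity,
                 rule = list(main_alpha = main_alpha, sens_alpha = sens_alpha,
                             min_support = min_support)),
            class = "causal_verdict")
}

#' @exportS3Method base::print
print.causal_verdict <- function(x, ...) {
  cat(sprintf("<causal_verdict> %s (direction %+d, IVW p = %.3g, %d sensitivity)\n",
              x$classification, x$direction, x$main$p,
              length(x$sensitivity)))
  invisible(x)
}

run_mr_direction <- function(exposure_ss, outcome_ss, ld_reference,
                             confounders = list(), config = list()) {
  cfg <- utils::modifyList(list(p_thresh = 1e-6, r2_thresh = 0.1,
                                window_kb = 1000, confounder_p = 1e-5,
                                steiger = TRUE, boot_reps = 1000,
                                presso_sims = 1000, seed = 1,
                                exposure_binary = FALSE,
                                outcome_binary = FALSE), config)
  mr <- select_instruments(exposure_ss, outcome_ss, ld_reference,
                           p_thresh = cfg$p_thresh,
                           r2_thresh = cfg$r2_thresh,
                           window_kb = cfg$window_kb)
  mr <- confounder_filter(mr, confounders, p_thresh = cfg$confounder_p)
  if (isTRUE(cfg$steiger))
    mr <- steiger_filter(mr, exposure_binary = cfg$exposure_binary,
                         outcome_binary = cfg$outcome_binary)
  if (!nrow(mr)) stop("no valid instruments after filtering")
  main <- mr_ivw(mr)
  sens <- list()
  if (nrow(mr) >= 3) {
    sens$weighted_median <- mr_weighted_median(mr, boot_reps = cfg$boot_reps,
                                               seed = cfg$seed)
    sens$egger <- tryCatch(mr_egger(mr), error = function(e) NULL)
  }
  if (nrow(mr) >= 4)
    sens$presso <- mr_presso(mr, n_sim = cfg$presso_sims, seed = cfg$seed)
  sens <- Filter(Negate(is.null), sens)
  verdict <- classify_causal(main, sens)
  verdict$instruments <- mr
  verdict
}

#' Bidirectional two-sample Mendelian randomization
#'
#' Runs the full instrument-selection, filtering, estimation and
#' classification pipeline in both directions between two traits whose
#' summary statistics come from disjoint cohorts, and emits a joint label.
#' A direction whose instrument selection fails (e.g. no variant passes the
#' p-value threshold) yields a "not_causal" verdict carrying the reason.
#'
#' @param a_exposure_ss,a_outcome_ss summary statistics for trait A in its
#'   exposure-role cohort and its outcome-role cohort.
#' @param b_exposure_ss,b_outcome_ss the same for trait B.
#' @param ld_reference `genotype_matrix` for clumping.
#' @param confounders list of confounder `summary_stats`.
#' @param config list overriding pipeline defaults (thresholds, seeds,
#'   binary-trait flags `a_binary` / `b_binary`).
#' @return list with `a_to_b` and `b_to_a` `causal_verdict`s and `label` in
#'   \{"a_to_b_only", "b_to_a_only", "bidirectional", "none"\}.
#' @export
bidirectional_mr <- function(a_exposure_ss, a_outcome_ss,
                             b_exposure_ss, b_outcome_ss,
                             ld_reference, confounders = list(),
                             config = list()) {
  a_binary <- isTRUE(config$a_binary)
  b_binary <- isTRUE(config$b_binary)
  safe <- function(expr) tryCatch(expr, error = function(e) {
    v <- structure(list(classification = "not_causal", direction = 0,
                        main = NULL, sensitivity = list(),
                        reason = conditionMessage(e)),
                   class = "causal_verdict")
    v
  })
  ab <- safe(run_mr_direction(a_exposure_ss, b_outcome_ss, ld_reference,
                              confounders,
                              utils::modifyList(config,
                                list(exposure_binary = a_binary,
                                     outcome_binary = b_binary))))
  ba <- safe(run_mr_direction(b_exposure_ss, a_outcome_ss, ld_reference,
                              confounders,
                              utils::modifyList(config,
                                list(exposure_binary = b_binary,
                                     outcome_binary = a_binary))))
  causal <- c(ab$classification, ba$classification) == "potential_causal"
  label <- if (all(causal)) "bidirectional"
    else if (causal[1]) "a_to_b_only"
    else if (causal[2]) "b_to_a_only"
    else "none"
  list(a_to_b = ab, b_to_a = ba, label = label)
}

#' Incident-event logistic comparison model
#'
#' Restricts to subjects free of the disease at baseline and fits a logistic
#' regression of the incident-event indicator on the (SD-scaled) trait plus
#' covariates, reporting the odds ratio per trait SD with a Wald confidence
#' interval. This is the observational counterpart of a potential-causal MR
#' finding for a disease endpoint.
#'
#' @param tt trait table containing `<disease>_baseline` and
#'   `<disease>_incident` columns.
#' @param trait trait column name.
#' @param disease endpoint name.
#' @param covariates covariate column names.
#' @param min_events minimum incident events required.
#' @return list with or, ci (length 2), p, n, n_excluded_baseline, n_events.
#' @export
incident_event_model <- function(tt, trait, disease,
                                 covariates = c("age", "sex", "diabetes",
                                                "dbp", "bmi"),
                                 min_events = 10) {
  base_col <- paste0(disease, "_baseline")
  inc_col <- paste0(disease, "_incident")
  if (!all(c(base_col, inc_col) %in% names(tt)))
    stop("trait table lacks baseline/incident columns for ", disease)
  keep <- tt[[base_col]] == 0
  n_excl <- sum(!keep)
  d <- tt[keep, , drop = FALSE]
  y <- d[[inc_col]]
  if (sum(y) < min_events)
    stop("fewer than ", min_events, " incident events")
  x <- std1(d[[trait]])
  C <- build_covariate_matrix(d[, covariates, drop = FALSE], nrow(d))
  fit <- logistic_scan(matrix(x), y, C, refine_p = 1)
  if (!is.finite(fit$beta))
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = nrow(d), n_excluded_baseline = n_excl,
                n_events = sum(y), flag = "separation or non-convergence"))
  list(or = exp(fit$beta),
       ci = exp(fit$beta + c(-1, 1) * 1.96 * fit$standard_error),
       p = fit$p_value, n = nrow(d), n_excluded_baseline = n_excl,
       n_events = sum(y))
}
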