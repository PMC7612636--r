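test_that("harmonization flips swapped alleles, drops palindromes, is involutive", {
  e <- make_ss(c("a", "b", "c", "d"),
               ea = c("G", "A", "C", "A"), oa = c("A", "T", "T", "C"),
               eaf = c(0.3, 0.49, 0.2, 0.3), beta = c(0.2, 0.1, 0.3, 0.15))
  o <- make_ss(c("a", "b", "c", "d"),
               ea = c("A", "A", "C", "A"), oa = c("G", "T", "T", "C"),
               eaf = c(0.7, 0.49, 0.2, 0.3), beta = c(0.2, 0.1, 0.3, 0.15))
  h <- harmonize(e, o)
  # swapped alleles: outcome beta negated, frequency complemented
  expect_equal(h$beta_out[h$variant_id == "a"], -0.2)
  expect_equal(h$eaf_out[h$variant_id == "a"], 0.3)
  # ambiguous palindrome dropped with reason
  expect_false("b" %in% h$variant_id)
  expect_true("ambiguous palindromic variant" %in% attr(h, "log")$reason)
  # aligned records pass through unchanged
  expect_equal(h$beta_out[h$variant_id == "d"], 0.15)
  # intersection rule: variants absent from the outcome study are dropped
  h2 <- harmonize(e[1:3, ], o[1:2, ])
  expect_false("c" %in% h2$variant_id)
  # involution: re-harmonizing the harmonized pair changes nothing
  e_h <- make_ss(h$variant_id, h$effect_allele, h$other_allele, h$eaf,
                 h$beta_exp, se = h$se_exp, p = h$p_exp, n = h$n_exp)
  o_h <- make_ss(h$variant_id, h$effect_allele, h$other_allele, h$eaf_out,
                 h$beta_out, se = h$se_out, p = h$p_out, n = h$n_out)
  h_again <- harmonize(e_h, o_h)
  expect_equal(h_again$beta_out, h$beta_out)
  expect_equal(h_again$beta_exp, h$beta_exp)
  # strand-complement records resolve through the complement map
  o_strand <- make_ss("a", ea = "C", oa = "T", eaf = 0.7, beta = 0.2)
  h_s <- harmonize(e[1, , drop = FALSE], o_strand)
  expect_equal(h_s$beta_out, 0.2)      # C/T is the complement of G/A: aligned
})

test_that("instrument selection intersects, clumps and refuses empty sets", {
  gm <- simulate_ld_genotypes(2000, n_blocks = 30, block_size = 5,
                              within_block_r = 0.85, seed = 7)
  set.seed(8)
  cidx <- c(3, 38, 73)
  X <- scale(diastolr:::impute_dosages(gm$dosages[, cidx]))
  y <- drop(X %*% c(0.3, 0.25, 0.2)) + rnorm(2000, 0, 0.8)
  ss_exp <- run_association(gm, y)
  ss_out <- run_association(gm, rnorm(2000))
  mr <- select_instruments(ss_exp, ss_out, gm)
  oracle <- brute_force_clump(ss_exp, gm, 1e-6, 0.1, 1000)
  expect_setequal(mr$variant_id, oracle$indices)
  # signals only in variants absent from the outcome study are excluded
  drop_ids <- gm$variants$id[cidx]
  ss_out_missing <- ss_out[!ss_out$variant_id %in% drop_ids, ]
  mr2 <- tryCatch(select_instruments(ss_exp, ss_out_missing, gm),
                  error = function(e) e)
  if (!inherits(mr2, "error")) expect_false(any(drop_ids %in% mr2$variant_id))
  expect_error(select_instruments(ss_out, ss_exp, gm), "no valid instruments")
})

test_that("confounder filtering drops flagged instruments and warns on gaps", {
  mr <- simulate_mr_input(5, 0.3, seed = 3)
  conf1 <- make_ss(mr$variant_id[1:3], "A", "G", 0.3, 0.1,
                   p = c(1e-8, 0.5, 0.5))
  conf2 <- make_ss(mr$variant_id[1:3], "A", "G", 0.3, 0.1,
                   p = c(0.9, 1e-6, 0.9))
  expect_warning(out <- confounder_filter(mr, list(conf1, conf2)),
                 "coverage")
  expect_setequal(out$variant_id, mr$variant_id[3:5])
  expect_true(all(c("v01", "v02") %in% attr(out, "log")$variant_id))
})

test_that("Steiger filtering removes reverse-direction instruments", {
  base <- simulate_mr_input(4, 0.3, seed = 5)
  # correct direction: large exposure r2, tiny outcome r2
  base$beta_exp <- c(0.10, 0.10, 0.10, 0.012)
  base$beta_out <- c(0.01, 0.01, 0.30, 0.011)
  base$eaf <- base$eaf_out <- rep(0.3, 4)
  base$n_exp <- base$n_out <- 50000L
  out <- steiger_filter(base)
  expect_true(all(c("v01", "v02") %in% out$variant_id))  # retained
  expect_false("v03" %in% out$variant_id)                # reverse, removed
  expect_true("v04" %in% out$variant_id)   # marginally reversed, ns, retained
  st <- attr(out, "steiger")
  expect_true(all(st$r2_exp[1:2] > st$r2_out[1:2]))
  base_na <- base; base_na$n_exp <- NA_integer_
  expect_error(steiger_filter(base_na), "sample sizes")
})

test_that("Steiger removal and retention rates behave under simulation", {
  # forward instruments (act on exposure) retained; reverse instruments
  # (act on outcome first) removed, at biobank-scale precision
  n_eff <- 50000
  removed <- retained <- logical(200)
  set.seed(55)
  for (r in 1:200) {
    eaf <- runif(1, 0.2, 0.5)
    se <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)
    fwd <- 0.08
    mr <- structure(data.frame(
      variant_id = c("fwd", "rev"), chrom = "1", pos = c(1e5, 2e5),
      effect_allele = "A", other_allele = "G",
      eaf = eaf, eaf_out = eaf,
      beta_exp = c(rnorm(1, fwd, se), rnorm(1, 0.3 * fwd, se)),
      se_exp = se, p_exp = 1e-8, n_exp = n_eff,
      beta_out = c(rnorm(1, 0.3 * fwd, se), rnorm(1, fwd, se)),
      se_out = se, p_out = 1e-4, n_out = n_eff,
      stringsAsFactors = FALSE), class = c("mr_input", "data.frame"))
    out <- steiger_filter(mr)
    removed[r] <- !("rev" %in% out$variant_id)
    retained[r] <- "fwd" %in% out$variant_id
  }
  expect_gt(mean(removed), 0.9)
  expect_gt(mean(retained), 0.95)
})

test_that("IVW reduces to the Wald ratio and the weighted ratio identity", {
  one <- simulate_mr_input(1, 0, seed = 1)
  one$beta_exp <- 0.1; one$se_exp <- 0.01
  one$beta_out <- 0.05; one$se_out <- 0.02
  iv <- mr_ivw(one)
  expect_equal(iv$estimate, 0.5)
  expect_equal(iv$se, 0.2)
  # two identical instruments: same estimate, SE / sqrt(2)
  two <- rbind(one, one)
  class(two) <- class(one)
  iv2 <- mr_ivw(two)
  expect_equal(iv2$estimate, 0.5)
  expect_equal(iv2$se, 0.2 / sqrt(2))
  # algebraic identity: weighted average of Wald ratios
  mr <- simulate_mr_input(15, 0.3, seed = 9)
  iv15 <- mr_ivw(mr)
  wj <- mr$beta_exp^2 / mr$se_out^2
  rj <- mr$beta_out / mr$beta_exp
  expect_equal(iv15$estimate, sum(wj * rj) / sum(wj), tolerance = 1e-12)
  expect_error(mr_ivw(mr[0, ]), "at least one")
})

test_that("weighted median is robust and matches symmetric cases", {
  eq <- simulate_mr_input(3, 0, seed = 2)
  eq$beta_exp <- c(1, 1, 1); eq$se_exp <- 1e-6
  eq$beta_out <- c(0.4, 0.5, 0.6); eq$se_out <- 0.1
  wm <- mr_weighted_median(eq, boot_reps = 200, seed = 4)
  expect_equal(wm$estimate, 0.5, tolerance = 1e-9)
  # deterministic given the seed
  wm2 <- mr_weighted_median(eq, boot_reps = 200, seed = 4)
  expect_equal(wm$se, wm2$se)
  # all ratios equal: estimate is that constant
  cst <- eq; cst$beta_out <- 0.7 * cst$beta_exp
  expect_equal(mr_weighted_median(cst, boot_reps = 100, seed = 1)$estimate, 0.7)
  expect_error(mr_weighted_median(eq[1:2, ]), "at least 3")
  # contamination: 10 valid instruments, 4 invalid with ratio 2.0
  ests <- sapply(1:60, function(r) {
    mr <- simulate_mr_input(14, 0.3, seed = 600 + r,
                            invalid_ratio = 2, n_invalid = 4)
    mr_weighted_median(mr, boot_reps = 200, seed = r)$estimate
  })
  expect_lt(abs(mean(ests) - 0.3), 0.05)
})

test_that("Egger recovers lines, intercepts and degenerates correctly", {
  mr <- simulate_mr_input(10, 0.4, seed = 11, se_exp = 1e-9, se_out = 1e-9)
  eg <- mr_egger(mr)
  expect_equal(eg$estimate, 0.4, tolerance = 1e-6)
  expect_equal(eg$intercept, 0, tolerance = 1e-6)
  # planted directional pleiotropy appears in the intercept (pleiotropy is
  # defined in the oriented frame where all exposure effects are positive)
  mrp <- simulate_mr_input(20, 0.3, seed = 12, se_exp = 1e-6, se_out = 0.005)
  mrp$beta_exp <- abs(mrp$beta_exp)
  mrp$beta_out <- 0.3 * mrp$beta_exp + 0.05
  same <- mr_egger(mrp)
  expect_equal(same$intercept, 0.05, tolerance = 1e-6)
  expect_equal(same$estimate, 0.3, tolerance = 1e-6)
  expect_lt(same$intercept_p, 1e-6)
  degenerate <- mr; degenerate$beta_exp <- 0.2
  expect_error(mr_egger(degenerate), "unidentifiable")
  # constrained-to-zero intercept reproduces IVW exactly: weighted
  # through-origin regression identity
  w <- 1 / mr$se_out^2
  slope0 <- sum(w * mr$beta_exp * mr$beta_out) / sum(w * mr$beta_exp^2)
  expect_equal(mr_ivw(mr)$estimate, slope0, tolerance = 1e-12)
})

test_that("MR-PRESSO flags planted outliers and matches manual correction", {
  clean <- simulate_mr_input(20, 0.3, seed = 21)
  pc <- mr_presso(clean, n_sim = 500, seed = 3)
  expect_gt(pc$global_p, 0.05)
  expect_length(pc$outliers, 0)
  planted <- simulate_mr_input(20, 0.3, seed = 22, outlier_shift = 0.3)
  pp <- mr_presso(planted, n_sim = 500, seed = 3)
  expect_true("v01" %in% pp$outliers)
  # removing the flagged outliers manually equals the corrected estimate
  manual <- mr_ivw(planted[!planted$variant_id %in% pp$outliers, ])
  expect_equal(pp$estimate, manual$estimate, tolerance = 1e-12)
  expect_error(mr_presso(clean[1:3, ]), "at least 4")
  expect_error(mr_presso(clean, n_sim = 10), "at least 100")
  # determinism
  pp2 <- mr_presso(planted, n_sim = 500, seed = 3)
  expect_equal(pp$global_p, pp2$global_p)
})

test_that("the causal decision rule matches its printed thresholds", {
  # main p = 0.005 (+), sensitivity 0.03 (+), 0.04 (+), 0.2 (-)
  v1 <- classify_causal(mk_result(1, 0.005),
                        list(mk_result(1, 0.03), mk_result(1, 0.04),
                             mk_result(-1, 0.2)))
  expect_identical(v1$classification, "potential_causal")
  # main p = 0.02: never causal regardless of sensitivity
  v2 <- classify_causal(mk_result(1, 0.02),
                        list(mk_result(1, 1e-4), mk_result(1, 1e-4)))
  expect_identical(v2$classification, "not_causal")
  # suggestive sensitivity with conflicting direction: inconsistent
  v3 <- classify_causal(mk_result(1, 0.001),
                        list(mk_result(1, 0.03), mk_result(-1, 0.04)))
  expect_identical(v3$classification, "inconsistent")
  # fewer than two supporting sensitivity analyses: not causal
  v4 <- classify_causal(mk_result(1, 0.001),
                        list(mk_result(1, 0.03), mk_result(1, 0.5)))
  expect_identical(v4$classification, "not_causal")
  # verdict is reproducible from its stored per-method results
  rebuilt <- classify_causal(v1$main, v1$sensitivity)
  expect_identical(rebuilt$classification, v1$classification)
  expect_error(classify_causal(NULL, list()), "required")
})

test_that("incident-event model excludes baseline disease and finds effects", {
  set.seed(31)
  n <- 6000
  tt <- simulate_covariates(n, seed = 44)
  tt$trait <- rnorm(n)
  lia <- -0.5 * scale(tt$trait)[, 1] + rnorm(n)
  ever <- as.integer(lia > quantile(lia, 0.8))
  baseline <- as.integer(ever == 1 & runif(n) < 0.3)
  tt$dz <- ever
  tt$dz_baseline <- baseline
  tt$dz_incident <- as.integer(ever == 1 & baseline == 0)
  fit <- incident_event_model(tt, "trait", "dz")
  expect_lt(fit$or, 1)                      # protective direction recovered
  expect_lt(fit$p, 1e-6)
  expect_equal(fit$n_excluded_baseline, sum(baseline))
  expect_true(fit$ci[1] < fit$or & fit$or < fit$ci[2])
  # null trait: odds ratio near 1
  tt$null_trait <- rnorm(n)
  fit0 <- incident_event_model(tt, "null_trait", "dz")
  expect_gt(fit0$p, 0.001)
  few <- tt[1:40, ]
  expect_error(incident_event_model(few, "trait", "dz"), "incident events")
})
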