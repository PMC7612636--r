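test_that("exact HWE test matches full enumeration of the conditional law", {
  # independent oracle: enumerate heterozygote counts directly
  enum_hwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    na <- 2 * n - nA
    if (nA == 0 || na == 0) return(1)
    hs <- seq(nA %% 2, min(nA, na), by = 2)
    pr <- sapply(hs, function(h) {
      exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
            lfactorial((na - h) / 2) + h * log(2) +
            lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[hs == nAa] * (1 + 1e-9)])
  }
  cases <- rbind(c(25, 50, 25), c(50, 0, 50), c(100, 0, 0), c(3, 7, 190),
                 c(40, 20, 40), c(0, 10, 90), c(120, 80, 50))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_test(cases[i, 1], cases[i, 2], cases[i, 3]),
                 enum_hwe(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-8)
  }
  expect_equal(hwe_test(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_equal(hwe_test(77, 0, 0), 1)
  expect_error(hwe_test(-1, 2, 3), "non-negative")
  # batch path agrees with the scalar path
  cnt <- `colnames<-`(cases, c("n_AA", "n_Aa", "n_aa"))
  expect_equal(diastolr:::hwe_test_batch(cnt),
               apply(cases, 1, function(r) hwe_test(r[1], r[2], r[3])),
               tolerance = 1e-8)
})

test_that("QC filter removes low-MAF and HWE-violating variants with reasons", {
  # constructed panel: 10 variants; 3 fail MAF, 2 fail HWE, 1 overlapping
  n <- 400
  set.seed(31)
  make_col <- function(p, hwe_break = FALSE) {
    if (hwe_break) {
      # no heterozygotes at intermediate frequency: gross HWE violation
      sample(c(0L, 2L), n, TRUE, c(1 - p, p))
    } else rbinom(n, 2, p)
  }
  cols <- cbind(
    make_col(0.3), make_col(0.001), make_col(0.002), make_col(0.25),
    make_col(0.4, hwe_break = TRUE), make_col(0.35, hwe_break = TRUE),
    make_col(0.45), make_col(0.002), make_col(0.2), make_col(0.15))
  # variant 8 fails MAF; make it also fail HWE (overlap) by removing hets
  cols[, 8] <- ifelse(cols[, 8] > 0, 2L, 0L)
  cols[1:2, 8] <- 2L
  gm <- diastolr:::new_genotype_matrix(
    `dimnames<-`(cols, list(sprintf("S%03d", 1:n), sprintf("v%02d", 1:10))),
    data.frame(id = sprintf("v%02d", 1:10), chrom = "1", pos = 1:10 * 1000,
               effect_allele = "A", other_allele = "G", eaf = 0.2,
               stringsAsFactors = FALSE))
  qc <- qc_filter(gm, maf_min = 0.005, hwe_p_min = 0.05)
  rep <- qc$report
  expect_true(all(rep$reason[rep$maf < 0.005] %in% c("MAF", "MAF;HWE")))
  expect_false(any(rep$keep[c(2, 3, 5, 6, 8)]))
  expect_true(all(rep$keep[c(1, 4, 7, 9, 10)]))
  expect_equal(ncol(qc$retained$dosages), 5)
  # perfect-HWE common variant is retained
  expect_true(rep$keep[1])
})

test_that("association scan recovers noiseless effects and controls type I error", {
  gm <- simulate_ld_genotypes(800, n_blocks = 100, block_size = 2,
                              within_block_r = 0.2, seed = 41)
  x <- gm$dosages[, 7]
  ss <- run_association(subset_genotypes(gm, variants = 1:10), 0.5 * x)
  # column 7 regressed on itself: exact slope, vanishing SE
  expect_equal(ss$beta[7], 0.5, tolerance = 1e-8)
  expect_lt(ss$standard_error[7], 1e-6)
  # null scan: empirical type-I error close to nominal
  set.seed(5)
  y <- rnorm(800)
  ss0 <- run_association(gm, y)
  expect_lt(abs(mean(ss0$p_value < 0.05) - 0.05), 0.02)
  # adding a pure-noise covariate leaves the effect within 1 SE (refit oracle)
  yx <- 0.3 * x + rnorm(800)
  s1 <- run_association(subset_genotypes(gm, variants = 7), yx)
  s2 <- run_association(subset_genotypes(gm, variants = 7), yx,
                        covariates = data.frame(z = rnorm(800)))
  expect_lt(abs(s1$beta - s2$beta), s1$standard_error)
  # matrix-algebra oracle: standardized beta equals the partial correlation
  z <- rnorm(800)
  s3 <- run_association(subset_genotypes(gm, variants = 7),
                        drop(scale(yx)), covariates = data.frame(z = z))
  xs <- drop(scale(x))
  rx <- resid(lm(xs ~ z)); ry <- resid(lm(drop(scale(yx)) ~ z))
  expect_equal(s3$beta * sd(x), cov(rx, ry) / var(rx), tolerance = 1e-8)
  expect_error(run_association(gm, rep(1, 800)), "constant")
})

test_that("logistic scan returns calibrated log-odds effects", {
  gm <- simulate_ld_genotypes(1500, n_blocks = 10, block_size = 2, seed = 43)
  set.seed(77)
  x <- gm$dosages[, 3]
  eta <- -0.8 + 0.6 * (x - mean(x))
  y <- rbinom(1500, 1, plogis(eta))
  ss <- run_association(gm, y, family = "logistic")
  fit <- glm(y ~ x, family = binomial)
  expect_equal(ss$beta[3], unname(coef(fit)[2]), tolerance = 0.02)
  expect_error(run_association(gm, y + 1, family = "logistic"), "0/1")
})

test_that("ld_r2 is a squared correlation with symmetry and flags", {
  gm <- simulate_ld_genotypes(300, n_blocks = 5, block_size = 3, seed = 51)
  gm$dosages[, 2] <- gm$dosages[, 1]
  expect_equal(ld_r2(gm, 1, 2), 1)
  expect_equal(ld_r2(gm, 4, 9), ld_r2(gm, 9, 4))
  gm$dosages[, 5] <- 0L
  expect_true(is.na(ld_r2(gm, 5, 6)))
  big <- simulate_ld_genotypes(10000, n_blocks = 2, block_size = 1, seed = 3)
  expect_lt(ld_r2(big, 1, 2), 0.01)
})

test_that("clumping matches the hand-built three-variant example", {
  # v1 (p=1e-9) tags v2 (r2 = 0.5); v3 (p=1e-7, r2 with v1 = 0.05) is its own
  # index; constructed genotypes with controlled correlations
  set.seed(61)
  n <- 4000
  x1 <- rbinom(n, 2, 0.4)
  x2 <- ifelse(runif(n) < 0.72, x1, rbinom(n, 2, 0.4))   # r2 about 0.5
  x3 <- ifelse(runif(n) < 0.25, x1, rbinom(n, 2, 0.4))   # r2 about 0.05
  D <- cbind(v1 = x1, v2 = x2, v3 = x3)
  storage.mode(D) <- "integer"
  rownames(D) <- sprintf("S%04d", 1:n)
  gm <- diastolr:::new_genotype_matrix(
    D, data.frame(id = c("v1", "v2", "v3"), chrom = "1",
                  pos = c(1e5, 2e5, 3e5), effect_allele = "A",
                  other_allele = "G", eaf = 0.4, stringsAsFactors = FALSE))
  stopifnot(abs(cor(x1, x2)^2 - 0.5) < 0.1, cor(x1, x3)^2 < 0.1)
  ss <- make_ss(c("v1", "v2", "v3"), "A", "G", 0.4, 0.1,
                p = c(1e-9, 1e-8, 1e-7), pos = c(1e5, 2e5, 3e5))
  cl <- clump(ss, gm, p_thresh = 1e-6, r2_thresh = 0.1, window_kb = 1000)
  expect_identical(attr(cl, "index_variants"), c("v1", "v3"))
  expect_setequal(cl$member[cl$index == "v1"], c("v1", "v2"))
  # no variant below threshold: empty result
  ss_hi <- make_ss("v1", "A", "G", 0.4, 0.1, p = 1e-3)
  expect_length(attr(clump(ss_hi, gm), "index_variants"), 0)
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_clump_instance(seed)
    p_th <- sample(c(1e-2, 1e-4, 1e-6), 1)
    cl <- clump(inst$ss, inst$gm, p_thresh = p_th, r2_thresh = 0.1,
                window_kb = 1000)
    oracle <- brute_force_clump(inst$ss, inst$gm, p_th, 0.1, 1000)
    expect_identical(attr(cl, "index_variants"), oracle$indices)
  }
})

test_that("LD scores match closed forms and duplicate-column bounds", {
  gm <- simulate_ld_genotypes(3000, n_blocks = 10, block_size = 5,
                              within_block_r = 0.8, seed = 71)
  gm$dosages[, 2] <- gm$dosages[, 1]
  sc <- ld_scores(gm, window_kb = 1000)
  expect_true(all(sc$ell >= 1))
  expect_gte(sc$ell[sc$variant_id == gm$variants$id[1]], 2 - 1e-6)
  # matrix input: true block-r2 structure gives ell = 1 + (bs - 1) * r2
  bs <- 5; r2 <- 0.49
  R <- diag(bs) * (1 - r2) + r2
  sc_true <- ld_scores(R, window_kb = 1000, positions = 1:bs * 1000)
  expect_equal(sc_true$ell, rep(1 + (bs - 1) * r2, bs))
  # unlinked panel: scores near 1 + (m_window - 1)/n
  gm0 <- simulate_ld_genotypes(4000, n_blocks = 20, block_size = 5,
                               within_block_r = 0, seed = 72)
  sc0 <- ld_scores(gm0, window_kb = 1000)
  expect_lt(abs(mean(sc0$ell) - (1 + 4 / 4000)), 0.01)
})

test_that("LDSC heritability has the stated algebraic properties", {
  set.seed(81)
  m <- 400
  ell <- runif(m, 1, 8)
  ss <- make_ss(sprintf("v%03d", 1:m), "A", "G", 0.3,
                beta = rnorm(m), se = 1, p = 0.5, n = 5000L,
                pos = 1:m * 1e4)
  scores <- data.frame(variant_id = ss$variant_id, ell = ell)
  # chi-squared identically 1: zero heritability, unit intercept
  ss$beta <- ss$standard_error  # chi2 = 1
  h0 <- ldsc_h2(ss, scores, n = 5000, m = m)
  expect_equal(h0$h2, 0, tolerance = 1e-10)
  expect_equal(h0$intercept, 1, tolerance = 1e-10)
  # doubling every chi-squared doubles slope and intercept
  ss2 <- ss; ss2$beta <- sqrt(2) * ss$standard_error *
    sample(c(-1, 1), m, TRUE)
  h2x <- ldsc_h2(ss2, scores, n = 5000, m = m)
  expect_equal(h2x$intercept, 2, tolerance = 1e-10)
  # invariant to permuting variant order
  perm <- sample(m)
  hp <- ldsc_h2(ss2[perm, ], scores, n = 5000, m = m)
  expect_equal(hp$h2, h2x$h2, tolerance = 1e-12)
})

test_that("LDSC genetic correlation is 1 for self and antisymmetric in sign", {
  gm <- simulate_ld_genotypes(4000, n_blocks = 60, block_size = 5,
                              within_block_r = 0.7, seed = 91)
  st <- simulate_traits(gm, 200, c(0.4, 0.4),
                        rg_structure = matrix(c(1, .9, .9, 1), 2), seed = 92)
  sc <- ld_scores(gm, window_kb = 1000)
  ssa <- run_association(gm, st$traits$trait1)
  ssb <- run_association(gm, st$traits$trait2)
  self <- ldsc_rg(ssa, ssa, sc, 4000, 4000)
  expect_equal(self$rg, 1, tolerance = 1e-8)
  rg_ab <- ldsc_rg(ssa, ssb, sc, 4000, 4000)
  ssb_neg <- ssb; ssb_neg$beta <- -ssb_neg$beta
  rg_neg <- ldsc_rg(ssa, ssb_neg, sc, 4000, 4000)
  expect_equal(rg_neg$rg, -rg_ab$rg, tolerance = 1e-10)
  # disjoint causal sets: rg near zero
  stn <- simulate_traits(gm, 50, 0.4, seed = 93)
  ssn <- run_association(gm, stn$traits$trait1)
  rg_null <- ldsc_rg(ssa, ssn, sc, 4000, 4000)
  expect_lt(abs(rg_null$rg), max(2 * rg_null$se, 0.25))
})

test_that("LoF collapsing builds carrier indicators by hand-enumerable rules", {
  flags <- matrix(c(1, 1, 0,
                    0, 1, 0,
                    0, 0, 1,
                    0, 0, 0), 4, 3, byrow = TRUE,
                  dimnames = list(sprintf("S%d", 1:4), c("va", "vb", "vc")))
  gmap <- data.frame(variant_id = c("va", "vb", "vc"),
                     gene = c("G1", "G1", "G2"),
                     maf = c(0.01, 0.02, 0.06), stringsAsFactors = FALSE)
  cm <- lof_collapse(flags, gmap, maf_max = 0.05)
  # sample 1 carries two qualifying variants in G1: indicator is 1, not 2
  expect_identical(cm$carriers[, "G1"], c(S1 = 1L, S2 = 1L, S3 = 0L, S4 = 0L))
  # vc exceeds the MAF ceiling: G2 has no qualifying carriers
  expect_identical(unname(cm$carriers[, "G2"]), rep(0L, 4))
  expect_equal(unname(cm$carrier_count), c(2, 0))
  expect_error(lof_collapse(flags, gmap[-1, ], 0.05), "not mapped")
})

test_that("LoF burden association filters, recovers effects and controls FDR", {
  set.seed(101)
  n <- 5000
  lof <- simulate_lof_carriers(n, paste0("G", 1:20), carrier_freq = 0.01,
                               effect_per_gene = c(G5 = -0.71), seed = 7)
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  traits <- data.frame(
    t1 = lof$trait_increment + rnorm(n),
    t2 = rnorm(n), t3 = rnorm(n))
  # add a single-carrier gene: must be excluded
  carr <- cbind(lof$carriers, G99 = c(1L, rep(0L, n - 1)))
  res <- lof_association(carr, traits, covs, min_carriers = 2)
  expect_true("G99" %in% attr(res, "excluded"))
  expect_false("G99" %in% res$gene)
  hit <- res[res$gene == "G5" & res$trait == "t1", ]
  expect_lt(abs(hit$beta - (-0.71)), 2 * hit$standard_error)
  expect_true(hit$significant)
  # null genes: BH-adjusted significance is rare
  null_sig <- res$significant[res$gene != "G5"]
  # 57 null gene-trait tests: nominal level plus two binomial SEs
  expect_lte(mean(null_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / length(null_sig)))
})
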