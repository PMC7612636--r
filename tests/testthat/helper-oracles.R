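# Independent oracles and small fixture builders used across the suite.

# Exhaustive greedy clumping, written directly from the rule: repeatedly take
# the smallest-p unassigned variant under the threshold, absorb every
# unassigned variant within the window at r2 >= threshold. Quadratic and
# index-by-index; independent of the package implementation.
brute_force_clump <- function(ss, gm, p_thresh, r2_thresh, window_kb) {
  # pairwise r2 computed up front for the whole (small) panel
  R2 <- suppressWarnings(
    stats::cor(gm$dosages, use = "pairwise.complete.obs")^2)
  g_of <- match(ss$variant_id, gm$variants$id)
  done <- rep(FALSE, nrow(ss))
  indices <- character(0)
  members <- list()
  repeat {
    cand <- which(!done & ss$p_value < p_thresh)
    if (!length(cand)) break
    ord <- cand[order(ss$p_value[cand], ss$chromosome[cand],
                      ss$base_pair_location[cand], ss$variant_id[cand])]
    i <- ord[1]
    done[i] <- TRUE
    indices <- c(indices, ss$variant_id[i])
    mem <- character(0)
    for (j in seq_len(nrow(ss))) {
      if (done[j]) next
      if (ss$chromosome[j] != ss$chromosome[i]) next
      if (abs(ss$base_pair_location[j] - ss$base_pair_location[i]) >
          window_kb * 1000) next
      if (is.na(g_of[i]) || is.na(g_of[j])) next
      r2 <- R2[g_of[i], g_of[j]]
      if (is.finite(r2) && r2 >= r2_thresh) {
        done[j] <- TRUE
        mem <- c(mem, ss$variant_id[j])
      }
    }
    members[[ss$variant_id[i]]] <- mem
  }
  list(indices = indices, members = members)
}

# Random summary statistics over a genotype panel for clumping tests.
random_clump_instance <- function(seed) {
  set.seed(seed)
  n_blocks <- sample(3:12, 1)
  bs <- sample(2:6, 1)
  gm <- simulate_ld_genotypes(120, n_blocks = n_blocks, block_size = bs,
                              within_block_r = runif(1, 0, 0.95),
                              n_chrom = sample(1:4, 1),
                              block_gap_bp = sample(c(5e5, 2e6), 1),
                              seed = seed)
  m <- ncol(gm$dosages)
  ss <- data.frame(
    variant_id = gm$variants$id,
    chromosome = gm$variants$chrom,
    base_pair_location = gm$variants$pos,
    effect_allele = gm$variants$effect_allele,
    other_allele = gm$variants$other_allele,
    effect_allele_frequency = gm$variants$eaf,
    beta = rnorm(m), standard_error = 1,
    p_value = 10^-runif(m, 0, 10), n = 120L,
    stringsAsFactors = FALSE)
  class(ss) <- c("summary_stats", "data.frame")
  list(gm = gm, ss = ss)
}

# Analytic strain curve: integral of a systolic and an early-diastolic
# Gaussian strain-rate wave (the same family the generator uses, evaluated
# independently here via pnorm).
analytic_strain <- function(t, pdsr, t_sys = 0.18, s_sys = 0.10,
                            t_dia = 0.60, s_dia = 0.08) {
  p_sys <- pdsr * s_dia / s_sys
  p_sys * s_sys * sqrt(2 * pi) *
    (pnorm((t - t_sys) / s_sys) - pnorm(-t_sys / s_sys)) -
    pdsr * s_dia * sqrt(2 * pi) *
    (pnorm((t - t_dia) / s_dia) - pnorm(-t_dia / s_dia))
}

# Simulated two-sample MR instrument table with known truth.
simulate_mr_input <- function(k = 20, effect = 0.3, seed = 1,
                              se_exp = 0.01, se_out = 0.02,
                              pleiotropy = 0, outlier_shift = 0,
                              invalid_ratio = NULL, n_invalid = 0) {
  set.seed(seed)
  bx <- rnorm(k, 0.12, 0.03) * sample(c(-1, 1), k, TRUE)
  by <- effect * bx + pleiotropy
  if (n_invalid > 0) by[seq_len(n_invalid)] <- invalid_ratio * bx[seq_len(n_invalid)]
  if (outlier_shift != 0) by[1] <- by[1] + outlier_shift
  out <- data.frame(
    variant_id = sprintf("v%02d", seq_len(k)),
    chrom = "1", pos = seq_len(k) * 1e6,
    effect_allele = "A", other_allele = "G",
    eaf = runif(k, 0.1, 0.5), eaf_out = runif(k, 0.1, 0.5),
    beta_exp = rnorm(k, bx, se_exp), se_exp = se_exp,
    p_exp = 1e-9, n_exp = 10000L,
    beta_out = rnorm(k, by, se_out), se_out = se_out,
    p_out = 0.5, n_out = 10000L,
    stringsAsFactors = FALSE)
  class(out) <- c("mr_input", "data.frame")
  out
}

# Minimal summary-stats constructor for harmonization tests.
make_ss <- function(id, ea, oa, eaf, beta, se = 0.05, p = 1e-3, n = 1000L,
                    chrom = "1", pos = seq_along(id)) {
  out <- data.frame(variant_id = id, chromosome = chrom,
                    base_pair_location = pos, effect_allele = ea,
                    other_allele = oa, effect_allele_frequency = eaf,
                    beta = beta, standard_error = se, p_value = p, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

mk_result <- function(est, p, method = "sens") {
  structure(list(method = method, estimate = est, se = 1, p = p,
                 n_instruments = 5L), class = "mr_result")
}
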