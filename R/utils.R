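# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Counter-based seed splitting: every stochastic stage of a pipeline draws its
# own child seed from the caller's seed and a stream index, so adding or
# reordering stages never perturbs the randomness of the others.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647                       # 2^31 - 1, keeps seeds in integer range
  s <- (abs(as.numeric(seed)) %% m)
  for (k in c(stream + 1, 12345)) {
    s <- (s * 48271 + k * 2654435) %% m
  }
  as.integer(s)
}

# Standardize a numeric vector (sample sd, denominator n - 1).
std1 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# Mean-impute missing dosages, column-wise.
impute_dosages <- function(D) {
  if (!anyNA(D)) return(D)
  cm <- colMeans(D, na.rm = TRUE)
  idx <- which(is.na(D), arr.ind = TRUE)
  D[idx] <- cm[idx[, 2L]]
  D
}

# Column means / sds without forming extra copies.
col_sds <- function(D) {
  n <- nrow(D)
  cm <- colMeans(D)
  sqrt((colSums(D * D) - n * cm^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) DNA_COMPLEMENT[a1] == a2
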