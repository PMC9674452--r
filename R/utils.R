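# Internal helpers shared across modules.

# Round half away from zero (so 3.5 -> 4), unlike base round()'s banker's
# rounding. Clone thresholds must reproduce "3.6 rounded to 4" style rules.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Validate a symmetric non-negative distance matrix with zero diagonal.
check_dist_matrix <- function(d, what = "distance matrix", nonneg = TRUE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop(what, " is not symmetric")
  if (any(abs(diag(d)) > 1e-10))
    stop(what, " has a non-zero diagonal")
  # pairwise F_ST "distances" may be slightly negative by estimation
  if (nonneg && any(d < -1e-10))
    stop(what, " has negative entries")
  invisible(d)
}

# Extract the lower-triangle (off-diagonal) values of a labeled square matrix
# as one row per unordered pair.
lower_pairs <- function(d) {
  labs <- rownames(d)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  data.frame(
    pop1 = labs[idx[, 2]],
    pop2 = labs[idx[, 1]],
    value = d[idx],
    stringsAsFactors = FALSE
  )
}

# Add-one permutation p-value: never exactly 0.
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}
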