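# Independent oracles used across tests.  These deliberately re-derive the
# quantities by brute force or closed form, without calling the package's
# own implementation paths.

# Dense-grid quadrature for the posterior mean/variance of the null-allele
# frequency: the oracle for the adaptive-integration estimator.
grid_posterior <- function(x, n, f_is, prior = c(1, 1), n_grid = 1e4) {
  h <- 1 / n_grid
  q <- seq(h / 2, 1 - h / 2, by = h)  # midpoint rule over n_grid cells
  phi <- q^2 + f_is * q * (1 - q)
  lik <- phi^x * (1 - phi)^(n - x)
  w <- lik * dbeta(q, prior[1], prior[2])
  w[!is.finite(w)] <- 0
  m0 <- sum(w)
  m1 <- sum(q * w) / m0
  m2 <- sum(q^2 * w) / m0
  list(q = m1, se2 = m2 - m1^2)
}

# Brute-force clone partition: all-pairs comparable-mismatch counts and
# union-find closure.
oracle_clone_groups <- function(scores, threshold) {
  n <- nrow(scores)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(scores[i, ]) & !is.na(scores[j, ])
      if (sum(ok) == 0) next
      mm <- sum(scores[i, ok] != scores[j, ok])
      if (mm <= threshold) parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(rownames(scores), roots))
}

# Canonical form of a partition for comparison.
canon_partition <- function(groups) {
  sorted <- lapply(groups, sort)
  sorted[order(vapply(sorted, `[`, character(1), 1))]
}

# Brute-force AMOVA sums of squares from pairwise squared distances.
oracle_amova_ss <- function(d2, pop) {
  N <- length(pop)
  ss_total <- 0
  for (i in seq_len(N - 1))
    for (j in seq(i + 1, N)) ss_total <- ss_total + d2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d2[i, j]
    ss_within <- ss_within + s / length(idx)
  }
  c(among = ss_total - ss_within, within = ss_within, total = ss_total)
}

# Balanced nested ANOVA mean squares by explicit summation (the
# expected-mean-squares oracle; balanced case only).
oracle_balanced_ems <- function(y, pop, fam, n_per_fam, fam_per_pop) {
  grand <- mean(y)
  pops <- unique(pop)
  fams <- unique(fam)
  ss_pop <- sum(vapply(pops, function(p) {
    length(y[pop == p]) * (mean(y[pop == p]) - grand)^2
  }, numeric(1)))
  ss_fam <- sum(vapply(fams, function(f) {
    p <- pop[fam == f][1]
    length(y[fam == f]) * (mean(y[fam == f]) - mean(y[pop == p]))^2
  }, numeric(1)))
  ss_err <- sum(vapply(fams, function(f) {
    sum((y[fam == f] - mean(y[fam == f]))^2)
  }, numeric(1)))
  P <- length(pops); Fam <- length(fams); N <- length(y)
  ms_pop <- ss_pop / (P - 1)
  ms_fam <- ss_fam / (Fam - P)
  ms_err <- ss_err / (N - Fam)
  # balanced EMS: MS_err = Ve; MS_fam = Ve + n Vf; MS_pop = Ve + n Vf + n f Vp
  v_error <- ms_err
  v_fam <- (ms_fam - ms_err) / n_per_fam
  v_pop <- (ms_pop - ms_fam) / (n_per_fam * fam_per_pop)
  list(v_pop = max(v_pop, 0), v_fam = max(v_fam, 0), v_error = v_error,
       ms = c(pop = ms_pop, fam = ms_fam, error = ms_err))
}

# Build an allele_freqs object directly (bypassing estimation) for testing
# the structure statistics on known frequencies.
make_freqs <- function(q, se2 = NULL, n = NULL, f_is = 0) {
  q <- as.matrix(q)
  if (is.null(rownames(q))) rownames(q) <- paste0("p", seq_len(nrow(q)))
  if (is.null(colnames(q))) colnames(q) <- paste0("L", seq_len(ncol(q)))
  if (is.null(se2)) se2 <- matrix(0, nrow(q), ncol(q), dimnames = dimnames(q))
  if (is.null(n)) n <- setNames(rep(10L, nrow(q)), rownames(q))
  structure(list(q = q, se2 = se2, n = n, f_is = f_is, prior = NULL),
            class = "allele_freqs")
}

# Balanced nested trait table generator for quantgen tests.
make_balanced_traits <- function(n_pop, n_fam, n_per_fam,
                                 v_pop, v_fam, v_error,
                                 grand_mean = 10, seed = 1) {
  set.seed(seed)
  pop <- rep(sprintf("p%02d", seq_len(n_pop)), each = n_fam * n_per_fam)
  fam <- rep(sprintf("p%02d_f%02d",
                     rep(seq_len(n_pop), each = n_fam),
                     rep(seq_len(n_fam), n_pop)), each = n_per_fam)
  y <- grand_mean +
    rep(rnorm(n_pop, 0, sqrt(v_pop)), each = n_fam * n_per_fam) +
    rep(rnorm(n_pop * n_fam, 0, sqrt(v_fam)), each = n_per_fam) +
    rnorm(length(pop), 0, sqrt(v_error))
  data.frame(plant_id = sprintf("pl%04d", seq_along(y)),
             population_id = pop, family_id = fam, y = y,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
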