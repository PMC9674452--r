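# Among-population structure for dominant markers: variance-component F_ST on
# estimated allele frequencies (AFLP-SURV style), permutation testing,
# pairwise F_ST / distinctness, and AMOVA on band phenotypes.

# Core F_ST estimator on frequency matrices.  For each locus the
# sample-size-weighted among-population variance of q is divided by
# qbar(1-qbar); loci are combined as a ratio of sums.  Because the posterior
# means are shrunken toward the fitted prior, their among-population variance
# already discounts sampling noise; subtracting the mean posterior variance
# on top of that double-corrects and is exposed only as an option.
fst_from_freqs <- function(q, se2, n,
                           bias_correction = c("none", "subtract")) {
  bias_correction <- match.arg(bias_correction)
  P <- nrow(q)
  stopifnot(P >= 2)
  w <- n / sum(n)
  num <- den <- rep(NA_real_, ncol(q))
  for (l in seq_len(ncol(q))) {
    ql <- q[, l]
    ok <- is.finite(ql)
    if (sum(ok) < 2) next
    wl <- w[ok] / sum(w[ok])
    qbar <- sum(wl * ql[ok])
    p_ok <- sum(ok)
    # weighted variance scaled so equal weights give the sample variance
    v_among <- sum(wl * (ql[ok] - qbar)^2) * p_ok / (p_ok - 1)
    num[l] <- v_among -
      if (bias_correction == "subtract") mean(se2[ok, l]) else 0
    den[l] <- qbar * (1 - qbar)
  }
  usable <- is.finite(num) & is.finite(den)
  if (!any(usable) || sum(den[usable]) <= 0) {
    warning("all loci monomorphic: F_ST undefined")
    return(list(fst = NA_real_, per_locus = num / den,
                num = num, den = den))
  }
  list(
    fst = sum(num[usable]) / sum(den[usable]),
    per_locus = ifelse(den > 0, num / den, NA_real_),
    num = num, den = den
  )
}

#' Global F_ST from estimated allele frequencies
#'
#' Per locus, the sample-size-weighted variance of allele frequency among
#' populations is divided by \code{qbar (1 - qbar)}; loci are combined as a
#' ratio of sums, so negative per-locus numerators are retained before
#' summation.  The across-locus SD of the per-locus ratios is reported as a
#' dispersion measure.  Sampling noise in the frequency estimates is already
#' discounted by the shrinkage of the Bayesian posterior means (their
#' among-population variance recovers the generating differentiation without
#' further adjustment); \code{bias_correction = "subtract"} additionally
#' subtracts the mean posterior variance per locus, the classical correction
#' appropriate for unshrunken method-of-moments frequency estimates.
#'
#' @param freqs an \code{allele_freqs} object from [estimate_allele_freqs].
#' @param bias_correction \code{"none"} (default) or \code{"subtract"}.
#' @return List with \code{fst}, \code{sd_loci} (SD of per-locus ratios over
#'   loci with positive denominator) and \code{per_locus}.
#' @export
global_fst <- function(freqs, bias_correction = "none") {
  stopifnot(inherits(freqs, "allele_freqs"))
  r <- fst_from_freqs(freqs$q, freqs$se2, freqs$n, bias_correction)
  list(fst = r$fst,
       sd_loci = stats::sd(r$per_locus[is.finite(r$per_locus)]),
       per_locus = r$per_locus)
}

#' Permutation test of the global F_ST
#'
#' Individuals are permuted among populations (sizes preserved), allele
#' frequencies are re-estimated and F_ST recomputed for each permutation.
#' The p-value uses the add-one estimator, so it is never exactly zero.
#'
#' @param m a [marker_matrix].
#' @param f_is inbreeding coefficient passed to [estimate_allele_freqs].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param two_pass passed to [estimate_allele_freqs].
#' @return List with \code{fst}, \code{p}, \code{null} (permutation F_ST
#'   values), \code{ci} (2.5--97.5\% quantiles of the null), \code{n_perm},
#'   \code{seed}.
#' @export
fst_permutation_test <- function(m, f_is = 0.643, n_perm = 1000, seed = 1,
                                 two_pass = TRUE) {
  stopifnot(inherits(m, "marker_matrix"))
  obs <- global_fst(estimate_allele_freqs(m, f_is, two_pass))$fst
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    mp <- m
    mp$population <- sample(m$population)
    global_fst(estimate_allele_freqs(mp, f_is, two_pass))$fst
  }, numeric(1))
  list(fst = obs,
       p = perm_pvalue(null, obs),
       null = null,
       ci = stats::quantile(null, c(0.025, 0.975), names = FALSE),
       n_perm = n_perm, seed = seed)
}

#' Pairwise F_ST matrix
#'
#' Applies the global estimator to every population pair, using the allele
#' frequencies and sampling variances already estimated per population.
#'
#' @param freqs an \code{allele_freqs} object.
#' @return Symmetric zero-diagonal matrix of pairwise F_ST.
#' @export
pairwise_fst <- function(freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  pops <- rownames(freqs$q)
  P <- length(pops)
  stopifnot(P >= 2)
  d <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      sel <- c(i, j)
      d[i, j] <- d[j, i] <- fst_from_freqs(
        freqs$q[sel, , drop = FALSE],
        freqs$se2[sel, , drop = FALSE],
        freqs$n[sel]
      )$fst
    }
  }
  d
}

#' Population distinctness: mean pairwise F_ST to all other populations
#'
#' @param pw a symmetric pairwise F_ST matrix from [pairwise_fst].
#' @return Named vector of off-diagonal row means.
#' @export
distinctness <- function(pw) {
  stopifnot(is.matrix(pw), nrow(pw) == ncol(pw), nrow(pw) >= 2)
  vapply(seq_len(nrow(pw)), function(i) mean(pw[i, -i]), numeric(1)) |>
    stats::setNames(rownames(pw))
}

# Squared phenotypic distances between individuals: mismatch counts over
# mutually scored loci, rescaled to the full locus count so partially scored
# pairs are comparable.  For complete data this is the squared Euclidean
# distance between 0/1 band profiles.
band_sq_dist <- function(scores) {
  pres <- !is.na(scores)
  x0 <- scores; x0[!pres] <- 0L
  both <- tcrossprod(pres * 1L)
  mm <- both - tcrossprod(x0) - tcrossprod((1L - x0) * (pres * 1L))
  if (any(both == 0 & row(both) != col(both)))
    stop("individual pair with no mutually scored loci")
  d2 <- mm * ncol(scores) / both
  diag(d2) <- 0
  d2
}

amova_components <- function(d2, pop) {
  pops <- unique(pop)
  N <- length(pop)
  P <- length(pops)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (p in pops) {
    idx <- which(pop == p)
    dsub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dsub[upper.tri(dsub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_among <- P - 1
  df_within <- N - P
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_sizes <- table(pop)
  n0 <- (N - sum(n_sizes^2) / N) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  list(ss = c(among = ss_among, within = ss_within, total = ss_total),
       df = c(among = df_among, within = df_within, total = N - 1),
       ms = c(among = ms_among, within = ms_within),
       n0 = n0,
       sigma_raw = c(among = sigma_among, within = sigma_within))
}

#' Analysis of molecular variance (AMOVA) on band phenotypes
#'
#' One-level AMOVA partitioning squared Euclidean distances between 0/1 band
#' profiles into among- and within-population components, with the standard
#' unequal-sample-size coefficient n0.  Negative among-population components
#' are clamped to zero for reporting (raw values retained).  Significance of
#' Phi_ST is assessed by permuting individuals among populations.
#'
#' @param m a [marker_matrix]; populations with a single individual are
#'   excluded with a warning.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return An object of class \code{amova_result}: data.frame \code{table}
#'   (df, SS, MS), \code{sigma} (clamped components), \code{sigma_raw},
#'   \code{percent}, \code{phi_st}, \code{p}, \code{n_perm}, \code{seed}.
#' @export
amova <- function(m, n_perm = 999, seed = 1) {
  stopifnot(inherits(m, "marker_matrix"))
  sizes <- table(m$population)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding populations with a single individual: ",
            paste(drop, collapse = ", "))
    m <- subset_individuals(m, which(!(m$population %in% drop)))
  }
  if (length(unique(m$population)) < 2)
    stop("AMOVA needs at least two populations with >= 2 individuals")
  d2 <- band_sq_dist(m$scores)
  obs <- amova_components(d2, m$population)
  sigma <- pmax(obs$sigma_raw, 0)
  phi <- if (sum(sigma) > 0) sigma[["among"]] / sum(sigma) else 0
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    s <- amova_components(d2, sample(m$population))$sigma_raw
    s <- pmax(s, 0)
    if (sum(s) > 0) s[["among"]] / sum(s) else 0
  }, numeric(1))
  structure(
    list(
      table = data.frame(
        source = c("among populations", "within populations", "total"),
        df = obs$df,
        SS = obs$ss,
        MS = c(obs$ms, NA_real_),
        row.names = NULL
      ),
      sigma = sigma,
      sigma_raw = obs$sigma_raw,
      percent = 100 * sigma / sum(sigma),
      phi_st = phi,
      p = perm_pvalue(null, phi),
      n_perm = n_perm,
      seed = seed
    ),
    class = "amova_result"
  )
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (band phenotypes)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Phi_ST = %.4f  (%.1f%% among, %.1f%% within), p = %.4g [%d perms]\n",
              x$phi_st, x$percent[["among"]], x$percent[["within"]],
              x$p, x$n_perm))
  invisible(x)
}
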