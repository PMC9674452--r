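# Bayesian estimation of null-allele frequencies from dominant band
# phenotypes under inbreeding.
#
# A dominant band is absent only in individuals homozygous for the null
# (band-absent) allele.  With null-allele frequency q and inbreeding
# coefficient F_IS the band-absence probability is
#   phi(q) = q^2 + F_IS * q * (1 - q).
# Given x band-absent individuals out of n, the posterior under a Beta(a, b)
# prior on q is proportional to phi(q)^x (1 - phi(q))^(n - x) q^(a-1)
# (1-q)^(b-1); its mean and variance are obtained by adaptive quadrature.

#' Posterior null-allele frequency at one locus in one population
#'
#' @param x number of band-absent (recessive phenotype) individuals.
#' @param n sample size.
#' @param f_is inbreeding coefficient in \[0, 1\].
#' @param prior length-2 vector \code{c(a, b)} of beta hyperparameters.
#' @return List with \code{q} (posterior mean) and \code{se2} (posterior
#'   variance).
#' @export
estimate_null_freq <- function(x, n, f_is, prior = c(1, 1)) {
  stopifnot(length(prior) == 2, all(prior > 0),
            x >= 0, x <= n, n >= 1, f_is >= 0, f_is <= 1)
  a <- prior[1]; b <- prior[2]
  kernel <- function(q, pow = 0) {
    phi <- q^2 + f_is * q * (1 - q)
    # guard endpoint log(0): the integrand is 0 there unless the exponent is 0
    lg <- x * log(ifelse(phi > 0, phi, 1)) +
      (n - x) * log(ifelse(phi < 1, 1 - phi, 1))
    lg[phi <= 0 & x > 0] <- -Inf
    lg[phi >= 1 & (n - x) > 0] <- -Inf
    q^pow * exp(lg) * stats::dbeta(q, a, b)
  }
  quad <- function(pow) {
    r <- tryCatch(
      stats::integrate(kernel, 0, 1, pow = pow,
                       rel.tol = 1e-10, subdivisions = 500L),
      error = function(e) stop("posterior integration failed (x=", x,
                               ", n=", n, ", F_IS=", f_is, "): ",
                               conditionMessage(e))
    )
    r$value
  }
  m0 <- quad(0)
  if (!is.finite(m0) || m0 <= 0)
    stop("degenerate posterior normalising constant (x=", x, ", n=", n, ")")
  m1 <- quad(1) / m0
  m2 <- quad(2) / m0
  list(q = m1, se2 = max(m2 - m1^2, 0))
}

#' Method-of-moments beta prior from preliminary frequency estimates
#'
#' Fits a Beta(a, b) to first-pass per-locus allele-frequency estimates by
#' matching mean and variance.  Degenerate moments (zero variance, variance at
#' or above the Bernoulli bound, fewer than two interior frequencies) fall
#' back to the uniform Beta(1, 1).
#'
#' @param freqs numeric vector of preliminary per-locus frequencies.
#' @return Length-2 numeric vector \code{c(a, b)}.
#' @export
fit_beta_prior <- function(freqs) {
  f <- freqs[is.finite(freqs)]
  f_in <- f[f > 0 & f < 1]
  if (length(f_in) < 2) return(c(1, 1))
  m <- mean(f)
  v <- stats::var(f)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m) || m <= 0 || m >= 1)
    return(c(1, 1))
  k <- m * (1 - m) / v - 1
  c(a = m * k, b = (1 - m) * k)
}

#' Per-population, per-locus allele frequencies for a marker matrix
#'
#' Two-pass scheme in the style of AFLP-SURV: a first pass with the uniform
#' prior yields preliminary per-locus estimates within each population, a beta
#' prior is fitted to these across loci ([fit_beta_prior]), and a second pass
#' re-estimates every locus under that nonuniform prior.
#'
#' @param m a [marker_matrix].
#' @param f_is inbreeding coefficient (plug-in; default 0.643).
#' @param two_pass logical; \code{FALSE} keeps the uniform-prior estimates.
#' @return A list of class \code{allele_freqs}: matrices \code{q} and
#'   \code{se2} (populations x loci), vector \code{n} of sample sizes,
#'   \code{f_is}, and the per-population \code{prior} matrix (a, b).
#' @export
estimate_allele_freqs <- function(m, f_is = 0.643, two_pass = TRUE) {
  stopifnot(inherits(m, "marker_matrix"))
  pops <- unique(m$population)
  loci <- colnames(m$scores)
  q <- se2 <- matrix(NA_real_, length(pops), length(loci),
                     dimnames = list(pops, loci))
  nvec <- integer(length(pops)); names(nvec) <- pops
  prior_mat <- matrix(1, length(pops), 2,
                      dimnames = list(pops, c("a", "b")))
  for (p in pops) {
    sub <- m$scores[m$population == p, , drop = FALSE]
    n_l <- colSums(!is.na(sub))            # scored individuals per locus
    x_l <- colSums(sub == 0L, na.rm = TRUE)  # band-absent counts
    nvec[p] <- nrow(sub)
    pass <- function(prior) {
      # cache over unique (x, n): all loci with the same counts share the
      # same posterior
      key <- paste(x_l, n_l)
      out_q <- out_v <- numeric(length(loci))
      for (k in unique(key)) {
        idx <- which(key == k)
        est <- estimate_null_freq(x_l[idx[1]], n_l[idx[1]], f_is, prior)
        out_q[idx] <- est$q
        out_v[idx] <- est$se2
      }
      list(q = out_q, se2 = out_v)
    }
    first <- pass(c(1, 1))
    if (two_pass) {
      pr <- fit_beta_prior(first$q)
      prior_mat[p, ] <- pr
      second <- pass(pr)
      q[p, ] <- second$q
      se2[p, ] <- second$se2
    } else {
      q[p, ] <- first$q
      se2[p, ] <- first$se2
    }
  }
  structure(
    list(q = q, se2 = se2, n = nvec, f_is = f_is, prior = prior_mat),
    class = "allele_freqs"
  )
}
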