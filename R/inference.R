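# Population-level statistical tests: correlations, permutation regressions
# of distance matrices, isolation by distance, and the Q_ST--F_ST contrast.

#' Pearson/Spearman correlation with optional exclusions
#'
#' @param x,y paired numeric vectors (or named vectors; names are used for
#'   exclusion matching).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param exclude indices or names of observations to drop before computing.
#' @return List with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      exclude = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- rep(TRUE, length(x))
  if (!is.null(exclude)) {
    if (is.character(exclude)) {
      if (is.null(names(x))) stop("named exclusions need named input")
      keep[names(x) %in% exclude] <- FALSE
    } else {
      keep[exclude] <- FALSE
    }
  }
  xs <- x[keep]; ys <- y[keep]
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3) stop("need at least 3 paired observations")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("zero variance in correlate()")
  ct <- stats::cor.test(xs, ys, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs),
       method = method)
}

#' One-sample t-test
#'
#' @param values numeric vector.
#' @param mu0 null mean.
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean}.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 values")
  if (stats::sd(v) == 0) {
    # constant data: t is 0/0 unless the constant equals mu0 exactly
    if (isTRUE(all.equal(mean(v), mu0)))
      return(list(t = 0, df = length(v) - 1, p = 1, mean = mean(v)))
    stop("zero variance in one_sample_t()")
  }
  tt <- stats::t.test(v, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(v))
}

# Build the response pairs for either permutation mode.  In "pairwise" mode
# the response rows of the pair table are shuffled directly; in "matrix" mode
# the population labels of the response matrix are permuted jointly over rows
# and columns (Mantel-style) and the pairs re-extracted, which preserves the
# dependence between pairs sharing a population.
permute_response <- function(y_obs, y_mat, mode) {
  if (mode == "pairwise") {
    sample(y_obs)
  } else {
    idx <- sample(nrow(y_mat))
    perm <- y_mat[idx, idx]
    perm[lower.tri(perm)]
  }
}

#' Sequential permutation regression of distance matrices
#'
#' Fits the response pairwise distances on the predictors in the given order
#' and reports sequential (type-I) sums of squares, so each term is adjusted
#' only for the terms preceding it.  Significance per term is the add-one
#' proportion of permuted sequential F statistics at or above the observed
#' one.  \code{mode = "pairwise"} permutes response rows of the pair table
#' (treating pairs as independent); \code{mode = "matrix"} permutes the
#' population labels of the response matrix jointly over rows and columns.
#'
#' @param response labeled symmetric distance matrix (the quantitative
#'   distance in the classic use).
#' @param predictors named list of labeled symmetric matrices, in entry
#'   order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param mode \code{"pairwise"} or \code{"matrix"}.
#' @return data.frame of class \code{seq_perm_result} with one row per term:
#'   \code{term}, \code{df}, \code{ss}, \code{f}, \code{p}; attributes
#'   \code{n_perm}, \code{seed}, \code{mode}, \code{ss_total},
#'   \code{ss_residual}.
#' @export
sequential_perm_regression <- function(response, predictors, n_perm = 999,
                                       seed = 1,
                                       mode = c("pairwise", "matrix")) {
  mode <- match.arg(mode)
  stopifnot(is.list(predictors), !is.null(names(predictors)))
  labs <- rownames(response)
  pt <- do.call(pair_table,
                c(list(response = response), predictors))
  terms <- names(predictors)
  X <- as.matrix(pt[terms])
  y_obs <- pt$response
  seq_f <- function(y) {
    # sequential single-df terms via incremental least-squares fits
    ss <- numeric(length(terms))
    rss_prev <- sum((y - mean(y))^2)
    for (k in seq_along(terms)) {
      fk <- stats::lm(y ~ X[, seq_len(k), drop = FALSE])
      rss_k <- sum(stats::resid(fk)^2)
      ss[k] <- rss_prev - rss_k
      rss_prev <- rss_k
    }
    ms_resid <- rss_prev / (length(y) - length(terms) - 1)
    list(ss = ss, f = ss / ms_resid, rss = rss_prev)
  }
  obs <- seq_f(y_obs)
  if (any(obs$ss < -1e-8)) stop("negative sequential SS")
  # collinearity diagnostic
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    warning("collinear predictors: sequential SS still defined by order")
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    yp <- permute_response(y_obs, response, mode)
    fp <- seq_f(yp)
    exceed <- exceed + (fp$f >= obs$f)
  }
  out <- data.frame(
    term = terms,
    df = rep(1L, length(terms)),
    ss = obs$ss,
    f = obs$f,
    p = (1 + exceed) / (n_perm + 1),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  attr(out, "ss_total") <- sum((y_obs - mean(y_obs))^2)
  attr(out, "ss_residual") <- obs$rss
  class(out) <- c("seq_perm_result", "data.frame")
  out
}

#' Isolation-by-distance permutation test
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices, with a permutation p-value (add-one, two-sided on |r|) under the
#' chosen mode (see [sequential_perm_regression]).
#'
#' @param dist_y,dist_x labeled symmetric matrices over the same populations.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param mode \code{"pairwise"} or \code{"matrix"}.
#' @return List with \code{r}, \code{p}, \code{n_pairs}, \code{n_perm},
#'   \code{mode}, \code{seed}.
#' @export
ibd_test <- function(dist_y, dist_x, n_perm = 999, seed = 1,
                     mode = c("pairwise", "matrix")) {
  mode <- match.arg(mode)
  labs <- rownames(dist_y)
  if (!identical(labs, rownames(dist_x)))
    dist_x <- dist_x[labs, labs]
  y <- dist_y[lower.tri(dist_y)]
  x <- dist_x[lower.tri(dist_x)]
  r_obs <- stats::cor(x, y)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(b) {
    abs(stats::cor(x, permute_response(y, dist_y, mode)))
  }, numeric(1))
  list(r = r_obs, p = perm_pvalue(null, abs(r_obs)),
       n_pairs = length(y), n_perm = n_perm, mode = mode, seed = seed)
}

#' Compare quantitative (Q_ST) and molecular (F_ST) differentiation
#'
#' Per trait: \code{"divergent"} if the Q_ST confidence interval lies
#' entirely above the F_ST interval, \code{"stabilizing"} if entirely below,
#' \code{"drift-consistent"} otherwise.  The F_ST interval is the 2.5--97.5\%
#' quantile range of the permutation null re-centred on the F_ST estimate.
#'
#' @param qst_table data.frame with columns \code{trait}, \code{qst},
#'   \code{qst_lo}, \code{qst_hi} (e.g. the \code{global} element of
#'   [quantgen_summary]).
#' @param fst_test result of [fst_permutation_test].
#' @return data.frame with trait, qst, qst_lo, qst_hi, fst, fst_lo, fst_hi,
#'   verdict.
#' @export
compare_qst_fst <- function(qst_table, fst_test) {
  need <- c("trait", "qst", "qst_lo", "qst_hi")
  stopifnot(all(need %in% names(qst_table)))
  half <- (fst_test$ci - stats::median(fst_test$null))
  f_lo <- fst_test$fst + half[1]
  f_hi <- fst_test$fst + half[2]
  verdict <- ifelse(qst_table$qst_lo > f_hi, "divergent",
                    ifelse(qst_table$qst_hi < f_lo, "stabilizing",
                           "drift-consistent"))
  data.frame(
    trait = qst_table$trait,
    qst = qst_table$qst, qst_lo = qst_table$qst_lo,
    qst_hi = qst_table$qst_hi,
    fst = fst_test$fst, fst_lo = f_lo, fst_hi = f_hi,
    verdict = verdict,
    stringsAsFactors = FALSE
  )
}
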