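# Common-garden quantitative genetics: nested variance components,
# heritability, evolvability, additive genetic SD and Q_ST under mixed mating.
#
# Seed families collected from open-pollinated mothers in a mixed-mating
# species are a mixture of selfed and full-sib progeny.  The kinship weight
# theta converts the family variance component into additive variance:
# V_A = V_fam / (2 theta), with theta = 0.5 for selfed sibships and 0.25 for
# full sibs.

#' Mixed-mating kinship weight
#'
#' @param selfing_fraction proportion of offspring derived from selfing.
#' @return theta = 0.5 * s + 0.25 * (1 - s), in \[0.25, 0.5\].
#' @export
mixed_mating_theta <- function(selfing_fraction) {
  stopifnot(selfing_fraction >= 0, selfing_fraction <= 1)
  0.5 * selfing_fraction + 0.25 * (1 - selfing_fraction)
}

# Apply the per-trait transformation tag ("sqrt" or "none").
apply_transform <- function(y, transform) {
  switch(transform,
         none = y,
         sqrt = {
           if (any(y < 0, na.rm = TRUE)) stop("sqrt transform of negative values")
           sqrt(y)
         },
         stop("unknown transform: ", transform))
}

validate_traits <- function(traits, trait) {
  need <- c("population_id", "family_id", trait)
  if (!all(need %in% names(traits)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  fam_pop <- unique(traits[, c("population_id", "family_id")])
  if (anyDuplicated(fam_pop$family_id))
    stop("family ids must be nested within exactly one population")
  invisible(traits)
}

#' Nested variance components for one trait
#'
#' Fits the two-level random model y = mu + pop + fam(pop) + error.
#' \code{method = "reml"} uses restricted maximum likelihood via
#' \code{lme4::lmer}; \code{method = "moments"} solves the nested-ANOVA
#' expected mean squares (Sokal--Rohlf style, with unbalanced-design
#' coefficients), clamping negative estimates to zero.  The moments method is
#' retained as an algebraically independent cross-check of the REML fit.
#'
#' @param traits data.frame with \code{population_id}, \code{family_id} and
#'   the trait column.
#' @param trait trait column name.
#' @param method \code{"reml"} or \code{"moments"}.
#' @param transform \code{"none"} or \code{"sqrt"} (flower counts are
#'   conventionally sqrt-transformed before fitting).
#' @return List of class \code{variance_components}: \code{v_pop},
#'   \code{v_fam}, \code{v_error}, \code{mean} (grand mean on the analysis
#'   scale), \code{trait}, \code{method}, \code{transform}, \code{converged}.
#' @export
fit_nested_components <- function(traits, trait, method = c("reml", "moments"),
                                  transform = "none") {
  method <- match.arg(method)
  validate_traits(traits, trait)
  y <- apply_transform(traits[[trait]], transform)
  d <- data.frame(y = y,
                  pop = factor(traits$population_id),
                  fam = factor(traits$family_id))
  d <- d[is.finite(d$y), ]
  if (nlevels(droplevels(d$pop)) < 2)
    stop("need at least two populations")
  if (method == "reml") {
    fit <- lme4::lmer(y ~ 1 + (1 | pop) + (1 | fam), data = d,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) vc$vcov[vc$grp == g]
    out <- list(v_pop = get("pop"), v_fam = get("fam"),
                v_error = get("Residual"), converged = TRUE)
  } else {
    out <- nested_moments(d)
  }
  structure(
    c(out, list(mean = mean(d$y), trait = trait, method = method,
                transform = transform)),
    class = "variance_components"
  )
}

# Nested ANOVA expected-mean-squares solution with unbalanced coefficients.
# EMS: MS_err = Ve; MS_fam = Ve + k1 Vf; MS_pop = Ve + k2 Vf + k3 Vp, where
# the k's are the standard unequal-n coefficients.
nested_moments <- function(d) {
  N <- nrow(d)
  pops <- levels(droplevels(d$pop))
  P <- length(pops)
  n_fam <- tapply(d$y, d$fam, length)
  n_fam <- n_fam[!is.na(n_fam)]
  Fami <- length(n_fam)
  grand <- mean(d$y)
  fam_mean <- tapply(d$y, d$fam, mean)
  pop_of_fam <- tapply(as.character(d$pop), d$fam, `[`, 1)
  pop_mean <- tapply(d$y, d$pop, mean)
  pop_n <- tapply(d$y, d$pop, length)
  ss_err <- sum((d$y - fam_mean[as.character(d$fam)])^2)
  ss_fam <- sum(n_fam * (fam_mean - pop_mean[pop_of_fam[names(n_fam)]])^2)
  ss_pop <- sum(pop_n * (pop_mean - grand)^2)
  df_err <- N - Fami
  df_fam <- Fami - P
  df_pop <- P - 1
  ms_err <- ss_err / df_err
  ms_fam <- ss_fam / df_fam
  ms_pop <- ss_pop / df_pop
  # unbalanced-design EMS coefficients
  sum_n2_by_pop <- tapply(n_fam^2, pop_of_fam[names(n_fam)], sum)
  k1 <- (N - sum(sum_n2_by_pop / pop_n)) / df_fam
  k2 <- (sum(sum_n2_by_pop / pop_n) - sum(n_fam^2) / N) / df_pop
  k3 <- (N - sum(pop_n^2) / N) / df_pop
  v_error <- ms_err
  v_fam <- max((ms_fam - ms_err) / k1, 0)
  v_pop <- max((ms_pop - ms_err - k2 * v_fam) / k3, 0)
  list(v_pop = v_pop, v_fam = v_fam, v_error = v_error, converged = TRUE,
       ms = c(pop = ms_pop, fam = ms_fam, error = ms_err),
       k = c(k1 = k1, k2 = k2, k3 = k3))
}

#' Narrow-sense heritability from family variance components
#'
#' h^2 = (V_fam / (2 theta)) / (V_fam + V_error), clipped to \[0, 1\].
#'
#' @param vc a \code{variance_components} object (or list with \code{v_fam},
#'   \code{v_error}).
#' @param theta kinship weight from [mixed_mating_theta].
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(vc, theta) {
  va <- vc$v_fam / (2 * theta)
  vp <- vc$v_fam + vc$v_error
  if (vp <= 0) return(0)
  min(max(va / vp, 0), 1)
}

#' Additive genetic standard deviation
#'
#' SD_A = sqrt(V_fam / (2 theta)).
#'
#' @inheritParams heritability
#' @return Non-negative SD on the analysis scale of the trait.
#' @export
additive_sd <- function(vc, theta) {
  sqrt(vc$v_fam / (2 * theta))
}

#' Evolvability (genetic coefficient of variation)
#'
#' CV_genetic = sqrt(V_fam / (2 theta)) / mean, the additive genetic SD
#' scaled by the trait mean.  Returned as a proportion; multiply by 100 for
#' the conventional percentage.
#'
#' @inheritParams heritability
#' @param trait_mean trait mean on the analysis scale; must be positive.
#' @return Non-negative proportion.
#' @export
evolvability <- function(vc, theta, trait_mean) {
  if (trait_mean <= 0) stop("evolvability needs a positive trait mean")
  additive_sd(vc, theta) / trait_mean
}

#' Quantitative genetic differentiation Q_ST
#'
#' Q_ST = V_pop / (V_fam / theta + V_pop).  With family variance converted to
#' additive variance via theta this is the among-population fraction of total
#' additive variance.
#'
#' @inheritParams heritability
#' @return Q_ST in \[0, 1\]; \code{NaN} with a warning when both components
#'   are zero.
#' @export
qst <- function(vc, theta) {
  if (vc$v_pop + vc$v_fam <= 0) {
    warning("Q_ST undefined: both V_pop and V_fam are zero")
    return(NaN)
  }
  min(max(vc$v_pop / (vc$v_fam / theta + vc$v_pop), 0), 1)
}

#' Q_ST with a jackknife-over-populations confidence interval
#'
#' Delete-one-population refits yield pseudo-values
#' P (Q_full) - (P - 1) Q_(-i); the CI is pseudo-value mean +/- t-quantile
#' times the pseudo-value standard error with df = populations - 1 (reduced
#' when leave-one-out refits fail).
#'
#' @param traits trait table (see [fit_nested_components]).
#' @param trait trait column name.
#' @param theta kinship weight.
#' @param level confidence level.
#' @param method,transform passed to [fit_nested_components].
#' @return List with \code{qst}, \code{ci} (length 2), \code{se},
#'   \code{pseudo_values}, \code{df}.
#' @export
qst_jackknife_ci <- function(traits, trait, theta, level = 0.95,
                             method = "reml", transform = "none") {
  validate_traits(traits, trait)
  pops <- unique(traits$population_id)
  P <- length(pops)
  if (P < 3) stop("jackknife over populations needs >= 3 populations")
  fit_q <- function(tt) {
    vc <- fit_nested_components(tt, trait, method = method,
                                transform = transform)
    qst(vc, theta)
  }
  q_full <- fit_q(traits)
  loo <- vapply(pops, function(p) {
    tryCatch(fit_q(traits[traits$population_id != p, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(loo)) {
    warning("leave-one-out refit failed for: ",
            paste(pops[is.na(loo)], collapse = ", "))
    loo <- loo[!is.na(loo)]
  }
  k <- length(loo)
  pseudo <- k * q_full - (k - 1) * loo
  se <- stats::sd(pseudo) / sqrt(k)
  tq <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  est <- mean(pseudo)
  list(qst = q_full, ci = c(est - tq * se, est + tq * se),
       se = se, pseudo_values = unname(pseudo), df = k - 1)
}

#' Per-population heritability, evolvability and trait means
#'
#' One-way family random-effects fits within each population; h^2 and
#' CV_genetic are derived from the within-population V_fam, V_error and mean.
#' Populations with fewer than two families are omitted with a warning.
#'
#' @param traits trait table.
#' @param trait trait column name.
#' @param theta kinship weight.
#' @param method \code{"reml"} (via \code{lme4}) or \code{"moments"}
#'   (one-way expected mean squares, V_fam = (MS_fam - MS_err) / n0).
#' @param transform \code{"none"} or \code{"sqrt"}.
#' @return data.frame with population, n_families, n_plants, v_fam, v_error,
#'   mean (analysis scale), mean_raw, h2, cv_genetic, sd_a.
#' @export
per_population_quantgen <- function(traits, trait, theta,
                                    method = c("reml", "moments"),
                                    transform = "none") {
  method <- match.arg(method)
  validate_traits(traits, trait)
  pops <- unique(traits$population_id)
  n_fam_per_pop <- vapply(pops, function(p) {
    length(unique(traits$family_id[traits$population_id == p]))
  }, integer(1))
  if (any(n_fam_per_pop < 2)) {
    warning("omitting populations with < 2 families: ",
            paste(pops[n_fam_per_pop < 2], collapse = ", "))
    pops <- pops[n_fam_per_pop >= 2]
  }
  rows <- lapply(pops, function(p) {
    tt <- traits[traits$population_id == p, , drop = FALSE]
    y <- apply_transform(tt[[trait]], transform)
    ok <- is.finite(y)
    y <- y[ok]
    fam <- factor(tt$family_id[ok])
    vc <- if (method == "reml") {
      fit <- lme4::lmer(y ~ 1 + (1 | fam),
                        data = data.frame(y = y, fam = fam),
                        control = lme4::lmerControl(calc.derivs = FALSE))
      vcd <- as.data.frame(lme4::VarCorr(fit))
      list(v_fam = vcd$vcov[vcd$grp == "fam"],
           v_error = vcd$vcov[vcd$grp == "Residual"])
    } else {
      oneway_moments(y, fam)
    }
    m <- mean(y)
    data.frame(
      population = p,
      n_families = nlevels(droplevels(fam)),
      n_plants = length(y),
      v_fam = vc$v_fam,
      v_error = vc$v_error,
      mean = m,
      mean_raw = mean(tt[[trait]][ok]),
      h2 = heritability(vc, theta),
      cv_genetic = if (m > 0) additive_sd(vc, theta) / m else NA_real_,
      sd_a = additive_sd(vc, theta),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# One-way random-effects moments solution: V_fam = (MS_fam - MS_err) / n0
# with n0 the unequal-n coefficient, clamped at zero.
oneway_moments <- function(y, fam) {
  fam <- droplevels(fam)
  k <- nlevels(fam)
  N <- length(y)
  n_i <- tabulate(fam)
  fm <- tapply(y, fam, mean)
  ms_err <- sum((y - fm[fam])^2) / (N - k)
  ms_fam <- sum(n_i * (fm - mean(y))^2) / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  list(v_fam = max((ms_fam - ms_err) / n0, 0), v_error = ms_err)
}

#' Full quantitative-genetic summary for a set of traits
#'
#' Convenience wrapper running the global nested fit, Q_ST with jackknife CI
#' and the per-population fits for each trait.
#'
#' @param traits trait table.
#' @param trait_transforms named character vector mapping trait column names
#'   to \code{"none"}/\code{"sqrt"}.
#' @param selfing_fraction proportion of selfed offspring (default 0.55).
#' @param level CI level for the jackknife.
#' @return List of class \code{quantgen_result} with \code{theta},
#'   \code{global} (per-trait data.frame), \code{per_population} (named list
#'   of data.frames) and \code{jackknife} (named list).
#' @export
quantgen_summary <- function(traits, trait_transforms,
                             selfing_fraction = 0.55, level = 0.95) {
  theta <- mixed_mating_theta(selfing_fraction)
  global <- list(); perpop <- list(); jack <- list()
  for (trait in names(trait_transforms)) {
    tr <- trait_transforms[[trait]]
    vc <- fit_nested_components(traits, trait, method = "reml", transform = tr)
    jk <- qst_jackknife_ci(traits, trait, theta, level = level, transform = tr)
    global[[trait]] <- data.frame(
      trait = trait, transform = tr,
      v_pop = vc$v_pop, v_fam = vc$v_fam, v_error = vc$v_error,
      mean = vc$mean,
      h2 = heritability(vc, theta),
      cv_genetic = evolvability(vc, theta, vc$mean),
      sd_a = additive_sd(vc, theta),
      qst = qst(vc, theta),
      qst_lo = jk$ci[1], qst_hi = jk$ci[2],
      stringsAsFactors = FALSE
    )
    perpop[[trait]] <- per_population_quantgen(traits, trait, theta,
                                               transform = tr)
    jack[[trait]] <- jk
  }
  structure(
    list(theta = theta,
         global = do.call(rbind, c(global, list(make.row.names = FALSE))),
         per_population = perpop,
         jackknife = jack),
    class = "quantgen_result"
  )
}
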