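# Synthetic study generator.  Emulates the sampling design the analysis
# assumes: ~19 fragmented populations within a ~61 km region, 13-15 plants
# sampled along 15 m transects, ~52 dominant loci with Balding-Nichols
# differentiation, strong inbreeding, scoring error and occasional clones;
# and a common garden of ~14 seed families per population with ~5.7 plants
# per family under a nested population/family/residual variance model.

#' Simulate a dominant-marker study
#'
#' Ancestral null-allele frequencies are drawn from a beta distribution;
#' population frequencies follow the Balding-Nichols model
#' \code{Beta(q(1-F)/F, (1-q)(1-F)/F)} with \code{F} the target F_ST.  An
#' individual lacks a band with probability \code{q^2 + F_IS q (1 - q)}
#' (inbreeding-inflated homozygosity for the null allele).  Each score is
#' then flipped with a per-scoring probability \code{eps} chosen so that two
#' independent scorings of the same genotype disagree at rate
#' \code{error_rate} (\code{2 eps (1 - eps) = error_rate}) -- the quantity a
#' replicate-scoring experiment estimates, and the rate at which members of
#' a clone pair mismatch.  Clone pairs are created before scoring error by
#' copying a genotype onto another individual of the same population placed
#' within 1 m on the transect.  A fraction of individuals is independently
#' re-scored to provide a replicate set for error-rate estimation.
#'
#' @param n_pops number of populations.
#' @param n_ind individuals sampled per population.
#' @param n_loci number of dominant loci.
#' @param fst target differentiation (Balding-Nichols F).
#' @param f_is inbreeding coefficient used for band-absence probabilities.
#' @param ancestral_beta length-2 beta parameters of ancestral frequencies.
#' @param error_rate replicate-disagreement scoring error rate.
#' @param n_clone_pairs number of injected clone pairs.
#' @param replicate_fraction fraction of individuals independently re-scored
#'   for the replicate set.
#' @param transect_length_m transect length for positions.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with \code{markers} (a [marker_matrix]), \code{replicates}
#'   (list of (original, re-scored) score-vector pairs) and \code{truth}
#'   (latent ancestral and population frequencies, clone ids, and the
#'   configuration).
#' @export
simulate_markers <- function(n_pops = 19, n_ind = 13, n_loci = 52,
                             fst = 0.08, f_is = 0.643,
                             ancestral_beta = c(2, 2),
                             error_rate = 0.066, n_clone_pairs = 3,
                             replicate_fraction = 0.2,
                             transect_length_m = 15, seed = 1) {
  stopifnot(fst > 0, fst < 1, error_rate >= 0, error_rate < 0.5,
            n_pops >= 1, n_ind >= 1, n_loci >= 1)
  eps <- (1 - sqrt(1 - 2 * error_rate)) / 2  # per-scoring flip probability
  set.seed(seed)
  q_anc <- stats::rbeta(n_loci, ancestral_beta[1], ancestral_beta[2])
  shape <- (1 - fst) / fst
  q_pop <- matrix(stats::rbeta(n_pops * n_loci,
                               rep(q_anc, each = n_pops) * shape,
                               rep(1 - q_anc, each = n_pops) * shape),
                  nrow = n_pops)
  pops <- sprintf("pop%02d", seq_len(n_pops))
  dimnames(q_pop) <- list(pops, sprintf("L%02d", seq_len(n_loci)))
  N <- n_pops * n_ind
  pop_of <- rep(pops, each = n_ind)
  ids <- sprintf("%s_i%02d", pop_of, rep(seq_len(n_ind), n_pops))
  # band-absence probability per individual x locus
  p_abs <- q_pop[pop_of, , drop = FALSE]
  p_abs <- p_abs^2 + f_is * p_abs * (1 - p_abs)
  geno <- matrix(as.integer(stats::runif(N * n_loci) >= p_abs), N, n_loci,
                 dimnames = list(ids, colnames(q_pop)))  # 1 = band present
  position <- stats::runif(N, 0, transect_length_m)
  clone_ids <- list()
  if (n_clone_pairs > 0) {
    donors <- sample(N, n_clone_pairs)
    for (d in donors) {
      same_pop <- setdiff(which(pop_of == pop_of[d]), c(d, unlist(clone_ids)))
      if (length(same_pop) == 0) next
      r <- same_pop[sample.int(length(same_pop), 1)]
      geno[r, ] <- geno[d, ]
      position[r] <- position[d] + stats::runif(1, 0.01, 0.95) *
        sample(c(-1, 1), 1)
      clone_ids[[length(clone_ids) + 1]] <- c(ids[d], ids[r])
    }
  }
  flip <- matrix(stats::runif(N * n_loci) < eps, N, n_loci)
  scored <- ifelse(flip, 1L - geno, geno)
  dimnames(scored) <- dimnames(geno)
  replicates <- list()
  if (replicate_fraction > 0) {
    re_ids <- sample(N, max(1, round(replicate_fraction * N)))
    replicates <- lapply(re_ids, function(i) {
      reflip <- stats::runif(n_loci) < eps
      list(scored[i, ], ifelse(reflip, 1L - geno[i, ], geno[i, ]))
    })
  }
  list(
    markers = marker_matrix(scored, pop_of, position),
    replicates = replicates,
    truth = list(q_ancestral = q_anc, q_pop = q_pop,
                 clone_pairs = clone_ids,
                 config = list(n_pops = n_pops, n_ind = n_ind,
                               n_loci = n_loci, fst = fst, f_is = f_is,
                               error_rate = error_rate, eps = eps,
                               n_clone_pairs = n_clone_pairs, seed = seed))
  )
}

#' Simulate population sites and climate
#'
#' Coordinates are uniform in a bounding box sized like a fragmented-meadow
#' study region (tens of km).  Each bioclimatic variable is a linear function
#' of two latent geographic gradients (a precipitation-like axis following
#' longitude and a temperature-like axis following latitude) plus noise, so
#' two principal components dominate the climate PCA.  Census sizes are
#' log-normal, spanning a few plants to tens of thousands.
#'
#' @param n_pops number of populations.
#' @param lat_range,lon_range bounding box in decimal degrees.
#' @param noise_sd SD of the climate noise relative to unit-variance
#'   gradients.
#' @param seed integer seed.
#' @return List with \code{sites} (population_id, latitude, longitude,
#'   census_size) and \code{climate} (population_id + 10 bioclim-style
#'   variables).
#' @export
simulate_sites_climate <- function(n_pops = 19,
                                   lat_range = c(49.45, 49.75),
                                   lon_range = c(5.90, 6.75),
                                   noise_sd = 0.15, seed = 1) {
  stopifnot(all(abs(lat_range) <= 90), all(abs(lon_range) <= 180))
  set.seed(seed)
  pops <- sprintf("pop%02d", seq_len(n_pops))
  lat <- stats::runif(n_pops, lat_range[1], lat_range[2])
  lon <- stats::runif(n_pops, lon_range[1], lon_range[2])
  g_precip <- as.numeric(scale(lon))   # precipitation-like axis
  g_temp <- as.numeric(scale(lat))     # temperature-like axis
  load <- rbind(
    annual_precip        = c(1.00, 0.05),
    precip_wettest_month = c(0.95, 0.00),
    precip_driest_month  = c(0.90, -0.05),
    precip_seasonality   = c(0.70, 0.10),
    diurnal_range        = c(-0.80, 0.20),
    temp_annual_range    = c(-0.60, 0.30),
    mean_annual_temp     = c(0.10, 0.95),
    max_temp_warmest     = c(0.05, 1.00),
    min_temp_coldest     = c(0.15, 0.85),
    temp_seasonality     = c(-0.20, 0.60)
  )
  clim <- sapply(rownames(load), function(v) {
    load[v, 1] * g_precip + load[v, 2] * g_temp +
      stats::rnorm(n_pops, 0, noise_sd)
  })
  census <- pmax(5L, as.integer(round(stats::rlnorm(n_pops,
                                                    meanlog = log(500),
                                                    sdlog = 2))))
  list(
    sites = data.frame(population_id = pops, latitude = lat,
                       longitude = lon, census_size = census,
                       stringsAsFactors = FALSE),
    climate = data.frame(population_id = pops, clim,
                         stringsAsFactors = FALSE)
  )
}

# Default common-garden trait configuration.  Variances chosen so that, at
# theta = 0.3875, each trait has narrow-sense heritability near 0.4 and
# Q_ST near 0.08 (matching differentiation at the molecular level).
default_trait_config <- function() {
  list(
    diameter = list(mean = 10, v_pop = 0.27, v_fam = 1.2, v_error = 2.8,
                    transform = "none", coupling = 0),
    leaf_width = list(mean = 5, v_pop = 0.09, v_fam = 0.4, v_error = 0.95,
                      transform = "none", coupling = 0),
    flowers = list(mean = 3, v_pop = 0.055, v_fam = 0.25, v_error = 0.58,
                   transform = "sqrt", coupling = 0)
  )
}

#' Simulate a common-garden trait table
#'
#' Nested model per trait: population effect ~ N(0, V_pop) plus an optional
#' deterministic climate-coupled shift (\code{coupling} times the
#' standardized longitude gradient of the sites), family effect
#' ~ N(0, V_fam), residual ~ N(0, V_error).  Traits with
#' \code{transform = "sqrt"} are generated on the square-root scale, then
#' squared and rounded to non-negative integers, so the variance model is
#' exact on the analysis scale.
#'
#' @param traits named list of per-trait configurations (mean, v_pop, v_fam,
#'   v_error, transform, coupling); see \code{fragpop:::default_trait_config}
#'   for the defaults.
#' @param sites site table from [simulate_sites_climate]; required when any
#'   coupling is non-zero, otherwise optional.
#' @param n_pops number of populations (ignored when \code{sites} given).
#' @param families_per_pop seed families per population.
#' @param plants_per_family mean plants per family; realized sizes vary
#'   between 3 and 10.
#' @param selfing_fraction recorded in the truth record (the design's mating
#'   mixture; variance components are specified directly).
#' @param seed integer seed.
#' @return List with \code{traits} (plant_id, population_id, family_id, one
#'   column per trait) and \code{truth}.
#' @export
simulate_traits <- function(traits = default_trait_config(), sites = NULL,
                            n_pops = 19, families_per_pop = 14,
                            plants_per_family = 5.7,
                            selfing_fraction = 0.55, seed = 1) {
  set.seed(seed)
  if (!is.null(sites)) {
    pops <- sites$population_id
    gradient <- as.numeric(scale(sites$longitude))
  } else {
    if (any(vapply(traits, function(t) t$coupling != 0, logical(1))))
      stop("climate coupling requires a site table")
    pops <- sprintf("pop%02d", seq_len(n_pops))
    gradient <- rep(0, n_pops)
  }
  P <- length(pops)
  fam_sizes <- lapply(seq_len(P), function(i) {
    pmin(pmax(round(stats::rnorm(families_per_pop, plants_per_family, 1.5)),
              3), 10)
  })
  rows <- list()
  truth_effects <- list()
  for (trait in names(traits)) {
    cfg <- traits[[trait]]
    pop_eff <- stats::rnorm(P, 0, sqrt(cfg$v_pop)) +
      cfg$coupling * gradient
    fam_eff <- lapply(seq_len(P), function(i) {
      stats::rnorm(families_per_pop, 0, sqrt(cfg$v_fam))
    })
    truth_effects[[trait]] <- list(pop = stats::setNames(pop_eff, pops))
    vals <- list()
    for (i in seq_len(P)) {
      for (j in seq_len(families_per_pop)) {
        nf <- fam_sizes[[i]][j]
        y <- cfg$mean + pop_eff[i] + fam_eff[[i]][j] +
          stats::rnorm(nf, 0, sqrt(cfg$v_error))
        if (cfg$transform == "sqrt")
          y <- round(pmax(y, 0)^2)
        vals[[paste(i, j)]] <- y
      }
    }
    rows[[trait]] <- unlist(vals, use.names = FALSE)
  }
  fam_id <- unlist(lapply(seq_len(P), function(i) {
    rep(sprintf("%s_f%02d", pops[i], seq_len(families_per_pop)),
        fam_sizes[[i]])
  }))
  pop_id <- unlist(lapply(seq_len(P), function(i) {
    rep(pops[i], sum(fam_sizes[[i]]))
  }))
  out <- data.frame(
    plant_id = sprintf("plant%04d", seq_along(fam_id)),
    population_id = pop_id,
    family_id = fam_id,
    stringsAsFactors = FALSE
  )
  for (trait in names(traits)) out[[trait]] <- rows[[trait]]
  list(
    traits = out,
    truth = list(config = traits, effects = truth_effects,
                 selfing_fraction = selfing_fraction,
                 theta = mixed_mating_theta(selfing_fraction),
                 seed = seed)
  )
}

#' Simulate the full study bundle
#'
#' Sites/climate, markers and common-garden traits in one call, sharing a
#' seed; the convenience entry point for end-to-end runs.
#'
#' @param seed integer seed.
#' @param ... overrides passed to the individual generators as lists
#'   \code{markers}, \code{traits}, \code{sites}.
#' @return List with \code{markers}, \code{traits}, \code{sites},
#'   \code{climate}, \code{truth}.
#' @export
simulate_study <- function(seed = 1, ...) {
  over <- list(...)
  sc <- do.call(simulate_sites_climate,
                c(list(seed = seed), over$sites))
  mk <- do.call(simulate_markers, c(list(seed = seed + 1), over$markers))
  tr <- do.call(simulate_traits,
                c(list(sites = sc$sites, seed = seed + 2), over$traits))
  list(markers = mk$markers, replicates = mk$replicates,
       traits = tr$traits, sites = sc$sites, climate = sc$climate,
       truth = list(markers = mk$truth, traits = tr$truth))
}
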