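test_that("generators are pure functions of their seeds", {
  m1 <- simulate_markers(n_pops = 3, n_ind = 6, n_loci = 12, seed = 5)
  m2 <- simulate_markers(n_pops = 3, n_ind = 6, n_loci = 12, seed = 5)
  expect_identical(m1$markers$scores, m2$markers$scores)
  expect_identical(m1$replicates, m2$replicates)
  m3 <- simulate_markers(n_pops = 3, n_ind = 6, n_loci = 12, seed = 6)
  expect_false(identical(m1$markers$scores, m3$markers$scores))
  t1 <- simulate_traits(n_pops = 4, families_per_pop = 5, seed = 2)
  t2 <- simulate_traits(n_pops = 4, families_per_pop = 5, seed = 2)
  expect_identical(t1$traits, t2$traits)
  s1 <- simulate_sites_climate(n_pops = 5, seed = 3)
  s2 <- simulate_sites_climate(n_pops = 5, seed = 3)
  expect_identical(s1, s2)
  st1 <- simulate_study(seed = 9)
  st2 <- simulate_study(seed = 9)
  expect_identical(st1$markers$scores, st2$markers$scores)
  expect_identical(st1$traits, st2$traits)
})

test_that("band-absence frequencies follow the phenotype model at the limit", {
  # near-zero differentiation, no inbreeding, no error: band-absence
  # frequency per locus approaches the ancestral q^2
  sim <- simulate_markers(n_pops = 4, n_ind = 250, n_loci = 30, fst = 1e-4,
                          f_is = 0, error_rate = 0, n_clone_pairs = 0,
                          replicate_fraction = 0, seed = 7)
  p_abs_obs <- colMeans(sim$markers$scores == 0)
  p_abs_exp <- sim$truth$q_ancestral^2
  n_tot <- nrow(sim$markers$scores)
  # within 4 binomial SEs locus-wise
  se <- sqrt(pmax(p_abs_exp * (1 - p_abs_exp), 1e-6) / n_tot)
  expect_true(all(abs(p_abs_obs - p_abs_exp) < 4 * se + 2e-3))
})

test_that("inbreeding raises band-absence beyond Hardy-Weinberg", {
  sim0 <- simulate_markers(n_pops = 2, n_ind = 400, n_loci = 25, fst = 1e-4,
                           f_is = 0, error_rate = 0, n_clone_pairs = 0,
                           replicate_fraction = 0, seed = 11)
  sim1 <- simulate_markers(n_pops = 2, n_ind = 400, n_loci = 25, fst = 1e-4,
                           f_is = 0.643, error_rate = 0, n_clone_pairs = 0,
                           replicate_fraction = 0, seed = 11)
  expect_gt(mean(sim1$markers$scores == 0), mean(sim0$markers$scores == 0))
})

test_that("replicate set recovers the configured scoring error rate", {
  e_hat <- vapply(1:10, function(s) {
    sim <- simulate_markers(n_pops = 10, n_ind = 13, n_loci = 52,
                            error_rate = 0.066, replicate_fraction = 0.5,
                            seed = s)
    estimate_error_rate(sim$replicates)$e
  }, numeric(1))
  expect_lt(abs(mean(e_hat) - 0.066), 0.01)
})

test_that("injected clones are recoverable through the derived threshold", {
  found <- t(sapply(1:20, function(s) {
    sim <- simulate_markers(error_rate = 0.05, n_clone_pairs = 2, seed = s)
    er <- estimate_error_rate(sim$replicates)
    thr <- clone_threshold(er, ncol(sim$markers$scores))$threshold
    call <- detect_clones(sim$markers, thr)
    hits <- vapply(sim$truth$clone_pairs, function(pr) {
      any(vapply(call$groups, function(g) all(pr %in% g), logical(1)))
    }, logical(1))
    c(n_found = sum(hits), spurious = call$n_groups <
        nrow(sim$markers$scores) - length(sim$truth$clone_pairs) - 2)
  }))
  # detection per pair is capped by the binomial mass below the threshold
  # (the threshold sits at the mean of the mismatch distribution), so full
  # recovery of both pairs is only intermittent while partial recovery is
  # routine
  expect_gte(mean(found[, "n_found"] >= 1), 0.8)
  expect_gte(mean(found[, "n_found"] == 2), 0.3)
  # no wholesale collapsing of distinct genotypes
  expect_equal(sum(found[, "spurious"]), 0)
})

test_that("clone pairs sit within a metre on the transect", {
  sim <- simulate_markers(n_clone_pairs = 3, error_rate = 0, seed = 3)
  for (pr in sim$truth$clone_pairs) {
    i <- match(pr, rownames(sim$markers$scores))
    expect_lt(abs(diff(sim$markers$position[i])), 1)
    expect_identical(sim$markers$scores[i[1], ], sim$markers$scores[i[2], ])
  }
})

test_that("trait generator reproduces its nested variance structure", {
  cfg <- list(y = list(mean = 10, v_pop = 0, v_fam = 1, v_error = 2,
                       transform = "none", coupling = 0))
  # no population variance: fitted Q_ST stays near zero
  q_null <- vapply(1:10, function(s) {
    sim <- simulate_traits(cfg, seed = s)
    qst(fit_nested_components(sim$traits, "y", method = "moments"), 0.3875)
  }, numeric(1))
  expect_lt(median(q_null), 0.05)
  # configured components are recovered on the study design
  fits <- sapply(1:10, function(s) {
    cfg2 <- list(y = list(mean = 10, v_pop = 0.5, v_fam = 1, v_error = 2,
                          transform = "none", coupling = 0))
    f <- fit_nested_components(simulate_traits(cfg2, seed = s)$traits, "y",
                               method = "moments")
    c(f$v_pop, f$v_fam, f$v_error)
  })
  expect_equal(unname(apply(fits, 1, median)), c(0.5, 1, 2), tolerance = 0.25)
})

test_that("flower counts are integers generated on the sqrt scale", {
  sim <- simulate_traits(seed = 5)
  expect_true(all(sim$traits$flowers >= 0))
  expect_true(all(sim$traits$flowers == round(sim$traits$flowers)))
  # analysis-scale components recover the configured values
  f <- fit_nested_components(sim$traits, "flowers", method = "moments",
                             transform = "sqrt")
  expect_equal(f$v_error, 0.58, tolerance = 0.35)
})

test_that("sites and climate emulate a two-axis gradient", {
  sc <- simulate_sites_climate(n_pops = 19, noise_sd = 1e-4, seed = 6)
  pc <- climate_pca(sc$climate, k = 2)
  expect_gt(sum(pc$explained[1:2]), 99.5)
  d <- geographic_distances(sc$sites)
  # distances bounded by the box diagonal
  diag_km <- geographic_distances(data.frame(
    population_id = c("x", "y"),
    latitude = c(49.45, 49.75), longitude = c(5.90, 6.75)))["x", "y"]
  expect_lte(max(d), diag_km + 1e-9)
  expect_true(all(sc$sites$census_size >= 1))
  # default noise keeps two dominant axes
  sc2 <- simulate_sites_climate(n_pops = 19, seed = 6)
  pc2 <- climate_pca(sc2$climate, k = 2)
  expect_gt(sum(pc2$explained[1:2]), 80)
})

test_that("climate coupling induces quantitative isolation by distance", {
  # with coupling, population means follow the longitude gradient
  cfg <- default_trait_config()
  for (tr in names(cfg)) cfg[[tr]]$coupling <- 1.0
  sc <- simulate_sites_climate(seed = 21)
  sim <- simulate_traits(cfg, sites = sc$sites, seed = 21)
  pop_means <- tapply(sim$traits$diameter, sim$traits$population_id, mean)
  grad <- sc$sites$longitude[match(names(pop_means), sc$sites$population_id)]
  expect_gt(cor(pop_means, grad), 0.5)
})
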