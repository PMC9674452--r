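test_that("mixed-mating kinship weight is the selfing-weighted mean", {
  expect_equal(mixed_mating_theta(0.55), 0.3875)
  expect_equal(mixed_mating_theta(0), 0.25)
  expect_equal(mixed_mating_theta(1), 0.5)
  # monotone in the selfing fraction
  s <- seq(0, 1, 0.1)
  expect_true(all(diff(vapply(s, mixed_mating_theta, numeric(1))) > 0))
  expect_error(mixed_mating_theta(1.2))
})

test_that("heritability, evolvability, SD_A and Q_ST follow their definitions", {
  vc <- list(v_pop = 0, v_fam = 0.775, v_error = 1)
  th <- 0.3875
  expect_equal(heritability(vc, th), 1 / 1.775)
  expect_equal(additive_sd(vc, th), 1)
  expect_equal(evolvability(vc, th, trait_mean = 2), 0.5)
  expect_error(evolvability(vc, th, trait_mean = 0), "positive")
  vc0 <- list(v_pop = 0, v_fam = 0, v_error = 1)
  expect_equal(heritability(vc0, th), 0)
  expect_equal(evolvability(vc0, th, 2), 0)
  expect_equal(qst(list(v_pop = 0, v_fam = 1, v_error = 1), th), 0)
  expect_equal(qst(list(v_pop = 1, v_fam = 0.3875, v_error = 1), 0.3875), 0.5)
  expect_warning(q <- qst(list(v_pop = 0, v_fam = 0, v_error = 1), th),
                 "undefined")
  expect_true(is.nan(q))
})

test_that("REML and moments agree with the balanced expected-mean-squares oracle", {
  tt <- make_balanced_traits(10, 10, 5, v_pop = 2, v_fam = 1, v_error = 4,
                             seed = 8)
  orc <- oracle_balanced_ems(tt$y, tt$population_id, tt$family_id,
                             n_per_fam = 5, fam_per_pop = 10)
  mom <- fit_nested_components(tt, "y", method = "moments")
  expect_equal(mom$v_pop, orc$v_pop, tolerance = 1e-10)
  expect_equal(mom$v_fam, orc$v_fam, tolerance = 1e-10)
  expect_equal(mom$v_error, orc$v_error, tolerance = 1e-10)
  reml <- fit_nested_components(tt, "y", method = "reml")
  # balanced interior case: REML coincides with the ANOVA estimator
  expect_equal(reml$v_pop, orc$v_pop, tolerance = 1e-3)
  expect_equal(reml$v_fam, orc$v_fam, tolerance = 1e-3)
  expect_equal(reml$v_error, orc$v_error, tolerance = 1e-3)
})

test_that("REML recovers generating variance components on a balanced design", {
  truth <- c(v_pop = 2, v_fam = 1, v_error = 4)
  est <- sapply(1:5, function(s) {
    tt <- make_balanced_traits(10, 10, 5, 2, 1, 4, seed = s)
    fit <- fit_nested_components(tt, "y")
    c(fit$v_pop, fit$v_fam, fit$v_error)
  })
  med <- apply(est, 1, median)
  expect_true(all(abs(med - truth) / truth < 0.15))
})

test_that("zero family effect yields a clamped near-zero V_fam", {
  ests <- sapply(1:6, function(s) {
    tt <- make_balanced_traits(6, 6, 5, v_pop = 1, v_fam = 0, v_error = 1,
                               seed = s)
    c(mom = fit_nested_components(tt, "y", method = "moments")$v_fam,
      reml = fit_nested_components(tt, "y", method = "reml")$v_fam)
  })
  expect_true(all(ests >= 0))          # clamped, never negative
  expect_lt(median(ests["mom", ]), 0.05)
  expect_lt(median(ests["reml", ]), 0.05)
})

test_that("sqrt transformation is applied before fitting", {
  tt <- make_balanced_traits(5, 5, 4, 1, 0.5, 1, grand_mean = 9, seed = 4)
  tt$counts <- round(pmax(tt$y, 0)^2)
  fit <- fit_nested_components(tt, "counts", transform = "sqrt")
  expect_lt(abs(fit$mean - mean(sqrt(tt$counts))), 1e-10)
  expect_error(fit_nested_components(
    transform(tt, counts = counts - 100), "counts", transform = "sqrt"),
    "negative")
})

test_that("Q_ST is invariant to affine trait rescaling", {
  tt <- make_balanced_traits(8, 6, 5, 1.5, 1, 2, seed = 10)
  th <- 0.3875
  q1 <- qst(fit_nested_components(tt, "y"), th)
  tt$y2 <- 3.7 * tt$y + 11
  q2 <- qst(fit_nested_components(tt, "y2"), th)
  expect_equal(q1, q2, tolerance = 1e-6)
})

test_that("jackknife CI is deterministic, covers 0 under no differentiation", {
  tt <- make_balanced_traits(8, 6, 5, v_pop = 0, v_fam = 1, v_error = 2,
                             seed = 12)
  th <- 0.3875
  jk1 <- qst_jackknife_ci(tt, "y", th)
  jk2 <- qst_jackknife_ci(tt, "y", th)
  expect_identical(jk1$ci, jk2$ci)
  expect_equal(jk1$df, 7)
  expect_lte(jk1$ci[1], 0.02)
  expect_length(jk1$pseudo_values, 8)
  expect_error(qst_jackknife_ci(tt[tt$population_id %in% c("p01", "p02"), ],
                                "y", th), ">= 3 populations")
})

test_that("per-population fits match the one-way expected-mean-squares oracle", {
  set.seed(21)
  # balanced one-way fixture: 5 families x 4 plants in one population
  y <- rep(rnorm(5, 0, 2), each = 4) + rnorm(20, 0, 1) + 10
  tt <- data.frame(plant_id = paste0("pl", 1:20),
                   population_id = "p1",
                   family_id = rep(paste0("f", 1:5), each = 4),
                   y = y, stringsAsFactors = FALSE)
  fm <- tapply(y, tt$family_id, mean)
  ms_fam <- 4 * sum((fm - mean(y))^2) / 4
  ms_err <- sum((y - fm[tt$family_id])^2) / 15
  v_fam_oracle <- (ms_fam - ms_err) / 4
  tt2 <- rbind(tt, transform(tt, population_id = "p2",
                             family_id = paste0("b", family_id),
                             plant_id = paste0("q", plant_id)))
  res <- per_population_quantgen(tt2, "y", 0.3875, method = "moments")
  expect_equal(res$v_fam[res$population == "p1"], max(v_fam_oracle, 0),
               tolerance = 1e-10)
  expect_equal(res$v_error[res$population == "p1"], ms_err, tolerance = 1e-10)
})

test_that("per-population evolvability tracks the generating family variance", {
  # gradient of V_fam across populations: estimated CV_genetic should rank
  # populations correctly
  set.seed(31)
  v_true <- seq(0.2, 3, length.out = 10)
  rows <- lapply(seq_along(v_true), function(i) {
    tt <- make_balanced_traits(1, 12, 6, 0, v_true[i], 1, grand_mean = 10,
                               seed = 100 + i)
    tt$population_id <- sprintf("p%02d", i)
    tt$family_id <- paste0(tt$population_id, tt$family_id)
    tt
  })
  tt <- do.call(rbind, rows)
  res <- per_population_quantgen(tt, "y", 0.3875)
  rho <- cor(v_true[match(res$population, sprintf("p%02d", 1:10))],
             res$cv_genetic, method = "spearman")
  expect_gt(rho, 0.7)
  # populations with < 2 families are omitted with a warning
  solo <- data.frame(plant_id = "x", population_id = "solo",
                     family_id = "sf", y = 1)
  expect_warning(res2 <- per_population_quantgen(rbind(tt, solo), "y", 0.3875),
                 "omitting")
  expect_false("solo" %in% res2$population)
})

test_that("quantgen_summary assembles global, jackknife and per-population views", {
  sim <- simulate_traits(n_pops = 6, families_per_pop = 6,
                         plants_per_family = 5, seed = 41)
  qs <- quantgen_summary(sim$traits,
                         c(diameter = "none", leaf_width = "none",
                           flowers = "sqrt"))
  expect_equal(qs$theta, 0.3875)
  expect_equal(nrow(qs$global), 3)
  expect_true(all(qs$global$h2 >= 0 & qs$global$h2 <= 1))
  expect_true(all(qs$global$qst >= 0 & qs$global$qst <= 1))
  expect_named(qs$per_population, c("diameter", "leaf_width", "flowers"))
})
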