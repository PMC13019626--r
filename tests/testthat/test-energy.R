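two_atom_conformer <- function(d) {
  as_conformer(tibble::tibble(
    res_index = c(0L, 4L), res_name = "UNK", atom_name = c("X1", "X2"),
    element = "C", mass = 12, x = c(0, d), y = 0, z = 0, is_cap = FALSE),
    validate = FALSE)
}

test_that("soft-sphere score follows its overlap formula", {
  radii <- c(C = 1)
  # at exact contact distance: zero
  expect_equal(soft_sphere_score(two_atom_conformer(2), radii), 0)
  expect_equal(soft_sphere_score(two_atom_conformer(2.5), radii), 0)
  # unit radii at distance 1: overlap 1 of 2 -> (1/2)^2 * scale
  expect_equal(soft_sphere_score(two_atom_conformer(1), radii), 0.25)
  expect_equal(soft_sphere_score(two_atom_conformer(1), radii, scale = 7),
               7 * 0.25)
  expect_error(soft_sphere_score(two_atom_conformer(1), radii = c(N = 1)),
               "radius for element")
})

test_that("soft-sphere score equals a naive double-loop oracle with bonded exclusions", {
  conf <- random_conformer(seed = 12)
  # bend the conformer into clashes by compressing coordinates
  squeezed <- conf
  squeezed$x <- squeezed$x * 0.55
  squeezed$y <- squeezed$y * 0.55
  squeezed$z <- squeezed$z * 0.55
  got <- soft_sphere_score(squeezed)
  excl <- peptide_exclusions(squeezed)
  want <- naive_soft_sphere(coords(squeezed), squeezed$element, excl,
                            c(H = 1.0, C = 1.5, N = 1.35, O = 1.3,
                              S = 1.6, P = 1.6))
  expect_gt(got, 0)
  expect_equal(got, want, tolerance = 1e-12)
  # directly bonded and 1-3/1-4 pairs are excluded: an open coil conformer
  # scores exactly 0 despite its short bonded contacts
  expect_equal(soft_sphere_score(random_conformer(seed = 5)), 0)
})

test_that("log-normal fit recovers hand-computed log moments", {
  # two tight value groups padded to 10 distinct values, shift forced to 0
  x <- c(2, 8, 2 + 1e-4 * (1:4), 8 - 1e-4 * (1:4))
  fit <- fit_lognormal(x, shift = 0)
  expect_equal(fit$mu, mean(log(x)), tolerance = 1e-12)
  expect_equal(fit$sigma, sqrt(mean((log(x) - mean(log(x)))^2)),
               tolerance = 1e-12)
  expect_equal(fit$n_fitted, 10L)
  expect_error(fit_lognormal(1:9), "at least 10")
  expect_error(fit_lognormal(rep(1, 20)), "at least 10")
})

test_that("log-normal fit matches Normal(0,1) logs at large n", {
  x <- with_seed(9L, exp(rnorm(1e5)))
  fit <- fit_lognormal(x, shift = 0)
  expect_lt(abs(fit$mu), 3 / sqrt(1e5))
  expect_lt(abs(fit$sigma - 1), 3 / sqrt(2e5))
  # cross-check against the MASS maximum-likelihood fit
  ml <- MASS::fitdistr(x, "lognormal")
  expect_equal(fit$mu, unname(ml$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(fit$sigma, unname(ml$estimate["sdlog"]), tolerance = 1e-6)
})

test_that("coverage cutoff equals the closed-form log-normal quantile", {
  fit <- structure(list(mu = 0, sigma = 1, shift = 0, n_fitted = 100L),
                   class = "erf_lognormal")
  expect_equal(coverage_cutoff(fit, 0.5), 1) # the median, exp(mu)
  expect_equal(coverage_cutoff(fit, 0.8), exp(qnorm(0.8)), tolerance = 1e-12)
  expect_equal(coverage_cutoff(fit, 0.8), 2.3200, tolerance = 1e-4)
  # monotone in coverage and in sigma
  covs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(covs, coverage_cutoff, numeric(1),
                              fit = fit)) > 0))
  fit2 <- fit; fit2$sigma <- 2
  expect_gt(coverage_cutoff(fit2, 0.8), coverage_cutoff(fit, 0.8))
  fit3 <- fit; fit3$shift <- 5
  expect_equal(coverage_cutoff(fit3, 0.5), 6)
  expect_error(coverage_cutoff(fit, 1))
})

test_that("gating retains exactly the sub-threshold conformers", {
  ens <- as_ensemble(lapply(1:5, function(i) random_conformer(seed = i)))
  scores <- c(3, 1, 4, 1.5, 9)
  gated <- gate_ensemble(ens, scores, 3)
  expect_equal(n_conformers(gated), sum(scores <= 3))
  expect_equal(gated$weights, rep(1 / 3, 3))
  expect_equal(gated$energies, scores[scores <= 3])
  rep_ <- attr(gated, "gate_report")
  expect_equal(rep_$retention, 3 / 5)
  # threshold = Inf is the identity on membership
  expect_equal(n_conformers(gate_ensemble(ens, scores, Inf)), 5L)
  # threshold = min keeps exactly the argmin set
  expect_equal(n_conformers(gate_ensemble(ens, scores, min(scores))), 1L)
  expect_error(gate_ensemble(ens, scores, 0.5), "no conformer")
  expect_error(gate_ensemble(ens, scores[-1], 3), "length")
})

test_that("realized retention approaches the nominal coverage on log-normal scores", {
  n <- 1e4
  scores <- with_seed(31L, rlnorm(n, meanlog = 2, sdlog = 0.7))
  fit <- fit_lognormal(scores)
  cut <- coverage_cutoff(fit, 0.8)
  retention <- mean(scores <= cut)
  expect_lt(abs(retention - 0.8), 4 * sqrt(0.8 * 0.2 / n))
})

test_that("refinement monotonically decreases the clash score", {
  # clash-free conformer is returned unchanged
  conf <- random_conformer(seed = 5)
  expect_equal(soft_sphere_score(conf), 0)
  out <- refine(conf)
  expect_identical(coords(out), coords(conf))

  # two overlapping free atoms separate
  clash <- two_atom_conformer(1.2)
  relaxed <- refine(clash, radii = c(C = 1), n_steps = 20)
  expect_lt(soft_sphere_score(relaxed, c(C = 1)),
            soft_sphere_score(clash, c(C = 1)))
  # second call from the relaxed state never increases the score
  again <- refine(relaxed, radii = c(C = 1))
  expect_lte(soft_sphere_score(again, c(C = 1)),
             soft_sphere_score(relaxed, c(C = 1)))

  # squeezed peptide: score trace is non-increasing, displacement bounded
  squeezed <- conf
  squeezed$x <- squeezed$x * 0.6
  squeezed$y <- squeezed$y * 0.6
  squeezed$z <- squeezed$z * 0.6
  ref <- refine(squeezed, n_steps = 20, max_step = 0.1)
  trace <- attr(ref, "refine_report")$scores
  expect_true(all(diff(trace) <= 1e-12))
  expect_lte(max(abs(coords(ref) - coords(squeezed))), 20 * 0.1 + 1e-9)

  # a custom scorer goes through the finite-difference path
  ref2 <- refine(two_atom_conformer(1.0), n_steps = 5,
                 scorer = function(cf) {
                   d <- sqrt(sum((c(cf$x[1], cf$y[1], cf$z[1]) -
                                    c(cf$x[2], cf$y[2], cf$z[2]))^2))
                   max(0, 2 - d)^2
                 })
  expect_gt(sqrt(sum((coords(ref2)[1, ] - coords(ref2)[2, ])^2)), 1.0)
})

test_that("ensemble refinement matches per-conformer refinement", {
  confs <- lapply(1:3, function(i) {
    cf <- random_conformer(seed = i + 50)
    cf$x <- cf$x * 0.6; cf$y <- cf$y * 0.6; cf$z <- cf$z * 0.6
    cf
  })
  ens <- refine_ensemble(as_ensemble(confs), n_steps = 10)
  for (i in 1:3) {
    solo <- refine(confs[[i]], n_steps = 10)
    expect_equal(coords(get_conformer(ens, i)), coords(solo),
                 tolerance = 1e-12)
    expect_equal(ens$energies[i], soft_sphere_score(solo), tolerance = 1e-12)
  }
})
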