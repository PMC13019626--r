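#' Define a restraint-reweighting problem
#'
#' Bundles the per-conformer observable matrix, the experimental targets and
#' uncertainties, the prior weights and the regularisation strength theta.
#' Larger theta means stronger adherence to the prior ensemble; the
#' protocol default is theta = 0.1.
#'
#' @param M Conformer x observable matrix of back-calculated values.
#' @param exp_values Experimental value per observable (length `ncol(M)`).
#' @param sigma Positive uncertainty per observable (same units as `M`).
#' @param prior Prior weights (uniform by default; normalised).
#' @param theta Regularisation strength (> 0).
#' @return List of class `erf_problem`.
#' @export
reweight_problem <- function(M, exp_values, sigma, prior = NULL,
                             theta = 0.1) {
  M <- as.matrix(M)
  stopifnot(length(exp_values) == ncol(M), length(sigma) == ncol(M),
            all(sigma > 0), theta > 0, all(is.finite(M)),
            all(is.finite(exp_values)))
  if (is.null(prior)) prior <- rep(1 / nrow(M), nrow(M))
  stopifnot(length(prior) == nrow(M), all(prior >= 0), sum(prior) > 0)
  prior <- prior / sum(prior)
  structure(list(M = M, exp_values = as.numeric(exp_values),
                 sigma = as.numeric(sigma), prior = prior, theta = theta),
            class = "erf_problem")
}

#' Posterior weights implied by restraint strengths
#'
#' A hypothetical harmonically restrained ensemble: conformer i gets weight
#' `w_i(k) propto w0_i * exp(-1/2 * sum_j k_j * ((M_ij - o_j)/sigma_j)^2)`,
#' normalised (overflow-guarded by max subtraction). `k = 0` returns the
#' prior.
#'
#' @param k Non-negative restraint strength per observable.
#' @param problem An `erf_problem`.
#' @return Normalised weight vector.
#' @export
restraint_weights <- function(k, problem) {
  stopifnot(length(k) == ncol(problem$M), all(k >= 0))
  Z2 <- sweep(sweep(problem$M, 2, problem$exp_values), 2, problem$sigma, "/")^2
  logw <- log(problem$prior) - 0.5 * as.vector(Z2 %*% k)
  logw <- logw - max(logw[is.finite(logw)])
  w <- exp(logw)
  w / sum(w)
}

#' @noRd
weights_from_z2 <- function(k, Z2, prior) {
  logw <- log(prior) - 0.5 * as.vector(Z2 %*% k)
  logw <- logw - max(logw[is.finite(logw)])
  w <- exp(logw)
  w / sum(w)
}

#' @noRd
reweight_objective <- function(k, problem, Z2 = NULL) {
  w <- if (is.null(Z2)) restraint_weights(k, problem) else
    weights_from_z2(k, Z2, problem$prior)
  avg <- as.vector(w %*% problem$M)
  z <- (avg - problem$exp_values) / problem$sigma
  chi2 <- sum(z^2)
  kl <- kl_divergence(w, problem$prior)
  list(value = 0.5 * chi2 + problem$theta * kl, chi2 = chi2, kl = kl, w = w,
       avg = avg)
}

#' Solve the theta-regularised reweighting problem
#'
#' Minimises `L(k) = 1/2 * chi^2(w(k)) + theta * KL(w(k) || w0)` over
#' restraint strengths `k >= 0`, where `w(k)` comes from
#' [restraint_weights()] and chi^2 compares posterior ensemble averages
#' with the experimental values. Deterministic: bound-constrained
#' quasi-Newton (L-BFGS-B) on `log(1 + k)` from a fixed fan of starting
#' points (k = 0 plus a few deterministic magnitudes, including a
#' data-adaptive scale), keeping the best optimum; the objective is not
#' convex in k, so the multi-start guards against boundary local minima.
#' Objective tolerance 1e-8, no stochastic steps.
#'
#' @param problem An `erf_problem`.
#' @param max_iter Optimiser iteration cap.
#' @return Object of class `erf_reweight`: `weights`, `k`, `objective`,
#'   `chi2` (also per-observable averages), `kl`, `kish`, `preservation`,
#'   `converged`, `theta`, and the `problem`.
#' @export
solve_reweight <- function(problem, max_iter = 500L) {
  stopifnot(inherits(problem, "erf_problem"))
  p <- ncol(problem$M)
  # the residual matrix is fixed over the optimisation; cache it
  Z2 <- sweep(sweep(problem$M, 2, problem$exp_values), 2, problem$sigma,
              "/")^2
  # pmax guards the finite-difference gradient, which can probe a hair
  # below the box constraint
  fn <- function(u) reweight_objective(pmax(expm1(u), 0), problem, Z2)$value
  k_scale <- 1 / pmax(as.vector(problem$prior %*% Z2), 1e-8)
  starts <- list(rep(0, p), rep(0.1, p), rep(1, p), rep(10, p),
                 k_scale, 10 * k_scale)
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(log1p(s), fn, method = "L-BFGS-B",
                        lower = rep(0, p), upper = rep(log1p(1e6), p),
                        control = list(maxit = max_iter,
                                       factr = 1e-8 / .Machine$double.eps))
    if (is.null(best) || opt$value < best$value - 1e-12) best <- opt
  }
  opt <- best
  k <- expm1(opt$par)
  at <- reweight_objective(k, problem)
  # k = 0 is always admissible; never return anything worse than the prior
  at0 <- reweight_objective(rep(0, p), problem)
  if (at0$value < at$value) { k <- rep(0, p); at <- at0 }
  structure(list(weights = at$w, k = k, objective = at$value,
                 chi2 = at$chi2, averages = at$avg, kl = at$kl,
                 kish = kish_ess(at$w),
                 preservation = ensemble_preservation(problem$prior, at$w),
                 converged = opt$convergence == 0,
                 theta = problem$theta, problem = problem),
            class = "erf_reweight")
}

#' Kish effective sample size of a weight vector
#'
#' `ESS = (sum w)^2 / sum(w^2)`; the ratio divides by the number of
#' weights. Uniform weights give ESS = N (ratio 1); a one-hot vector gives
#' ESS = 1 (ratio 1/N).
#'
#' @param weights Non-negative weights, not all zero.
#' @return List with `ess` and `ratio`.
#' @export
kish_ess <- function(weights) {
  stopifnot(all(weights >= 0))
  s <- sum(weights)
  if (s <= 0) stop("all weights are zero", call. = FALSE)
  ess <- s^2 / sum(weights^2)
  list(ess = ess, ratio = ess / length(weights))
}

#' Ensemble preservation between prior and posterior weights
#'
#' Conformers whose weight increased contribute 100%; conformers whose
#' weight decreased contribute the remaining fraction `w_i / w0_i`. The
#' mean over conformers (prior-zero conformers excluded) is the
#' preservation; 100% means identical ensembles.
#'
#' @param prior,posterior Normalised weight vectors of equal length.
#' @return Percentage in (0, 100].
#' @export
ensemble_preservation <- function(prior, posterior) {
  if (length(prior) != length(posterior)) {
    stop("prior and posterior must have equal length", call. = FALSE)
  }
  keep <- prior > 0
  100 * mean(pmin(1, posterior[keep] / prior[keep]))
}

#' Kullback-Leibler divergence between weight vectors
#'
#' `sum w_i log(w_i / w0_i)` in nats, with `0 log 0 = 0`. Posterior mass on
#' a prior-zero conformer is an error (not absolutely continuous).
#'
#' @param posterior,prior Normalised weight vectors.
#' @return Divergence in nats (>= 0 up to rounding).
#' @export
kl_divergence <- function(posterior, prior) {
  stopifnot(length(posterior) == length(prior))
  bad <- posterior > 0 & prior <= 0
  if (any(bad)) {
    stop("posterior has mass where the prior is zero", call. = FALSE)
  }
  i <- posterior > 0
  sum(posterior[i] * log(posterior[i] / prior[i]))
}

#' Scan the regularisation strength theta
#'
#' Re-solves the problem on a grid of theta values and tabulates the
#' agreement/preservation trade-off, mirroring the overfitting check used
#' to pick theta: as theta decreases, chi^2 falls and the KL divergence
#' rises, and a value is chosen at which a considerable share of the prior
#' ensemble still contributes.
#'
#' @param problem An `erf_problem` (its own theta is ignored).
#' @param thetas Numeric grid of theta values.
#' @return Tibble with `theta`, `chi2`, `kl`, `kish_ess`, `kish_ratio`,
#'   `preservation`, `converged`.
#' @export
theta_scan <- function(problem, thetas = 10^seq(-3, 2, by = 0.5)) {
  purrr::map_dfr(thetas, function(th) {
    pr <- problem
    pr$theta <- th
    fit <- solve_reweight(pr)
    tibble::tibble(theta = th, chi2 = fit$chi2, kl = fit$kl,
                   kish_ess = fit$kish$ess, kish_ratio = fit$kish$ratio,
                   preservation = fit$preservation,
                   converged = fit$converged)
  })
}

#' @export
print.erf_reweight <- function(x, ...) {
  cat(sprintf(
    "<erf_reweight> theta = %g | chi2 = %.4g | KL = %.4g nats\n",
    x$theta, x$chi2, x$kl))
  cat(sprintf("  Kish ESS %.1f / %d (ratio %.3f), preservation %.1f%%%s\n",
              x$kish$ess, length(x$weights), x$kish$ratio, x$preservation,
              if (x$converged) "" else " [optimizer not converged]"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-observable summary of a reweighting fit
#'
#' @param x An `erf_reweight`.
#' @param ... Unused.
#' @return Tibble with one row per observable: experimental value, sigma,
#'   prior and posterior ensemble means, and the optimised restraint
#'   strength `k`.
#' @export
tidy.erf_reweight <- function(x, ...) {
  pr <- x$problem
  tibble::tibble(
    observable = seq_len(ncol(pr$M)),
    experimental = pr$exp_values,
    sigma = pr$sigma,
    prior_mean = as.vector(pr$prior %*% pr$M),
    posterior_mean = x$averages,
    k = x$k
  )
}

#' One-row diagnostics of a reweighting fit
#' @param x An `erf_reweight`.
#' @param ... Unused.
#' @return One-row tibble: `theta`, `n_conformers`, `n_observables`,
#'   `objective`, `chi2`, `kl`, `kish_ess`, `kish_ratio`, `preservation`,
#'   `converged`.
#' @export
glance.erf_reweight <- function(x, ...) {
  tibble::tibble(
    theta = x$theta,
    n_conformers = length(x$weights),
    n_observables = length(x$k),
    objective = x$objective,
    chi2 = x$chi2,
    kl = x$kl,
    kish_ess = x$kish$ess,
    kish_ratio = x$kish$ratio,
    preservation = x$preservation,
    converged = x$converged
  )
}
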