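## soft-sphere radii (Angstrom), deliberately below full van der Waals so
## hydrogen-bond-range contacts are not penalised
SOFT_RADII <- c(H = 1.0, C = 1.5, N = 1.35, O = 1.3, S = 1.6, P = 1.6)

#' @noRd
bonds_from_template <- function(tpl) {
  key <- paste(tpl$res_index, tpl$atom_name)
  at <- function(ri, name) match(paste(ri, name), key)
  pairs <- list()
  link <- function(i, j) {
    if (!is.na(i) && !is.na(j)) pairs[[length(pairs) + 1L]] <<- c(i, j)
  }
  for (ri in unique(tpl$res_index)) {
    res <- tpl$res_name[tpl$res_index == ri][1]
    if (res == "ACE") {
      link(at(ri, "CH3"), at(ri, "C")); link(at(ri, "C"), at(ri, "O"))
    } else if (res == "NME") {
      link(at(ri, "N"), at(ri, "H")); link(at(ri, "N"), at(ri, "CH3"))
    } else {
      link(at(ri, "N"), at(ri, "H")); link(at(ri, "N"), at(ri, "CA"))
      link(at(ri, "CA"), at(ri, "C")); link(at(ri, "CA"), at(ri, "CB"))
      link(at(ri, "C"), at(ri, "O"))
    }
    link(at(ri, "C"), at(ri + 1L, "N"))
  }
  do.call(rbind, pairs)
}

## pairs within `depth` bonds (plus self) as a logical exclusion matrix
#' @noRd
topological_exclusions <- function(tpl, depth = 3L) {
  n <- nrow(tpl)
  A <- matrix(0, n, n)
  b <- bonds_from_template(tpl)
  A[b] <- 1; A[b[, 2:1, drop = FALSE]] <- 1
  reach <- A
  P <- A
  for (k in seq_len(depth - 1L)) {
    P <- P %*% A
    reach <- reach + P
  }
  excl <- reach > 0
  diag(excl) <- TRUE
  excl
}

## precomputed machinery for scoring many conformers on one roster:
## indices into the dist() vector plus contact distances for included pairs
#' @noRd
soft_sphere_context <- function(tpl, radii = SOFT_RADII, depth = 3L) {
  n <- nrow(tpl)
  r <- radii[tpl$element]
  if (anyNA(r)) {
    stop(sprintf("no soft-sphere radius for element '%s'",
                 tpl$element[which(is.na(r))[1]]), call. = FALSE)
  }
  excl <- topological_exclusions(tpl, depth)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  keep <- !excl[cbind(ii, jj)]
  list(n = n, i = ii[keep], j = jj[keep],
       didx = which(keep),                     # index into dist() vector
       contact = r[ii[keep]] + r[jj[keep]])
}

#' @noRd
score_xyz <- function(xyz, ctx, scale = 1) {
  d <- as.vector(stats::dist(xyz))[ctx$didx]
  ov <- (ctx$contact - d) / ctx$contact
  sum(ov[ov > 0]^2) * scale
}

#' Soft-sphere clash score of a conformer
#'
#' Sums `((r_i + r_j - d) / (r_i + r_j))^2` over all atom pairs closer than
#' their contact distance, excluding pairs separated by at most three bonds;
#' clash-free conformers score exactly 0. Lower is better. This is the
#' built-in pluggable energy backend; externally computed per-conformer
#' scores (e.g. force-field energies) can be supplied to [gate_ensemble()]
#' instead.
#'
#' @param conf Conformer atom table.
#' @param radii Named per-element radii (Angstrom).
#' @param scale Multiplicative constant on the summed penalty.
#' @param depth Bond-separation depth excluded from scoring.
#' @return Non-negative scalar score.
#' @export
soft_sphere_score <- function(conf, radii = SOFT_RADII, scale = 1,
                              depth = 3L) {
  ctx <- soft_sphere_context(conf, radii, depth)
  score_xyz(coords(conf), ctx, scale)
}

#' Score every conformer of an ensemble
#' @param ens An `erf_ensemble`.
#' @inheritParams soft_sphere_score
#' @return Numeric vector of scores (one per conformer).
#' @export
score_ensemble <- function(ens, radii = SOFT_RADII, scale = 1, depth = 3L) {
  ctx <- soft_sphere_context(ens$template, radii, depth)
  vapply(seq_len(n_conformers(ens)), function(m) {
    score_xyz(matrix(ens$xyz[m, ], ncol = 3L, byrow = TRUE), ctx, scale)
  }, numeric(1))
}

#' Fit a log-normal distribution to conformer scores
#'
#' Scores are shifted by `min(scores) - epsilon` (epsilon a small fraction of
#' the score range) so their logs are finite, then mu and sigma are the mean
#' and population standard deviation of the logs (the maximum-likelihood
#' log-normal fit).
#'
#' @param scores Numeric vector (at least 10 distinct values).
#' @param shift Optional fixed shift overriding the convention above.
#' @param eps_fraction Fraction of the score range used for the shift.
#' @return Object of class `erf_lognormal`: `mu`, `sigma`, `shift`,
#'   `n_fitted`.
#' @export
fit_lognormal <- function(scores, shift = NULL, eps_fraction = 1e-6) {
  scores <- scores[is.finite(scores)]
  if (length(unique(scores)) < 10L) {
    stop("need at least 10 distinct finite scores to fit a log-normal",
         call. = FALSE)
  }
  rng <- max(scores) - min(scores)
  if (rng <= 0) stop("degenerate score distribution (all equal)", call. = FALSE)
  if (is.null(shift)) shift <- min(scores) - eps_fraction * rng
  arg <- scores - shift
  if (any(arg <= 0)) {
    stop("shift leaves non-positive arguments; lower the shift", call. = FALSE)
  }
  lg <- log(arg)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  if (sigma <= 0) stop("degenerate log-score distribution", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, shift = shift,
                 n_fitted = length(scores)),
            class = "erf_lognormal")
}

#' Energy threshold covering a fraction of the fitted log-normal
#'
#' The cutoff is the score below which the requested fraction of the fitted
#' log-normal mass lies: `shift + exp(mu + sigma * qnorm(coverage))`. The
#' default 0.8 keeps the gated ensemble broad while removing the
#' high-energy tail.
#'
#' @param fit An `erf_lognormal` fit.
#' @param coverage Fraction in (0, 1).
#' @return Scalar score threshold.
#' @export
coverage_cutoff <- function(fit, coverage = 0.8) {
  stopifnot(inherits(fit, "erf_lognormal"), coverage > 0, coverage < 1)
  fit$shift + exp(fit$mu + fit$sigma * stats::qnorm(coverage))
}

#' Gate an ensemble at a score threshold
#'
#' Retains conformers with `score <= threshold`, re-uniformises the weights
#' over the survivors, and records a gate report (`attr(result,
#' "gate_report")`: threshold, counts, retention fraction). Provenance and
#' the retained scores travel with the result.
#'
#' @param ens An `erf_ensemble`.
#' @param scores One score per conformer (lower = better).
#' @param threshold Score cutoff, e.g. from [coverage_cutoff()].
#' @return The gated `erf_ensemble`.
#' @export
gate_ensemble <- function(ens, scores, threshold) {
  stopifnot(length(scores) == n_conformers(ens))
  keep <- which(scores <= threshold)
  if (!length(keep)) stop("no conformer survives the energy gate", call. = FALSE)
  out <- new_ensemble(ens$template, ens$xyz[keep, , drop = FALSE],
                      weights = rep(1 / length(keep), length(keep)),
                      energies = scores[keep],
                      provenance = if (!is.null(ens$provenance))
                        ens$provenance[keep, , drop = FALSE])
  attr(out, "gate_report") <- list(threshold = threshold,
                                   n_in = n_conformers(ens),
                                   n_out = length(keep),
                                   retention = length(keep) / n_conformers(ens))
  out
}

#' @noRd
soft_sphere_gradient <- function(xyz, ctx, scale = 1) {
  d <- as.vector(stats::dist(xyz))[ctx$didx]
  ov <- (ctx$contact - d) / ctx$contact
  hit <- which(ov > 0 & d > 1e-12)
  g <- matrix(0, nrow(xyz), 3L)
  if (length(hit)) {
    i <- ctx$i[hit]; j <- ctx$j[hit]
    coef <- -2 * ov[hit] / ctx$contact[hit] * scale  # d score / d distance
    contrib <- coef * (xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]) / d[hit]
    for (k in 1:3) {
      gi <- rowsum(contrib[, k], i)
      gj <- rowsum(contrib[, k], j)
      g[as.integer(rownames(gi)), k] <- g[as.integer(rownames(gi)), k] + gi
      g[as.integer(rownames(gj)), k] <- g[as.integer(rownames(gj)), k] - gj
    }
  }
  g
}

#' Relax a conformer by bounded steepest descent on its clash score
#'
#' At most `n_steps` descent steps with backtracking line search; each step
#' moves no atom more than `max_step` Angstrom. The returned score never
#' exceeds the input score, and a clash-free conformer (score 0) is returned
#' unchanged. With the default built-in scorer the gradient is analytic; a
#' custom `scorer` function is differentiated by central finite differences.
#'
#' @param conf Conformer atom table.
#' @param n_steps Maximum number of descent steps (default 20).
#' @param max_step Per-atom per-step displacement cap (Angstrom).
#' @param scorer Optional function `conformer -> scalar`; default soft-sphere.
#' @param radii,scale Soft-sphere parameters for the default scorer.
#' @return The relaxed conformer; `attr(, "refine_report")` holds the score
#'   trajectory.
#' @export
refine <- function(conf, n_steps = 20L, max_step = 0.1, scorer = NULL,
                   radii = SOFT_RADII, scale = 1) {
  xyz <- coords(conf)
  if (is.null(scorer)) {
    ctx <- soft_sphere_context(conf, radii)
    fscore <- function(x) score_xyz(x, ctx, scale)
    fgrad <- function(x) soft_sphere_gradient(x, ctx, scale)
  } else {
    fscore <- function(x) scorer(set_coords(conf, x))
    fgrad <- function(x) {
      h <- 1e-5
      g <- matrix(0, nrow(x), 3L)
      for (a in seq_len(nrow(x))) for (k in 1:3) {
        xp <- x; xp[a, k] <- xp[a, k] + h
        xm <- x; xm[a, k] <- xm[a, k] - h
        g[a, k] <- (fscore(xp) - fscore(xm)) / (2 * h)
      }
      g
    }
  }
  s <- fscore(xyz)
  trace <- s
  for (step in seq_len(n_steps)) {
    if (s <= 0) break
    g <- fgrad(xyz)
    gmax <- max(sqrt(rowSums(g^2)))
    if (gmax < 1e-12) break
    dir <- -g * (max_step / gmax)  # largest atom moves exactly max_step
    alpha <- 1
    improved <- FALSE
    while (alpha > 1e-4) {
      trial <- xyz + alpha * dir
      st <- fscore(trial)
      if (st < s) {
        xyz <- trial; s <- st; improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    trace <- c(trace, s)
    if (!improved) break
  }
  out <- set_coords(conf, xyz)
  attr(out, "refine_report") <- list(scores = trace, steps = length(trace) - 1L)
  out
}

#' Relax every conformer of an ensemble in place
#' @param ens An `erf_ensemble`.
#' @inheritParams refine
#' @return The ensemble with refined coordinates and updated energies.
#' @export
refine_ensemble <- function(ens, n_steps = 20L, max_step = 0.1,
                            radii = SOFT_RADII, scale = 1) {
  ctx <- soft_sphere_context(ens$template, radii)
  energies <- numeric(n_conformers(ens))
  for (m in seq_len(n_conformers(ens))) {
    xyz <- matrix(ens$xyz[m, ], ncol = 3L, byrow = TRUE)
    s <- score_xyz(xyz, ctx, scale)
    for (step in seq_len(n_steps)) {
      if (s <= 0) break
      g <- soft_sphere_gradient(xyz, ctx, scale)
      gmax <- max(sqrt(rowSums(g^2)))
      if (gmax < 1e-12) break
      dir <- -g * (max_step / gmax)
      alpha <- 1
      improved <- FALSE
      while (alpha > 1e-4) {
        trial <- xyz + alpha * dir
        st <- score_xyz(trial, ctx, scale)
        if (st < s) { xyz <- trial; s <- st; improved <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!improved) break
    }
    ens$xyz[m, ] <- as.vector(t(xyz))
    energies[m] <- s
  }
  ens$energies <- energies
  ens
}
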