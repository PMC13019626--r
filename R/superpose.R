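#' Optimal rigid-body superposition of two point sets
#'
#' Least-squares (Kabsch) superposition of `Q` onto `P`: returns the proper
#' rotation `R` and translation `t` minimising the RMSD of `Q %*% R + t`
#' against `P`, together with that minimal RMSD.
#'
#' @param P,Q Matched `n x 3` coordinate matrices, `n >= 3`, not collinear.
#' @return List with `rotation` (3x3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom), and `apply(X)` transforming any
#'   coordinate matrix by the fitted rigid motion.
#' @examples
#' P <- matrix(rnorm(18), 6, 3)
#' fit <- superpose(P, P)
#' fit$rmsd  # 0
#' @export
superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  if (nrow(P) < 3L) stop("superposition needs at least 3 points", call. = FALSE)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  # collinearity check on either set
  if (min(svd(Pc)$d[2], svd(Qc)$d[2]) < 1e-9 * max(1, max(abs(Pc)), max(abs(Qc)))) {
    stop("degenerate (collinear) point set: superposition is ill-defined",
         call. = FALSE)
  }
  H <- crossprod(Qc, Pc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_ <- pbar - as.vector(qbar %*% R)
  rmsd <- sqrt(max(0, mean(rowSums((Pc - Qc %*% R)^2))))
  list(rotation = R, translation = t_, rmsd = rmsd,
       apply = function(X) sweep(as.matrix(X) %*% R, 2, t_, "+"))
}

#' @noRd
select_atoms <- function(tpl, atom_names = c("N", "CA", "C", "O", "CB"),
                         include_caps = FALSE) {
  sel <- tpl$atom_name %in% atom_names
  if (!include_caps) sel <- sel & !tpl$is_cap
  which(sel)
}

#' Pairwise similarity matrix for affinity propagation
#'
#' Similarity between conformers i and j is the negative squared
#' superposition RMSD (Angstrom^2) over the selected atoms; the diagonal is
#' set to the affinity-propagation preference. A frame `stride` subsamples
#' the conformer list (members 1, 1+stride, ...).
#'
#' @param ens An `erf_ensemble` (e.g. a fragment library).
#' @param atom_names Atom selection for the RMSD (caps excluded).
#' @param preference Diagonal value (the protocol's reference default
#'   is -30).
#' @param stride Keep every `stride`-th conformer.
#' @return List of class `erf_similarity`: `S` (square matrix), `members`
#'   (indices into the ensemble), `preference`.
#' @export
pairwise_similarity <- function(ens, atom_names = c("N", "CA", "C", "O", "CB"),
                                preference = -30, stride = 1L) {
  stopifnot(stride >= 1L)
  sel <- select_atoms(ens$template, atom_names)
  if (!length(sel)) stop("atom selection is empty", call. = FALSE)
  members <- seq(1L, n_conformers(ens), by = stride)
  m <- length(members)
  xyz <- lapply(members, function(i) {
    matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)[sel, , drop = FALSE]
  })
  S <- matrix(0, m, m)
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        r <- superpose(xyz[[i]], xyz[[j]])$rmsd
        S[i, j] <- S[j, i] <- -r^2
      }
    }
  }
  diag(S) <- preference
  structure(list(S = S, members = members, preference = preference),
            class = "erf_similarity")
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing with damping on a
#' similarity matrix whose diagonal holds the exemplar preference. Iteration
#' stops once the exemplar set is unchanged for `convergence_iter`
#' consecutive sweeps, or at `max_iter` (the result then reports
#' `converged = FALSE`). Ties in the final assignment go to the
#' lowest-index exemplar.
#'
#' @param S Square similarity matrix (or an `erf_similarity`).
#' @param damping Message damping factor in `[0.5, 1)`; default 0.9.
#' @param max_iter Maximum sweeps.
#' @param convergence_iter Sweeps of exemplar stability required.
#' @return List of class `erf_apcluster`: `exemplars` (indices into `S`),
#'   `labels` (exemplar index per member), `iterations`, `converged`.
#' @export
affinity_propagation <- function(S, damping = 0.9, max_iter = 1000L,
                                 convergence_iter = 50L) {
  members <- NULL
  if (inherits(S, "erf_similarity")) { members <- S$members; S <- S$S }
  S <- as.matrix(S)
  dimnames(S) <- NULL
  n <- nrow(S)
  if (n != ncol(S) || any(!is.finite(S))) {
    stop("similarity matrix must be square and finite", call. = FALSE)
  }
  stopifnot(damping >= 0.5, damping < 1, max_iter >= convergence_iter,
            convergence_iter >= 1L)
  if (n == 1L) {
    return(structure(list(exemplars = 1L, labels = 1L, iterations = 0L,
                          converged = TRUE, members = members),
                     class = "erf_apcluster"))
  }
  # tiny similarity jitter-free symmetric tie-break is not needed: assignment
  # tie-break below is deterministic (lowest exemplar index)
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  ex_prev <- integer(0)
  stable <- 0L
  it <- 0L
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), which1)] <- max2
    Rnew <- S - Rmax
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, ex_prev) && length(ex)) stable <- stable + 1L
    else stable <- 0L
    ex_prev <- ex
    if (stable >= convergence_iter) break
  }
  converged <- stable >= convergence_iter
  ex <- ex_prev
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  # deterministic assignment: best similarity, ties to lowest exemplar index
  labels <- vapply(seq_len(n), function(i) {
    if (i %in% ex) return(i)
    s <- S[i, ex]
    ex[which(s == max(s))[1]]
  }, integer(1))
  structure(list(exemplars = ex, labels = labels, iterations = it,
                 converged = converged, members = members),
            class = "erf_apcluster")
}

#' Reduce a fragment library to its affinity-propagation exemplars
#'
#' Computes the pairwise similarity over the clustering atom selection, runs
#' affinity propagation, and returns the sub-library of exemplar conformers
#' (provenance retained; deterministic given the settings). The defaults
#' (preference -30, damping 0.9) are the protocol's reference settings,
#' chosen to yield around 35 exemplars per fragment on the original data.
#'
#' @param lib An `erf_ensemble` fragment library.
#' @param preference Exemplar preference (diagonal of the similarity).
#' @param damping Message damping.
#' @param stride Frame stride applied before clustering.
#' @param atom_names RMSD atom selection.
#' @param max_iter,convergence_iter Iteration control.
#' @return The exemplar sub-library; `attr(, "clustering")` holds the
#'   `erf_apcluster` result.
#' @export
select_exemplars <- function(lib, preference = -30, damping = 0.9,
                             stride = 1L,
                             atom_names = c("N", "CA", "C", "O", "CB"),
                             max_iter = 1000L, convergence_iter = 50L) {
  stopifnot(n_conformers(lib) >= 1L)
  sim <- pairwise_similarity(lib, atom_names, preference, stride)
  cl <- affinity_propagation(sim, damping, max_iter, convergence_iter)
  keep <- sim$members[cl$exemplars]
  out <- subset_ensemble(lib, keep)
  out$fragment_index <- lib$fragment_index
  out$seed <- lib$seed
  attr(out, "clustering") <- cl
  out
}
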