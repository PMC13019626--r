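test_that("superposition recovers exact transforms and matches the quaternion oracle", {
  set.seed(101)
  P <- matrix(rnorm(18), 6, 3)
  # identity case
  fit <- superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # exact recovery of a known rigid motion
  ang <- 0.7
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% R, 2, c(1, -2, 3), "+")
  fit2 <- superpose(P, Q)
  expect_lt(fit2$rmsd, 1e-9)
  expect_lt(max(abs(fit2$apply(Q) - P)), 1e-9)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  # random pairs against Horn's quaternion method
  for (i in 1:50) {
    A <- matrix(rnorm(18), 6, 3)
    B <- matrix(rnorm(18), 6, 3)
    expect_lt(abs(superpose(A, B)$rmsd - horn_rmsd(A, B)), 1e-9)
  }
})

test_that("superposition rejects degenerate input and rotation is always proper", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line + 1), "collinear")
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  # reflection-prone case still yields a proper rotation
  set.seed(8)
  A <- matrix(rnorm(12), 4, 3)
  B <- A %*% diag(c(-1, 1, 1)) # mirrored
  expect_equal(det(superpose(A, B)$rotation), 1, tolerance = 1e-9)
})

test_that("superposition RMSD behaves as a pseudo-metric on conformers", {
  confs <- lapply(1:3, function(i) random_conformer(seed = 40 + i))
  sel <- which(confs[[1]]$atom_name %in% c("N", "CA", "C", "O", "CB") &
                 !confs[[1]]$is_cap)
  r <- function(i, j) superpose(coords(confs[[i]])[sel, ],
                                coords(confs[[j]])[sel, ])$rmsd
  expect_equal(r(1, 2), r(2, 1), tolerance = 1e-9)
  expect_equal(r(1, 1), 0, tolerance = 1e-9)
  expect_lte(r(1, 3), r(1, 2) + r(2, 3) + 1e-9)
})

test_that("similarity matrix is negative squared RMSD with preference diagonal", {
  lib <- as_ensemble(lapply(1:10, function(i) random_conformer(seed = i)))
  sim <- pairwise_similarity(lib, preference = -30)
  expect_equal(diag(sim$S), rep(-30, 10))
  expect_equal(sim$S, t(sim$S))
  # definition check on one off-diagonal entry
  sel <- select_atoms_for_test(lib$template)
  r12 <- superpose(matrix(lib$xyz[1, ], ncol = 3, byrow = TRUE)[sel, ],
                   matrix(lib$xyz[2, ], ncol = 3, byrow = TRUE)[sel, ])$rmsd
  expect_equal(sim$S[1, 2], -r12^2, tolerance = 1e-9)
  # identical conformers have similarity 0
  twin <- as_ensemble(list(get_conformer(lib, 1), get_conformer(lib, 1)))
  expect_equal(pairwise_similarity(twin, preference = -1)$S[1, 2], 0,
               tolerance = 1e-12)
  # stride subsamples frames 1, 5, 9
  sim4 <- pairwise_similarity(lib, stride = 4)
  expect_equal(dim(sim4$S), c(3L, 3L))
  expect_equal(sim4$members, c(1L, 5L, 9L))
  expect_error(pairwise_similarity(lib, atom_names = "XX"), "empty")
})

test_that("affinity propagation matches brute-force exemplar optimisation", {
  # two tight, well-separated pairs -> 2 exemplars, pairs intact
  pts <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  S <- -as.matrix(dist(pts))^2
  diag(S) <- median(S[upper.tri(S)])
  cl <- affinity_propagation(S, damping = 0.9)
  expect_true(cl$converged)
  expect_equal(length(cl$exemplars), 2L)
  expect_equal(cl$labels[1], cl$labels[2])
  expect_equal(cl$labels[3], cl$labels[4])
  # attains the brute-force optimum (exemplar identity within a tight pair
  # is a near-tie; the net similarity is what the optimum fixes)
  net <- sum(diag(S)[cl$exemplars]) +
    sum(S[cbind(1:4, cl$labels)][-cl$exemplars])
  bf <- ap_brute_force(S)$score
  expect_gte(net, bf - 1e-4 * abs(bf))

  # preference far above all similarities: everyone their own exemplar
  S2 <- -as.matrix(dist(pts))^2
  diag(S2) <- 100
  cl2 <- affinity_propagation(S2)
  expect_equal(sort(cl2$exemplars), 1:4)
  expect_equal(length(ap_brute_force(S2)$exemplars), 4L)

  # clustered <= 8-member instances: net similarity equals the exact
  # optimum (message passing is reliable in the separated-cluster regime)
  set.seed(77)
  for (case in 1:20) {
    S <- separated_instance()
    cl <- affinity_propagation(S)
    if (!cl$converged) next
    net <- sum(diag(S)[cl$exemplars]) +
      sum(S[cbind(seq_len(nrow(S)), cl$labels)][-cl$exemplars])
    # equality up to near-tie exemplar swaps within a cluster (relative
    # gaps ~1e-6 of the optimum); the cluster structure itself is exact
    bf <- ap_brute_force(S)$score
    expect_gte(net, bf - 1e-4 * abs(bf))
    expect_lte(net, bf + 1e-9)
  }
})

test_that("raising the preference never decreases the optimal exemplar count", {
  set.seed(5)
  x <- matrix(rnorm(12, sd = 2), 6, 2)
  D <- -as.matrix(dist(x))^2
  counts <- vapply(c(-50, -20, -5, -1, -0.1), function(pref) {
    S <- D; diag(S) <- pref
    length(ap_brute_force(S)$exemplars)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("exemplar selection is deterministic and collapses duplicates", {
  lib1 <- as_ensemble(list(random_conformer(seed = 1)))
  one <- select_exemplars(lib1)
  expect_equal(n_conformers(one), 1L)

  # many copies of one conformer plus one distinct conformer
  base <- random_conformer(seed = 2)
  far <- random_conformer(seed = 3)
  lib <- as_ensemble(c(replicate(12, base, simplify = FALSE), list(far)))
  ex <- select_exemplars(lib, preference = -1)
  expect_lte(n_conformers(ex), 2L)
  labels <- attr(ex, "clustering")$labels
  expect_equal(length(unique(labels[1:12])), 1L) # copies stay together
  expect_true(13L %in% attr(ex, "clustering")$exemplars)

  lib2 <- as_ensemble(lapply(1:9, function(i) random_conformer(seed = i)))
  a <- select_exemplars(lib2, preference = -5)
  b <- select_exemplars(lib2, preference = -5)
  expect_identical(attr(a, "clustering")$exemplars,
                   attr(b, "clustering")$exemplars)
  expect_identical(a$xyz, b$xyz)
})

test_that("affinity propagation validates its inputs", {
  expect_error(affinity_propagation(matrix(1, 2, 3)), "square")
  expect_error(affinity_propagation(matrix(c(0, NA, 1, 0), 2, 2)), "finite")
  one <- affinity_propagation(matrix(-5, 1, 1))
  expect_equal(one$exemplars, 1L)
  expect_equal(one$labels, 1L)
})
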