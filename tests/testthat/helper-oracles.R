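# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Horn's quaternion method: minimal RMSD via the largest eigenvalue of the
# 4x4 key matrix built from the correlation matrix of the centred sets.
horn_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Qc, Pc) # rotate Q onto P
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lam) / n))
}

# exact exemplar-set optimiser for affinity propagation instances (n <= 8):
# maximise sum of similarities to assigned exemplars plus the preferences of
# the chosen exemplars
ap_brute_force <- function(S) {
  n <- nrow(S)
  stopifnot(n <= 8)
  best <- list(score = -Inf, exemplars = integer(0))
  for (mask in 1:(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    score <- sum(diag(S)[E])
    for (i in setdiff(seq_len(n), E)) score <- score + max(S[i, E])
    if (score > best$score + 1e-12) best <- list(score = score, exemplars = E)
  }
  best
}

# a small well-separated cluster instance (the regime where affinity
# propagation reliably attains the exact exemplar optimum): 1-2 groups of
# 3-4 jittered points with separation far exceeding the spread. Returns the
# similarity matrix with the preference on the diagonal.
separated_instance <- function() {
  k <- sample(1:2, 1)
  per <- sample(3:4, k, replace = TRUE)
  centres <- matrix(runif(2 * k, -15, 15), k, 2)
  if (k == 2) {
    while (sqrt(sum((centres[1, ] - centres[2, ])^2)) < 12) {
      centres <- matrix(runif(2 * k, -15, 15), k, 2)
    }
  }
  x <- do.call(rbind, lapply(seq_len(k), function(g) {
    sweep(matrix(rnorm(2 * per[g], sd = 0.3), per[g], 2), 2,
          centres[g, ], "+")
  }))
  S <- -as.matrix(dist(x))^2
  diag(S) <- if (k == 1) -4 else median(S[upper.tri(S)])
  S
}

# independent bonded-topology exclusion (pairs within `depth` bonds),
# built from peptide connectivity rules via igraph shortest paths
peptide_exclusions <- function(conf, depth = 3) {
  key <- paste(conf$res_index, conf$atom_name)
  at <- function(ri, nm) match(paste(ri, nm), key)
  edges <- integer(0)
  link <- function(i, j) {
    if (!is.na(i) && !is.na(j)) edges <<- c(edges, i, j)
  }
  for (ri in unique(conf$res_index)) {
    res <- conf$res_name[conf$res_index == ri][1]
    if (res == "ACE") {
      link(at(ri, "CH3"), at(ri, "C")); link(at(ri, "C"), at(ri, "O"))
    } else if (res == "NME") {
      link(at(ri, "N"), at(ri, "H")); link(at(ri, "N"), at(ri, "CH3"))
    } else {
      link(at(ri, "N"), at(ri, "H")); link(at(ri, "N"), at(ri, "CA"))
      link(at(ri, "CA"), at(ri, "C")); link(at(ri, "CA"), at(ri, "CB"))
      link(at(ri, "C"), at(ri, "O"))
    }
    link(at(ri, "C"), at(ri + 1, "N"))
  }
  g <- igraph::make_graph(edges, n = nrow(conf), directed = FALSE)
  igraph::distances(g) <= depth
}

# naive all-pairs soft-sphere score with explicit neighbour exclusion
naive_soft_sphere <- function(xyz, elements, excl, radii, scale = 1) {
  n <- nrow(xyz)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (excl[i, j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      cont <- radii[elements[i]] + radii[elements[j]]
      if (d < cont) s <- s + ((cont - d) / cont)^2
    }
  }
  unname(s * scale)
}
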