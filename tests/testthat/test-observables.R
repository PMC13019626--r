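test_that("backbone phi follows the IUPAC torsion convention", {
  # four points constructed to a 90-degree torsion
  conf <- as_conformer(tibble::tibble(
    res_index = c(0L, 1L, 1L, 1L),
    res_name = c("ALA", "ALA", "ALA", "ALA"),
    atom_name = c("C", "N", "CA", "C"),
    element = c("C", "N", "C", "C"),
    x = c(0, 0, 1, 1), y = c(1, 0, 0, 0), z = c(0, 0, 0, 1),
    is_cap = FALSE), validate = FALSE)
  expect_equal(backbone_phi(conf, 1L), 90)
  # planar trans (zigzag) arrangement
  conf$x <- c(-1, 0, 1, 2); conf$y <- c(1, 0, 0, -1); conf$z <- 0
  expect_equal(abs(backbone_phi(conf, 1L)), 180)
  # first residue has no preceding carbonyl
  expect_error(backbone_phi(conf, 0L), "missing C")
})

test_that("Karplus equation closed forms hold", {
  p <- tibble::tibble(name = "t", A = 6.4, B = -1.4, C = 1.9, delta = -60)
  expect_equal(karplus_j3(60, p), p$A + p$B + p$C)   # phi = -delta
  expect_equal(karplus_j3(150, p), p$C)              # cosine zero
  p2 <- tibble::tibble(name = "r", A = 1, B = 0, C = 0, delta = 0)
  phis <- seq(-170, 170, by = 37)
  expect_equal(karplus_j3(phis, p2), cos(phis * pi / 180)^2)
  # periodicity and the cosine symmetry about -delta
  expect_equal(karplus_j3(phis, p), karplus_j3(phis + 360, p))
  expect_equal(karplus_j3(phis, p), karplus_j3(-2 * p$delta - phis, p))
})

test_that("consensus prediction averages sets and doubles the spread", {
  ens <- as_ensemble(lapply(1:4, function(i) random_conformer(seed = i)))
  # constant parameter sets give controlled ensemble-level predictions 4,5,6
  sets <- tibble::tibble(name = c("a", "b", "c"), A = 0, B = 0,
                         C = c(4, 5, 6), delta = -60)
  j3 <- predict_j3_with_consensus(ens, sets)
  expect_true(all(abs(j3$M - 5) < 1e-12))
  expect_equal(unique(j3$observables$sigma), 2 * sqrt(2 / 3),
               tolerance = 1e-9)
  expect_equal(unique(j3$observables$sigma), 1.633, tolerance = 1e-3)
  # identical sets: spread collapses to the floor
  sets0 <- sets; sets0$C <- 5
  j30 <- predict_j3_with_consensus(ens, sets0, sigma_floor = 0.1)
  expect_true(all(j30$observables$sigma == 0.1))
  expect_error(predict_j3_with_consensus(ens, sets[1, ]), "at least 2")
})

test_that("consensus prediction excludes prolines, terminals and phosphosites", {
  seqs <- toy_sequence() # SRTPGLKAV: PRO at index 3
  ens <- as_ensemble(lapply(1:3, function(i) random_conformer(seqs, i)))
  # strip caps to emulate an assembled conformer (first residue has no phi)
  stripped <- lapply(1:3, function(i) {
    cf <- get_conformer(ens, i)
    as_conformer(cf[!cf$is_cap, ], validate = FALSE)
  })
  ens2 <- as_ensemble(stripped)
  j3 <- predict_j3_with_consensus(ens2, residues = 0:8)
  expect_false(0L %in% j3$observables$res_index)
  expect_false(3L %in% j3$observables$res_index)
  expect_true(all(c("proline: no amide proton",
                    "first residue: phi undefined") %in% j3$excluded$reason))
  # phospho-flagged residues are excluded when the sequence is given
  seqp <- parse_sequence("SRtPGLKAV", 1)
  expect_false(2L %in% j3_residues(seqp))
  expect_true(2L %in% j3_residues(parse_sequence("SRTPGLKAV", 1)))
})

test_that("per-conformer phi matrix matches the scalar path", {
  ens <- as_ensemble(lapply(1:3, function(i) random_conformer(seed = i)))
  sets <- default_karplus()
  j3 <- predict_j3_with_consensus(ens)
  ri <- j3$observables$res_index[2]
  conf <- get_conformer(ens, 2)
  expect_equal(j3$M[2, 2],
               mean(vapply(seq_len(nrow(sets)), function(s)
                 karplus_j3(backbone_phi(conf, ri), sets[s, ]), numeric(1))),
               tolerance = 1e-9)
})

test_that("shift ingestion is order-insensitive and refuses missing cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- expand.grid(model = 1:3, residue = c(211, 212), atom = "CA")
  df$value <- round(50 + seq_len(nrow(df)) / 10, 3)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sh <- load_shift_predictions(path, 3)
  expect_equal(dim(sh$M), c(3L, 2L))
  expect_equal(sh$observables$kind, rep("shift", 2))
  # shuffled rows give the same matrix
  write.table(df[sample(nrow(df)), ], path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_equal(load_shift_predictions(path, 3)$M, sh$M)
  # a missing cell is an error naming the cell, not an imputation
  write.table(df[-4, ], path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_shift_predictions(path, 3), "model 1, residue 212")
})

test_that("radius of gyration matches direct summation", {
  single <- as_conformer(tibble::tibble(
    res_index = 0L, res_name = "GLY", atom_name = "CA", element = "C",
    x = 3, y = -1, z = 2, is_cap = FALSE), validate = FALSE)
  expect_equal(radius_of_gyration(single), 0)
  dumbbell <- as_conformer(tibble::tibble(
    res_index = c(0L, 0L), res_name = "GLY", atom_name = c("CA", "C"),
    element = "C", mass = 1, x = c(0, 2), y = 0, z = 0, is_cap = FALSE),
    validate = FALSE)
  expect_equal(radius_of_gyration(dumbbell), 1)
  conf <- random_conformer(seed = 14)
  xyz <- coords(conf)
  cm <- colSums(xyz * conf$mass) / sum(conf$mass)
  oracle <- sqrt(sum(conf$mass * rowSums(sweep(xyz, 2, cm)^2)) /
                   sum(conf$mass))
  expect_equal(radius_of_gyration(conf), oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(radius_of_gyration(conf),
                                radius_of_gyration(conf, FALSE))))
  # vectorised ensemble path agrees with the scalar path
  ens <- as_ensemble(lapply(1:4, function(i) random_conformer(seed = i)))
  expect_equal(ensemble_rgyr(ens),
               vapply(1:4, function(i)
                 radius_of_gyration(get_conformer(ens, i)), numeric(1)),
               tolerance = 1e-9)
})

test_that("ensemble averages are weighted column means, linear in weights", {
  M <- matrix(c(0, 4, 2, 6), 2, 2)
  expect_equal(ensemble_average(M, c(0.5, 0.5)), colMeans(M))
  expect_equal(ensemble_average(M, c(0, 1)), M[2, ])
  expect_equal(ensemble_average(M[, 1, drop = FALSE], c(0.25, 0.75)), 3)
  w1 <- c(0.3, 0.7); w2 <- c(0.9, 0.1); a <- 0.4
  expect_equal(ensemble_average(M, a * w1 + (1 - a) * w2),
               a * ensemble_average(M, w1) +
                 (1 - a) * ensemble_average(M, w2))
  expect_error(ensemble_average(M, c(1, 2)), "sum to 1")
  expect_error(ensemble_average(M, 1), "match")
})

test_that("observable RMSD is computed per kind and is order-invariant", {
  pred <- tibble::tibble(res_index = c(1L, 2L, 3L), kind = "J3",
                         label = "HN-HA", value = c(5, 6, 7))
  exp_t <- pred
  expect_equal(rmsd_to_experiment(pred, exp_t)$rmsd, 0)
  exp_t$value <- c(5.5, 6, 7)
  expect_equal(rmsd_to_experiment(pred[1, ], exp_t[1, ])$rmsd, 0.5)
  exp2 <- tibble::tibble(res_index = 1:2, kind = "J3", label = "HN-HA",
                         value = c(8, 10))
  expect_equal(rmsd_to_experiment(pred[1:2, ], exp2)$rmsd, sqrt(12.5))
  expect_equal(rmsd_to_experiment(pred[1:2, ], exp2[2:1, ])$rmsd,
               sqrt(12.5))
  # mixed kinds are reported separately
  pred_m <- dplyr::bind_rows(pred,
                             tibble::tibble(res_index = 1L, kind = "shift",
                                            label = "CA", value = 50))
  exp_m <- dplyr::bind_rows(exp_t,
                            tibble::tibble(res_index = 1L, kind = "shift",
                                           label = "CA", value = 51))
  out <- rmsd_to_experiment(pred_m, exp_m)
  expect_equal(nrow(out), 2L)
  expect_equal(out$rmsd[out$kind == "shift"], 1)
  # panel filtering by label list
  panel <- tibble::tibble(res_index = 1L, kind = "J3", label = "HN-HA")
  expect_equal(rmsd_to_experiment(pred_m, exp_m, panel)$rmsd, 0.5)
  expect_error(rmsd_to_experiment(pred, exp_t[0, ]), "no matched")
})

test_that("weighted density integrates to one and locates modes", {
  # symmetric bimodal with equal weights: mode tie resolves to lower value
  v <- with_seed(8L, c(rnorm(500, -3, 0.3), rnorm(500, 3, 0.3)))
  v <- c(v, -v) # force exact symmetry
  d <- weighted_density(v, bw = 0.3)
  expect_lt(abs(sum(d$y) * diff(d$x[1:2]) - 1), 1e-3)
  # symmetric density: the mode sits at either peak
  expect_lt(abs(abs(d$mode) - 3), 0.2)
  # all weight on one value: mode within a grid step
  v2 <- c(1, 2, 3, 4)
  d2 <- weighted_density(v2, weights = c(0, 1, 0, 0))
  expect_lt(abs(d2$mode - 2), diff(d2$x[1:2]) + 1e-9)
  # standard normal, uniform weights: mode near 0
  v3 <- with_seed(4L, rnorm(1e4))
  expect_lt(abs(weighted_density(v3)$mode), 0.1)
  # uniform weights equal the unweighted estimator on the same grid
  v4 <- with_seed(5L, rnorm(200))
  dw <- weighted_density(v4, weights = rep(1, 200), bw = 0.4)
  du <- weighted_density(v4, bw = 0.4)
  expect_equal(dw$y, du$y, tolerance = 1e-12)
  expect_error(weighted_density(rep(1, 5)), "degenerate")
})
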