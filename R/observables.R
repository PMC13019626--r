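#' Load Karplus parameter sets for 3J(HN-HA)
#' @param path YAML file; defaults to the three literature sets shipped with
#'   the package.
#' @return Tibble with `name`, `A`, `B`, `C` (Hz) and `delta` (degrees).
#' @export
default_karplus <- function(path = system.file("extdata", "karplus.yaml",
                                               package = "erfr")) {
  dplyr::bind_rows(lapply(yaml::read_yaml(path)$sets, tibble::as_tibble))
}

#' Backbone phi dihedral of one residue
#'
#' `phi(i) = dihedral(C(i-1), N(i), CA(i), C(i))`; the preceding carbonyl may
#' belong to an acetyl cap. Undefined (error) for a first residue without a
#' cap or when an atom is missing.
#'
#' @param conf Conformer atom table.
#' @param res_index Residue index (0-based).
#' @return Signed angle in degrees, in (-180, 180].
#' @export
backbone_phi <- function(conf, res_index) {
  pos <- function(ri, name) {
    hit <- which(conf$res_index == ri & conf$atom_name == name)
    if (!length(hit)) {
      stop(sprintf("phi undefined at residue %d: missing %s at residue %d",
                   res_index, name, ri), call. = FALSE)
    }
    c(conf$x[hit[1]], conf$y[hit[1]], conf$z[hit[1]])
  }
  p1 <- pos(res_index - 1L, "C")
  p2 <- pos(res_index, "N")
  p3 <- pos(res_index, "CA")
  p4 <- pos(res_index, "C")
  dihedral(p1, p2, p3, p4)
}

#' @noRd
ensemble_phi <- function(ens, res_indices) {
  # vectorised phi over all conformers; columns follow res_indices
  tpl <- ens$template
  idx_of <- function(ri, name) {
    hit <- which(tpl$res_index == ri & tpl$atom_name == name)
    if (!length(hit)) stop(sprintf("missing %s at residue %d", name, ri),
                           call. = FALSE)
    hit[1]
  }
  n <- n_conformers(ens)
  out <- matrix(NA_real_, n, length(res_indices))
  for (k in seq_along(res_indices)) {
    ri <- res_indices[k]
    a <- idx_of(ri - 1L, "C"); b <- idx_of(ri, "N")
    c_ <- idx_of(ri, "CA"); d <- idx_of(ri, "C")
    P <- function(i) ens$xyz[, (3L * (i - 1L) + 1L):(3L * i), drop = FALSE]
    b1 <- P(b) - P(a); b2 <- P(c_) - P(b); b3 <- P(d) - P(c_)
    n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
                b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
                b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
    n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
                b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
                b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
    b2n <- b2 / sqrt(rowSums(b2^2))
    cr <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
                n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
                n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
    ang <- atan2(rowSums(cr * b2n), rowSums(n1 * n2)) * 180 / pi
    out[, k] <- ifelse(ang <= -180, ang + 360, ang)
  }
  out
}

#' Karplus back-calculation of 3J(HN-HA)
#'
#' `J = A cos^2(phi + delta) + B cos(phi + delta) + C` in Hz.
#'
#' @param phi Backbone phi dihedral(s), degrees.
#' @param params One row of a Karplus set table (`A`, `B`, `C`, `delta`).
#' @return Coupling(s) in Hz.
#' @export
karplus_j3 <- function(phi, params) {
  cs <- cos((phi + params$delta) * pi / 180)
  params$A * cs^2 + params$B * cs + params$C
}

#' Residues carrying a measurable 3J(HN-HA) coupling
#'
#' Excludes the first residue (no preceding carbonyl once caps are
#' stripped), prolines (no amide H), and - when the sequence carries
#' phospho flags - the phosphosites themselves, since observables on
#' modified residues are kept out of the reweighting.
#'
#' @param seq An `erf_sequence`.
#' @param exclude_phospho Drop phospho-flagged residues.
#' @return Integer residue indices (0-based).
#' @export
j3_residues <- function(seq, exclude_phospho = TRUE) {
  drop <- seq$index == 0L | seq$res_name == "PRO"
  if (exclude_phospho) drop <- drop | seq$phospho
  seq$index[!drop]
}

#' Consensus 3J prediction over several Karplus parameter sets
#'
#' For every conformer and eligible residue the coupling is computed with
#' each parameter set; the per-conformer consensus is the mean over sets.
#' The per-observable uncertainty is twice the (population) standard
#' deviation over sets of the ensemble-level (weight-averaged) predictions,
#' floored at `sigma_floor` - an estimate of the summed prediction and
#' experimental error.
#'
#' @param ens An `erf_ensemble` of full-length conformers.
#' @param params Karplus set table ([default_karplus()]), at least 2 rows.
#' @param residues Residue indices; default all non-proline, non-first.
#' @param seq Optional `erf_sequence` used to pick `residues` (and exclude
#'   phosphosites).
#' @param sigma_floor Lower bound on the uncertainty (Hz).
#' @return List of class `erf_j3`: `M` (conformer x observable consensus
#'   matrix), `observables` (tibble: `res_index`, `kind`, `label`, `sigma`,
#'   plus per-set ensemble means), `excluded` (tibble of skipped residues
#'   with reasons).
#' @export
predict_j3_with_consensus <- function(ens, params = default_karplus(),
                                      residues = NULL, seq = NULL,
                                      sigma_floor = 0.1) {
  if (nrow(params) < 2L) {
    stop("need at least 2 Karplus parameter sets for a consensus",
         call. = FALSE)
  }
  tpl <- ens$template
  core <- tpl[!tpl$is_cap, , drop = FALSE]
  res_tab <- dplyr::distinct(core[, c("res_index", "res_name")])
  if (is.null(residues)) {
    if (!is.null(seq)) {
      residues <- j3_residues(seq)
    } else {
      residues <- res_tab$res_index
    }
  }
  first <- min(res_tab$res_index)
  has_cap_c <- any(tpl$is_cap & tpl$res_index == first - 1L)
  reasons <- dplyr::mutate(
    res_tab[res_tab$res_index %in% residues, , drop = FALSE],
    reason = dplyr::case_when(
      res_name == "PRO" ~ "proline: no amide proton",
      res_index == first & !has_cap_c ~ "first residue: phi undefined",
      TRUE ~ NA_character_
    ))
  excluded <- reasons[!is.na(reasons$reason), , drop = FALSE]
  keep <- reasons$res_index[is.na(reasons$reason)]
  if (!length(keep)) stop("no residue eligible for 3J prediction", call. = FALSE)

  phi <- ensemble_phi(ens, keep)
  per_set <- lapply(seq_len(nrow(params)), function(s) {
    karplus_j3(phi, params[s, , drop = FALSE])
  })
  M <- Reduce(`+`, per_set) / length(per_set)
  ens_means <- vapply(per_set, function(Js) as.vector(ens$weights %*% Js),
                      numeric(length(keep)))
  ens_means <- matrix(ens_means, nrow = length(keep))
  pop_sd <- apply(ens_means, 1, function(v) sqrt(mean((v - mean(v))^2)))
  sigma <- pmax(2 * pop_sd, sigma_floor)
  obs <- tibble::tibble(
    res_index = keep,
    kind = "J3",
    label = "HN-HA",
    sigma = sigma
  )
  obs <- cbind(obs, stats::setNames(as.data.frame(ens_means), params$name))
  structure(list(M = M, observables = tibble::as_tibble(obs),
                 excluded = excluded),
            class = "erf_j3")
}

#' Read per-conformer chemical-shift predictions
#'
#' Ingests externally predicted shifts from delimited text with a one-line
#' header and columns `model` (1-based conformer), `residue` (author
#' number), `atom`, `value` (ppm). Every (model, residue, atom) cell must be
#' present; missing cells are an error, not imputed, and row order is
#' irrelevant.
#'
#' @param path Delimited text file (whitespace or tab separated).
#' @param n_models Expected conformer count (e.g. `n_conformers(ens)`).
#' @return List of class `erf_shifts`: `M` (model x observable matrix),
#'   `observables` (tibble: `author_number`, `kind = "shift"`, `label`).
#' @export
load_shift_predictions <- function(path, n_models) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("model", "residue", "atom", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("shift table needs columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  # canonical observable order (residue, then atom) so ingestion is
  # insensitive to row order
  obs_key <- unique(paste(df$residue, df$atom))
  obs_key <- obs_key[order(as.integer(sub(" .*", "", obs_key)),
                           sub(".* ", "", obs_key))]
  obs <- tibble::tibble(
    author_number = as.integer(sub(" .*", "", obs_key)),
    kind = "shift",
    label = sub(".* ", "", obs_key)
  )
  M <- matrix(NA_real_, n_models, length(obs_key))
  row_i <- df$model
  col_j <- match(paste(df$residue, df$atom), obs_key)
  if (any(row_i < 1L | row_i > n_models)) {
    stop("shift table references a model outside 1..n_models", call. = FALSE)
  }
  M[cbind(row_i, col_j)] <- df$value
  if (anyNA(M)) {
    miss <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing shift prediction for model %d, residue %d, atom %s",
                 miss[1], obs$author_number[miss[2]], obs$label[miss[2]]),
         call. = FALSE)
  }
  structure(list(M = M, observables = obs), class = "erf_shifts")
}

#' Radius of gyration of a conformer
#'
#' `sqrt(sum(m_i * |r_i - r_cm|^2) / sum(m_i))`; the unweighted variant uses
#' unit masses.
#'
#' @param conf Conformer atom table.
#' @param mass_weighted Use atomic masses (default) or unit masses.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf, mass_weighted = TRUE) {
  xyz <- coords(conf)
  m <- if (mass_weighted) conf$mass else rep(1, nrow(xyz))
  cm <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
}

#' Radius of gyration of every conformer in an ensemble
#' @param ens An `erf_ensemble`.
#' @param mass_weighted Use atomic masses.
#' @return Numeric vector (Angstrom), one value per conformer.
#' @export
ensemble_rgyr <- function(ens, mass_weighted = TRUE) {
  m <- if (mass_weighted) ens$template$mass else rep(1, nrow(ens$template))
  w <- m / sum(m)
  n_at <- nrow(ens$template)
  xs <- ens$xyz[, 3L * seq_len(n_at) - 2L, drop = FALSE]
  ys <- ens$xyz[, 3L * seq_len(n_at) - 1L, drop = FALSE]
  zs <- ens$xyz[, 3L * seq_len(n_at), drop = FALSE]
  cx <- as.vector(xs %*% w); cy <- as.vector(ys %*% w); cz <- as.vector(zs %*% w)
  sq <- (xs - cx)^2 + (ys - cy)^2 + (zs - cz)^2
  sqrt(as.vector(sq %*% w))
}

#' Weighted ensemble average of per-conformer observables
#' @param M Conformer x observable matrix.
#' @param weights Normalised weights (length `nrow(M)`).
#' @return Named numeric vector of column-wise weighted means.
#' @export
ensemble_average <- function(M, weights) {
  M <- as.matrix(M)
  if (length(weights) != nrow(M)) {
    stop("weights length must match the conformer count", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  as.vector(weights %*% M)
}

#' RMSD between predicted ensemble averages and experimental observables
#'
#' Matches predictions to the experimental table by (residue, kind, label)
#' and reports `sqrt(mean((pred - exp)^2))` separately per observable kind
#' (Hz for `J3`, ppm for `shift`). An optional label/residue filter selects
#' an observable panel before matching.
#'
#' @param predicted Tibble with columns `res_index` or `author_number`,
#'   `kind`, `label`, `value` (the ensemble-averaged predictions).
#' @param experimental Tibble with the same keys plus `value` (and
#'   optionally `sigma`).
#' @param panel Optional tibble/data frame of keys to keep (same columns).
#' @return Tibble with `kind`, `n`, `rmsd`.
#' @export
rmsd_to_experiment <- function(predicted, experimental, panel = NULL) {
  key_cols <- intersect(c("author_number", "res_index", "kind", "label"),
                        intersect(names(predicted), names(experimental)))
  if (!length(key_cols)) stop("no shared key columns", call. = FALSE)
  if (!is.null(panel)) {
    pk <- intersect(key_cols, names(panel))
    experimental <- dplyr::semi_join(experimental, panel, by = pk)
  }
  j <- dplyr::inner_join(predicted, experimental, by = key_cols,
                         suffix = c("_pred", "_exp"))
  if (!nrow(j)) stop("no matched observables after filtering", call. = FALSE)
  dplyr::summarise(dplyr::group_by(j, .data$kind),
                   n = dplyr::n(),
                   rmsd = sqrt(mean((.data$value_pred - .data$value_exp)^2)),
                   .groups = "drop")
}

#' Weighted Gaussian kernel density with mode location
#'
#' Bandwidth follows a Silverman-type rule on the weighted sample with the
#' Kish effective sample size in place of n; the density is evaluated on a
#' 512-point grid spanning the data plus three bandwidths and integrates to
#' 1 on that grid. Mode ties resolve to the lower value.
#'
#' @param values Numeric vector (at least 2 distinct values).
#' @param weights Non-negative weights (normalised internally); uniform by
#'   default.
#' @param bw Optional fixed bandwidth overriding the rule.
#' @param n_grid Grid size.
#' @return List of class `erf_density`: `x`, `y`, `mode`, `bw`.
#' @export
weighted_density <- function(values, weights = NULL, bw = NULL,
                             n_grid = 512L) {
  stopifnot(length(values) >= 2L)
  if (length(unique(values)) < 2L) {
    stop("degenerate sample: all values identical", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  if (is.null(bw)) {
    ess <- 1 / sum(w^2)
    mu <- sum(w * values)
    sdw <- sqrt(sum(w * (values - mu)^2))
    qs <- stats::approx(cumsum(w[order(values)]), sort(values),
                        xout = c(0.25, 0.75), rule = 2, ties = "ordered")$y
    iqr <- diff(qs)
    spread <- min(sdw, if (iqr > 0) iqr / 1.34 else Inf)
    # near-degenerate weighting (e.g. one-hot): fall back to the unweighted
    # spread so the bandwidth stays positive
    if (!is.finite(spread) || spread <= 0) {
      spread <- max(stats::sd(values), 1e-3 * diff(range(values)))
    }
    bw <- 0.9 * spread * ess^(-1 / 5)
  }
  d <- stats::density(values, weights = w, bw = bw, n = n_grid,
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  mode <- d$x[which.max(d$y)]
  structure(list(x = d$x, y = d$y, mode = mode, bw = bw),
            class = "erf_density")
}
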