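## element masses (u) for the atoms the package places or reads
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)

#' @noRd
guess_element <- function(atom_name) {
  # PDB v3: element is the first alphabetic character after stripping digits,
  # except two-letter cases we never place here. Handles "CH3", "1HB" etc.
  stripped <- gsub("[0-9']", "", atom_name)
  substr(stripped, 1L, 1L)
}

#' Assemble a conformer atom table
#'
#' A conformer is a tibble of atom records: `res_index` (0-based),
#' `res_name` (PDB three-letter component code; `ACE`/`NME` for caps),
#' `atom_name` (PDB v3), `element`, `mass` (u), `x`, `y`, `z` (Angstrom) and
#' `is_cap`. All geometric stages operate on this table.
#'
#' @param atoms A data frame with at least `res_index`, `res_name`,
#'   `atom_name`, `x`, `y`, `z`; `element`, `mass` and `is_cap` are filled in
#'   when missing.
#' @param validate Check backbone completeness and name uniqueness.
#' @return A tibble of class `erf_conformer`.
#' @export
as_conformer <- function(atoms, validate = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("res_index", "res_name", "atom_name", "x", "y", "z") %in%
                  names(atoms)))
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$atom_name)
  }
  blank <- !nzchar(atoms$element) | is.na(atoms$element)
  atoms$element[blank] <- guess_element(atoms$atom_name[blank])
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- unname(ELEMENT_MASS[atoms$element])
  }
  if (!"is_cap" %in% names(atoms)) {
    atoms$is_cap <- atoms$res_name %in% CAP_NAMES
  }
  atoms$res_index <- as.integer(atoms$res_index)
  if (validate) validate_conformer(atoms)
  class(atoms) <- unique(c("erf_conformer", class(atoms)))
  atoms
}

#' Validate a conformer atom table
#'
#' Every non-cap residue must carry at least N, CA and C; CB may be absent
#' only for glycine when `require_cb`; atom names must be unique within a
#' residue and coordinates finite.
#'
#' @param atoms Conformer atom table.
#' @param require_cb Also require CB on non-glycine residues.
#' @return Invisibly `TRUE`; errors describe the offending residue.
#' @export
validate_conformer <- function(atoms, require_cb = FALSE) {
  if (!nrow(atoms)) stop("conformer has no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("conformer has non-finite coordinates", call. = FALSE)
  }
  key <- paste(atoms$res_index, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate atom name within residue: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  core <- atoms[!atoms$is_cap, , drop = FALSE]
  for (ri in unique(core$res_index)) {
    res <- core[core$res_index == ri, , drop = FALSE]
    missing_bb <- setdiff(c("N", "CA", "C"), res$atom_name)
    if (length(missing_bb)) {
      stop(sprintf("residue %d (%s) is missing backbone atom(s) %s", ri,
                   res$res_name[1], paste(missing_bb, collapse = ", ")),
           call. = FALSE)
    }
    if (require_cb && res$res_name[1] != "GLY" && !"CB" %in% res$atom_name) {
      stop(sprintf("residue %d (%s) is missing CB", ri, res$res_name[1]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Conformer coordinates as an n x 3 matrix
#' @param conf Conformer atom table.
#' @return Numeric matrix with one row per atom.
#' @export
coords <- function(conf) {
  cbind(x = conf$x, y = conf$y, z = conf$z)
}

#' @noRd
set_coords <- function(conf, xyz) {
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  conf
}

#' Build an ensemble container from conformers sharing one atom roster
#'
#' Ensembles are stored as a shared atom-template tibble plus an
#' `n_conformers x (3 * n_atoms)` coordinate matrix (rows are conformers,
#' columns interleave x,y,z per atom), which keeps tens of thousands of
#' assembled conformers affordable. Weights default to uniform.
#'
#' @param conformers List of conformer atom tables with identical rosters,
#'   or a single conformer.
#' @param weights Optional non-negative weights (normalised to sum to 1).
#' @param energies Optional per-conformer scores.
#' @param provenance Optional tibble with one row per conformer.
#' @return An object of class `erf_ensemble`.
#' @export
as_ensemble <- function(conformers, weights = NULL, energies = NULL,
                        provenance = NULL) {
  if (inherits(conformers, "erf_ensemble")) return(conformers)
  if (inherits(conformers, "erf_conformer")) conformers <- list(conformers)
  stopifnot(is.list(conformers), length(conformers) >= 1L)
  template <- conformers[[1]][, setdiff(names(conformers[[1]]),
                                        c("x", "y", "z"))]
  roster <- paste(template$res_index, template$atom_name)
  xyz <- matrix(NA_real_, nrow = length(conformers), ncol = 3L * nrow(template))
  for (i in seq_along(conformers)) {
    ci <- conformers[[i]]
    if (!identical(paste(ci$res_index, ci$atom_name), roster)) {
      stop(sprintf("conformer %d does not share the ensemble atom roster", i),
           call. = FALSE)
    }
    xyz[i, ] <- as.vector(t(coords(ci)))
  }
  new_ensemble(template, xyz, weights, energies, provenance)
}

#' @noRd
new_ensemble <- function(template, xyz, weights = NULL, energies = NULL,
                         provenance = NULL) {
  n <- nrow(xyz)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  if (!is.null(energies)) stopifnot(length(energies) == n)
  structure(list(template = tibble::as_tibble(template), xyz = xyz,
                 weights = weights, energies = energies,
                 provenance = provenance),
            class = "erf_ensemble")
}

#' Number of conformers in an ensemble
#' @param ens An `erf_ensemble`.
#' @export
n_conformers <- function(ens) nrow(ens$xyz)

#' Extract one conformer from an ensemble
#' @param ens An `erf_ensemble`.
#' @param i Conformer index (1-based).
#' @return A conformer atom table.
#' @export
get_conformer <- function(ens, i) {
  stopifnot(i >= 1, i <= n_conformers(ens))
  xyz <- matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
  conf <- ens$template
  conf$x <- xyz[, 1]; conf$y <- xyz[, 2]; conf$z <- xyz[, 3]
  as_conformer(conf, validate = FALSE)
}

#' @export
print.erf_ensemble <- function(x, ...) {
  cat(sprintf(
    "<erf_ensemble> %d conformers x %d atoms (%d residues)%s\n",
    n_conformers(x), nrow(x$template),
    length(unique(x$template$res_index[!x$template$is_cap])),
    if (is.null(x$energies)) "" else ", scored"))
  cat(sprintf("  Kish ESS of weights: %.1f\n", kish_ess(x$weights)$ess))
  invisible(x)
}

#' Subset an ensemble by conformer index
#' @param ens An `erf_ensemble`.
#' @param idx Integer vector of conformer indices to keep.
#' @param renormalise Re-normalise the retained weights (default `TRUE`).
#' @export
subset_ensemble <- function(ens, idx, renormalise = TRUE) {
  stopifnot(length(idx) >= 1L)
  w <- ens$weights[idx]
  if (renormalise) w <- w / sum(w)
  new_ensemble(ens$template, ens$xyz[idx, , drop = FALSE], w,
               ens$energies[idx],
               if (!is.null(ens$provenance)) ens$provenance[idx, , drop = FALSE])
}
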