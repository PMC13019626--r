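## default six-point junction alignment set: backbone + CB + amide H of the
## overlap residue (glycine contributes 5 points - no CB; proline 5 - no H)
JUNCTION_ATOMS <- c("N", "H", "CA", "CB", "C", "O")

#' @noRd
junction_rows <- function(conf_tpl, res_index, atoms) {
  hit <- which(conf_tpl$res_index == res_index & !conf_tpl$is_cap &
                 conf_tpl$atom_name %in% atoms)
  hit[order(match(conf_tpl$atom_name[hit], atoms))]
}

#' Rigidly align a moving fragment onto a fixed fragment's overlap residue
#'
#' Both fragments carry a copy of the shared junction residue; the moving
#' fragment is rigidly transformed so its copy optimally superposes (six
#' alignment points: backbone, CB and amide H, fewer for glycine/proline)
#' onto the fixed fragment's copy. Internal geometry of the moving fragment
#' is untouched.
#'
#' @param fixed,moving Conformer atom tables.
#' @param junction Length-2 integer: the junction residue's `res_index` in
#'   `fixed` and in `moving`.
#' @param atoms Alignment atom names (intersection with both copies is used;
#'   at least 3 common atoms required).
#' @return List: `moving` (transformed conformer), `junction_rmsd`
#'   (Angstrom), `rotation`, `translation`.
#' @export
junction_align <- function(fixed, moving, junction,
                           atoms = JUNCTION_ATOMS) {
  stopifnot(length(junction) == 2L)
  fi <- junction_rows(fixed, junction[1], atoms)
  common <- intersect(fixed$atom_name[fi],
                      moving$atom_name[moving$res_index == junction[2] &
                                         !moving$is_cap])
  if (length(common) < 3L) {
    missing <- setdiff(atoms, common)
    stop(sprintf(
      "junction residue needs at least 3 shared alignment atoms; missing %s at residue %d",
      paste(missing, collapse = ", "), junction[1]), call. = FALSE)
  }
  fi <- junction_rows(fixed, junction[1], common)
  mi <- junction_rows(moving, junction[2], common)
  fit <- superpose(coords(fixed)[fi, , drop = FALSE],
                   coords(moving)[mi, , drop = FALSE])
  list(moving = set_coords(moving, fit$apply(coords(moving))),
       junction_rmsd = fit$rmsd,
       rotation = fit$rotation, translation = fit$translation)
}

#' Merge an aligned fragment pair into one chain
#'
#' Keeps the fixed fragment's copy of the junction residue and appends the
#' moving fragment's residues beyond the junction; the facing caps (fixed
#' C-cap, moving N-cap) and the moving copy of the junction residue are
#' discarded, residue indices are renumbered contiguously, and no re-bonding
#' optimisation is applied at the seam (downstream refinement relieves seam
#' strain). Coordinates of all kept atoms are preserved bitwise.
#'
#' @param fixed Fixed conformer.
#' @param moving_aligned Moving conformer already transformed by
#'   [junction_align()].
#' @param junction Length-2 integer junction residue indices
#'   (fixed, moving).
#' @return Merged conformer atom table.
#' @export
merge_pair <- function(fixed, moving_aligned, junction) {
  jf <- junction[1]; jm <- junction[2]
  keep_fixed <- fixed[!(fixed$is_cap & fixed$res_index > jf), , drop = FALSE]
  tail_m <- moving_aligned[moving_aligned$res_index > jm &
                             !(moving_aligned$is_cap &
                                 moving_aligned$res_index < jm), , drop = FALSE]
  tail_m$res_index <- tail_m$res_index - jm + jf
  out <- dplyr::bind_rows(keep_fixed, tail_m)
  as_conformer(out, validate = FALSE)
}

#' Build an assembly plan from fragment libraries
#'
#' Re-bases each library's residue indices into the parent sequence frame
#' and records the junction residue (the overlap residue shared by
#' consecutive fragments) for every junction.
#'
#' @param libraries List of `erf_ensemble` fragment libraries, N- to
#'   C-terminal order.
#' @param fragments The `erf_fragments` table the libraries were built from.
#' @param atoms Junction alignment atom names.
#' @return List of class `erf_assembly_plan`.
#' @export
assembly_plan <- function(libraries, fragments, atoms = JUNCTION_ATOMS) {
  stopifnot(length(libraries) == nrow(fragments), length(libraries) >= 1L)
  libs <- lapply(seq_along(libraries), function(m) {
    lib <- libraries[[m]]
    lib$template$res_index <- lib$template$res_index + fragments$start[m]
    lib
  })
  junctions <- if (nrow(fragments) > 1L) fragments$start[-1L] else integer(0)
  structure(list(libraries = libs, junctions = junctions, atoms = atoms),
            class = "erf_assembly_plan")
}

#' Enumerate all fragment recombinations into a raw ensemble
#'
#' Forms one full-length conformer per element of the Cartesian product of
#' the fragment libraries, assembled left to right: at each junction the
#' incoming fragment is rigidly aligned on the shared overlap residue
#' ([junction_align()]) and the facing caps plus the duplicate overlap-residue
#' copy are discarded ([merge_pair()]); terminal caps are stripped last, so
#' the result carries exactly the parent residues. Fragment 1 defines the
#' global frame. Internally the per-junction rigid transforms are
#' precomputed per library pair and composed per tuple, which is identical
#' to the literal pairwise assembly because every operation is rigid.
#'
#' @param plan An `erf_assembly_plan`.
#' @return An `erf_ensemble` with uniform weights and provenance column
#'   `frag_<m>` giving each conformer's library member tuple.
#' @export
enumerate_assemblies <- function(plan) {
  libs <- plan$libraries
  K <- length(libs)
  sizes <- vapply(libs, n_conformers, integer(1))
  stopifnot(all(sizes >= 1L))

  # atom rows each fragment contributes to the final (cap-free) conformer
  keep_rows <- lapply(seq_len(K), function(m) {
    tpl <- libs[[m]]$template
    keep <- !tpl$is_cap
    if (m > 1L) keep <- keep & tpl$res_index > plan$junctions[m - 1L]
    which(keep)
  })
  template <- dplyr::bind_rows(lapply(seq_len(K), function(m) {
    libs[[m]]$template[keep_rows[[m]], , drop = FALSE]
  }))

  # per-junction transforms aligning each member of lib m+1 onto each member
  # of lib m, both in their native frames (row-vector convention)
  transforms <- vector("list", max(K - 1L, 0L))
  for (m in seq_len(K - 1L)) {
    j <- plan$junctions[m]
    fa <- junction_rows(libs[[m]]$template, j, plan$atoms)
    common <- intersect(libs[[m]]$template$atom_name[fa],
                        libs[[m + 1L]]$template$atom_name[
                          libs[[m + 1L]]$template$res_index == j &
                            !libs[[m + 1L]]$template$is_cap])
    if (length(common) < 3L) {
      stop(sprintf("junction at residue %d has fewer than 3 shared alignment atoms",
                   j), call. = FALSE)
    }
    fa <- junction_rows(libs[[m]]$template, j, common)
    mb <- junction_rows(libs[[m + 1L]]$template, j, common)
    tr <- vector("list", sizes[m])
    for (a in seq_len(sizes[m])) {
      Pa <- matrix(libs[[m]]$xyz[a, ], ncol = 3L, byrow = TRUE)[fa, , drop = FALSE]
      tr[[a]] <- lapply(seq_len(sizes[m + 1L]), function(b) {
        Qb <- matrix(libs[[m + 1L]]$xyz[b, ], ncol = 3L,
                     byrow = TRUE)[mb, , drop = FALSE]
        fit <- superpose(Pa, Qb)
        list(R = fit$rotation, t = fit$translation, rmsd = fit$rmsd)
      })
    }
    transforms[[m]] <- tr
  }

  frag_xyz <- lapply(seq_len(K), function(m) {
    lapply(seq_len(sizes[m]), function(a) {
      matrix(libs[[m]]$xyz[a, ], ncol = 3L, byrow = TRUE)
    })
  })

  n_total <- prod(sizes)
  n_atoms <- nrow(template)
  xyz <- matrix(NA_real_, n_total, 3L * n_atoms)
  tuples <- as.matrix(rev(expand.grid(rev(lapply(sizes, seq_len)))))
  colnames(tuples) <- paste0("frag_", seq_len(K))

  for (row in seq_len(n_total)) {
    tup <- tuples[row, ]
    R <- diag(3); t_ <- c(0, 0, 0)
    parts <- vector("list", K)
    parts[[1L]] <- frag_xyz[[1L]][[tup[1L]]][keep_rows[[1L]], , drop = FALSE]
    for (m in seq_len(K - 1L)) {
      tr <- transforms[[m]][[tup[m]]][[tup[m + 1L]]]
      # compose: native frame of fragment m+1 -> assembly frame
      t_ <- as.vector(tr$t %*% R) + t_
      R <- tr$R %*% R
      X <- frag_xyz[[m + 1L]][[tup[m + 1L]]][keep_rows[[m + 1L]], , drop = FALSE]
      parts[[m + 1L]] <- sweep(X %*% R, 2, t_, "+")
    }
    xyz[row, ] <- as.vector(t(do.call(rbind, parts)))
  }
  new_ensemble(template, xyz,
               provenance = tibble::as_tibble(tuples))
}
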