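#' Load the ideal-geometry table for the conformer builder
#' @param path YAML file; defaults to the table shipped with the package.
#' @return Nested list with `bond_lengths`, `bond_angles`, `torsion_offsets`.
#' @export
default_geometry <- function(path = system.file("extdata", "geometry.yaml",
                                                package = "erfr")) {
  yaml::read_yaml(path)
}

#' @noRd
geom_get <- function(geometry, table, key) {
  v <- geometry[[table]][[key]]
  if (is.null(v)) {
    stop(sprintf("geometry table has no %s entry '%s'", table, key),
         call. = FALSE)
  }
  v
}

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(vcross(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @noRd
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

## natural extension of reference frame: place D from A-B-C with
## |CD| = bond, angle(B,C,D) = theta, torsion(A,B,C,D) = chi
#' @noRd
place_atom <- function(a, b, c_, bond, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- c_ - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- vcross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("collinear reference atoms in placement", call. = FALSE)
  n <- n / nn
  m <- vcross(n, bc)
  c_ + bond * (-cos(theta) * bc + sin(theta) * (cos(chi) * m + sin(chi) * n))
}

#' Build a capped fragment conformer from backbone dihedrals
#'
#' Places atoms by sequential internal-to-Cartesian construction from the
#' ideal-geometry table: per residue N, H (except proline), CA, CB (except
#' glycine), C and O, plus an N-terminal acetyl (`ACE`: CH3, C, O) and a
#' C-terminal N-methyl amide (`NME`: N, H, CH3) cap. Measured backbone
#' dihedrals of the result reproduce the inputs to numerical precision,
#' which [measure_dihedrals()] can verify.
#'
#' @param seq_window An `erf_sequence` (typically from [fragment_window()]).
#' @param dihedrals Data frame with one row per residue and columns
#'   `phi`, `psi`, `omega` in degrees.
#' @param geometry Geometry table from [default_geometry()].
#' @return A conformer atom table.
#' @export
build_conformer <- function(seq_window, dihedrals,
                            geometry = default_geometry()) {
  n <- nrow(seq_window)
  stopifnot(nrow(dihedrals) == n,
            all(c("phi", "psi", "omega") %in% names(dihedrals)))
  bl <- function(k) geom_get(geometry, "bond_lengths", k)
  ba <- function(k) geom_get(geometry, "bond_angles", k)
  off <- function(k) geom_get(geometry, "torsion_offsets", k)

  rows <- list()
  add <- function(res_index, res_name, atom_name, pos, is_cap = FALSE) {
    rows[[length(rows) + 1L]] <<- list(res_index = res_index,
                                       res_name = res_name,
                                       atom_name = atom_name,
                                       x = pos[1], y = pos[2], z = pos[3],
                                       is_cap = is_cap)
    pos
  }

  # ACE cap bootstrap in a canonical frame
  ch3 <- add(-1L, "ACE", "CH3", c(0, 0, 0), TRUE)
  c_ace <- add(-1L, "ACE", "C", c(bl("CH3-C"), 0, 0), TRUE)
  th <- ba("CH3-C-O") * pi / 180
  o_ace <- add(-1L, "ACE", "O",
               c_ace + bl("C-O") * c(-cos(th), sin(th), 0), TRUE)

  prev_ca <- ch3; prev_c <- c_ace; prev_o <- o_ace
  prev_n <- NULL; prev_psi <- NA_real_
  for (i in seq_len(n)) {
    res <- seq_window$res_name[i]
    omega <- wrap_angle(dihedrals$omega[i])
    phi <- wrap_angle(dihedrals$phi[i])
    psi <- wrap_angle(dihedrals$psi[i])
    ridx <- seq_window$index[i]
    if (i == 1L) {
      # improper about the acetyl C places N anti to O
      n_at <- add(ridx, res, "N",
                  place_atom(prev_o, prev_ca, prev_c, bl("C-N"),
                             ba("CH3-C-N"), 180))
    } else {
      n_at <- add(ridx, res, "N",
                  place_atom(prev_n, prev_ca, prev_c, bl("C-N"),
                             ba("CA-C-N"), prev_psi))
    }
    ca <- place_atom(prev_ca, prev_c, n_at, bl("N-CA"), ba("C-N-CA"), omega)
    if (res != "PRO") {
      add(ridx, res, "H",
          place_atom(prev_ca, prev_c, n_at, bl("N-H"), ba("C-N-H"),
                     wrap_angle(omega + off("h"))))
    }
    add(ridx, res, "CA", ca)
    c_at <- add(ridx, res, "C",
                place_atom(prev_c, n_at, ca, bl("CA-C"), ba("N-CA-C"), phi))
    if (res != "GLY") {
      add(ridx, res, "CB",
          place_atom(prev_c, n_at, ca, bl("CA-CB"), ba("N-CA-CB"),
                     wrap_angle(phi + off("cb"))))
    }
    add(ridx, res, "O",
        place_atom(n_at, ca, c_at, bl("C-O"), ba("CA-C-O"),
                   wrap_angle(psi + off("o"))))
    prev_n <- n_at; prev_ca <- ca; prev_c <- c_at; prev_psi <- psi
  }
  # NME cap: closes psi of the last residue and a trans methyl amide
  last_idx <- seq_window$index[n] + 1L
  n_nme <- add(last_idx, "NME", "N",
               place_atom(prev_n, prev_ca, prev_c, bl("C-N"),
                          ba("CA-C-N"), prev_psi), TRUE)
  add(last_idx, "NME", "H",
      place_atom(prev_ca, prev_c, n_nme, bl("N-H"), ba("C-N-H"), 0), TRUE)
  add(last_idx, "NME", "CH3",
      place_atom(prev_ca, prev_c, n_nme, bl("N-CH3"), ba("C-N-CH3"), 180),
      TRUE)
  as_conformer(dplyr::bind_rows(rows))
}

#' Measure backbone dihedrals of a capped conformer
#'
#' phi(i) uses the preceding residue's (or acetyl cap's) carbonyl C; psi(i)
#' uses the following residue's (or N-methyl cap's) N; omega(i) spans the
#' peptide bond into residue i.
#'
#' @param conf Conformer atom table with ACE/NME caps.
#' @return Tibble with `res_index`, `phi`, `psi`, `omega` in degrees.
#' @export
measure_dihedrals <- function(conf) {
  atom_pos <- function(ri, name) {
    hit <- which(conf$res_index == ri & conf$atom_name == name)
    if (!length(hit)) return(NULL)
    c(conf$x[hit[1]], conf$y[hit[1]], conf$z[hit[1]])
  }
  core <- sort(unique(conf$res_index[!conf$is_cap]))
  purrr::map_dfr(core, function(ri) {
    c_prev <- atom_pos(ri - 1L, "C")
    ca_prev <- atom_pos(ri - 1L, "CA")
    if (is.null(ca_prev)) ca_prev <- atom_pos(ri - 1L, "CH3")
    n <- atom_pos(ri, "N"); ca <- atom_pos(ri, "CA"); c_ <- atom_pos(ri, "C")
    n_next <- atom_pos(ri + 1L, "N")
    tibble::tibble(
      res_index = ri,
      phi = if (is.null(c_prev)) NA_real_ else dihedral(c_prev, n, ca, c_),
      psi = if (is.null(n_next)) NA_real_ else dihedral(n, ca, c_, n_next),
      omega = if (is.null(c_prev) || is.null(ca_prev)) NA_real_ else
        dihedral(ca_prev, c_prev, n, ca)
    )
  })
}
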