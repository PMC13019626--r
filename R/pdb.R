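#' Read a multi-model PDB file as an ensemble
#'
#' One conformer per `MODEL`/`ENDMDL` block (a bare single-model file is
#' accepted as one conformer). Atom order is preserved; residue indices are
#' re-based so the first non-cap residue is 0 (an N-terminal `ACE` cap gets
#' index -1, a C-terminal `NME` cap index n). Elements are inferred from the
#' atom name when the element column is blank. Ensemble weights written by
#' [write_ensemble_pdb()] as `REMARK 250 ERF WEIGHT` records are recovered;
#' otherwise weights are uniform.
#'
#' @param path Path to a PDB file.
#' @return An `erf_ensemble`.
#' @export
read_ensemble_pdb <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  atom_line <- rec %in% c("ATOM  ", "HETATM")
  if (length(model_starts) > 1L) {
    model_ends <- which(rec == "ENDMDL")
    counts <- vapply(seq_along(model_starts), function(i) {
      sum(atom_line[model_starts[i]:model_ends[i]])
    }, integer(1))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop(sprintf(
        "model %d has %d atoms where model 1 has %d: all models must share one atom roster",
        bad, counts[bad], counts[1]), call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  first_model <- seq_len(ncol(pdb$xyz) / 3L)
  atom <- atom[seq_along(first_model), , drop = FALSE]

  # sequential residue re-basing: order of first appearance
  res_key <- paste(atom$resno, atom$insert, atom$chain)
  res_index <- match(res_key, unique(res_key)) - 1L
  res_name <- toupper(atom$resid)
  if (res_name[1] == "ACE") res_index <- res_index - 1L
  elem <- toupper(trimws(ifelse(is.na(atom$elesy) | !nzchar(trimws(atom$elesy)),
                                guess_element(trimws(atom$elety)),
                                atom$elesy)))
  template <- tibble::tibble(
    res_index = res_index,
    res_name = res_name,
    atom_name = trimws(atom$elety),
    element = elem,
    mass = unname(ELEMENT_MASS[elem]),
    is_cap = res_name %in% CAP_NAMES
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  validate_conformer(as_conformer(cbind(template,
                                        x = xyz[1, c(TRUE, FALSE, FALSE)],
                                        y = xyz[1, c(FALSE, TRUE, FALSE)],
                                        z = xyz[1, c(FALSE, FALSE, TRUE)]),
                                  validate = FALSE))

  weights <- NULL
  wl <- grep("^REMARK 250 ERF WEIGHT ", lines, value = TRUE)
  if (length(wl)) {
    parts <- strsplit(trimws(sub("^REMARK 250 ERF WEIGHT ", "", wl)), "\\s+")
    idx <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    val <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    weights <- val[order(idx)]
    if (length(weights) != nrow(xyz)) {
      stop("weight REMARK count does not match model count", call. = FALSE)
    }
  }
  new_ensemble(template, unclass(xyz), weights)
}

#' Write an ensemble (or conformer list) as a multi-model PDB file
#'
#' Coordinates are written at PDB precision (3 decimals). Weights, when
#' given (or carried by the ensemble and `weights = TRUE`), are emitted as
#' `REMARK 250 ERF WEIGHT <model> <value>` header lines that
#' [read_ensemble_pdb()] parses back.
#'
#' @param ens An `erf_ensemble`, a conformer, or a list of conformers
#'   sharing one atom roster.
#' @param path Output path.
#' @param weights `TRUE` to emit the ensemble's weights, `FALSE`/`NULL` for
#'   none, or a numeric vector.
#' @param numbering_offset Author number given to residue index 0.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ens, path, weights = FALSE,
                               numbering_offset = 1L) {
  if (is.list(ens) && !inherits(ens, "erf_ensemble") &&
      !inherits(ens, "erf_conformer")) {
    if (!length(ens)) stop("cannot write an empty ensemble", call. = FALSE)
  }
  ens <- as_ensemble(ens)
  n <- n_conformers(ens)
  tpl <- ens$template
  if (isTRUE(weights)) weights <- ens$weights
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (is.numeric(weights)) {
    stopifnot(length(weights) == n)
    writeLines(sprintf("REMARK 250 ERF WEIGHT %d %.10g", seq_len(n), weights),
               con)
  }
  resno <- tpl$res_index + as.integer(numbering_offset)
  name4 <- ifelse(nchar(tpl$atom_name) >= 4L, tpl$atom_name,
                  sprintf(" %-3s", tpl$atom_name))
  for (m in seq_len(n)) {
    xyz <- matrix(ens$xyz[m, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(tpl)), name4, tpl$res_name, "A", resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, tpl$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
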