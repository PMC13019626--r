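#' Load the Ramachandran basin model for the synthetic generator
#' @param path YAML file; defaults to the coil-like model shipped with the
#'   package (basins per residue class: default, glycine, proline,
#'   preproline).
#' @return A named list of basin tables (tibbles with `name`, `phi`, `psi`,
#'   `sd`, `weight`), weights normalised within each class.
#' @export
default_basins <- function(path = system.file("extdata", "basins.yaml",
                                              package = "erfr")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cls) {
    tb <- dplyr::bind_rows(lapply(cls, tibble::as_tibble))
    stopifnot(all(tb$weight >= 0), sum(tb$weight) > 0)
    tb$weight <- tb$weight / sum(tb$weight)
    tb
  })
}

#' @noRd
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
residue_class <- function(res_names) {
  n <- length(res_names)
  cls <- rep("default", n)
  cls[res_names == "GLY"] <- "glycine"
  pre <- which(c(res_names[-1] == "PRO", FALSE)) # residue before a proline
  cls[pre[res_names[pre] != "PRO" & res_names[pre] != "GLY"]] <- "preproline"
  cls[res_names == "PRO"] <- "proline"
  cls
}

#' Draw backbone dihedrals from the basin model
#'
#' Per residue a basin is chosen by its weight and phi/psi are drawn from a
#' wrapped normal around the basin centre; omega is trans (180 degrees)
#' throughout, matching the coil behaviour the generator emulates. Proline
#' uses its own class with phi held near -65 degrees.
#'
#' @param seq_window An `erf_sequence` window.
#' @param basins Basin model from [default_basins()].
#' @param seed RNG seed; `NULL` continues the caller's RNG stream.
#' @return Tibble with `res_index`, `basin`, `phi`, `psi`, `omega`.
#' @export
sample_dihedrals <- function(seq_window, basins = default_basins(),
                             seed = NULL) {
  with_seed_local(seed, {
    cls <- residue_class(seq_window$res_name)
    purrr::map_dfr(seq_len(nrow(seq_window)), function(i) {
      tb <- basins[[cls[i]]]
      if (is.null(tb)) tb <- basins$default
      b <- sample.int(nrow(tb), 1L, prob = tb$weight)
      tibble::tibble(
        res_index = seq_window$index[i],
        basin = tb$name[b],
        phi = wrap_angle(stats::rnorm(1, tb$phi[b], tb$sd[b])),
        psi = wrap_angle(stats::rnorm(1, tb$psi[b], tb$sd[b])),
        omega = 180
      )
    })
  })
}

#' Generate a synthetic fragment conformer library
#'
#' Builds `n` capped conformers of one fragment from independent dihedral
#' draws, rejecting and redrawing any draw whose built conformer exceeds the
#' soft-sphere clash threshold (bounded retries). Stands in for per-fragment
#' molecular-dynamics sampling so the full recombination protocol can run on
#' synthetic input.
#'
#' @param seq An `erf_sequence` for the parent peptide.
#' @param frag An `erf_fragments` table (with `index`) or one of its rows.
#' @param n Number of library members.
#' @param basins Basin model.
#' @param seed RNG seed recorded on the library.
#' @param clash_threshold Maximum accepted soft-sphere score.
#' @param max_retries Redraw budget per member.
#' @param geometry Builder geometry table.
#' @param index Fragment index when `frag` is a full table.
#' @return An `erf_ensemble` with `$fragment_index` and `$seed` set;
#'   provenance records the member id and accepted draw.
#' @export
generate_library <- function(seq, frag, n, basins = default_basins(),
                             seed = 1L, clash_threshold = 1,
                             max_retries = 50L,
                             geometry = default_geometry(), index = NULL) {
  stopifnot(n >= 1L)
  win <- fragment_window(seq, frag, index)
  confs <- vector("list", n)
  draws <- integer(n)
  with_seed_local(seed, {
    for (j in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        dh <- sample_dihedrals(win, basins, seed = NULL)
        conf <- build_conformer(win, dh, geometry)
        if (soft_sphere_score(conf) <= clash_threshold) {
          confs[[j]] <- conf
          draws[j] <- try
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "library member %d: %d draws all exceeded clash threshold %g; consider a looser threshold",
          j, max_retries, clash_threshold), call. = FALSE)
      }
    }
  })
  lib <- as_ensemble(confs,
                     provenance = tibble::tibble(member = seq_len(n),
                                                 draw = draws))
  lib$fragment_index <- if (!is.null(index)) index else frag$index[1]
  lib$seed <- seed
  lib
}
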