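#' Default run configuration for the full protocol
#'
#' Returns the configuration list [run_pipeline()] consumes, populated with
#' the reference study conditions: the tau 210-240 sequence split into
#' three one-residue-overlap fragments, synthetic coil libraries, affinity
#' propagation at preference -30 / damping 0.9, the 80% log-normal energy
#' gate, 20-step refinement, three-set Karplus consensus couplings and
#' theta = 0.1 reweighting. Override any entry via `...` or edit the
#' returned list / a YAML file with the same structure.
#'
#' @param ... Named overrides merged over the defaults (one level deep).
#' @return Named list of class `erf_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    sequence = "SRTPSLPTPPTREPKKVAVVRTPPKSPSSAK",
    numbering_offset = 210L,
    phosphosites = integer(0),        # author numbers, e.g. c(212, 217, 231, 235)
    fragment_lengths = c(11L, 11L, 11L),
    overlap = 1L,
    library = list(source = "synthetic", n_pool = 300L, clash_threshold = 1,
                   paths = NULL),
    # preference calibrated (as in the reference protocol) to yield around
    # 30 exemplars per fragment on the synthetic coil libraries
    clustering = list(preference = -17, damping = 0.9, stride = 1L,
                      max_iter = 1000L, convergence_iter = 50L),
    gating = list(coverage = 0.8),
    refinement = list(n_steps = 20L, max_step = 0.1),
    reweighting = list(theta = 0.1, sigma_floor = 0.1),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("erf_config", "list"))
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror [default_config()].
#' @return An `erf_config` list (defaults filled in for absent keys).
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' @noRd
config_sequence <- function(config) {
  seq_text <- config$sequence
  if (length(config$phosphosites)) {
    chars <- strsplit(seq_text, "")[[1]]
    pos <- config$phosphosites - config$numbering_offset + 1L
    if (any(pos < 1L | pos > length(chars))) {
      stop("phosphosite outside the sequence", call. = FALSE)
    }
    chars[pos] <- tolower(chars[pos])
    seq_text <- paste(chars, collapse = "")
  }
  parse_sequence(seq_text, config$numbering_offset)
}

#' @noRd
log_stage <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full fragment-assembly and reweighting pipeline
#'
#' Executes the stages in order - fragment the sequence, obtain per-fragment
#' conformer libraries (synthetic or from multi-model PDB files), cluster
#' each library to its affinity-propagation exemplars, enumerate all
#' recombinations, score and gate at the log-normal coverage cutoff, refine
#' the survivors, back-calculate consensus 3J couplings, and reweight
#' against the experimental table - writing every stage artifact as a plain
#' file under `outdir` and returning a manifest. Per-stage RNG seeds are
#' derived from the single configured seed by fixed small offsets, so a
#' rerun with the same config and seed reproduces all artifacts.
#'
#' @param config An `erf_config`, see [default_config()].
#' @param outdir Output directory (created if needed).
#' @param experimental Optional experimental observable tibble
#'   (`res_index`, `kind`, `label`, `value`); when `NULL`, reweighting is
#'   skipped unless `synthetic_experiment` is set.
#' @param synthetic_experiment When `TRUE` and no experimental table is
#'   given, a synthetic one is generated from a compactness-biased target
#'   posterior over the gated ensemble (useful for end-to-end exercises).
#' @param quiet Suppress progress messages.
#' @return The run manifest (list of class `erf_manifest`): configuration,
#'   per-stage summaries, artifact paths and checksums.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("erf_run_"),
                         experimental = NULL, synthetic_experiment = FALSE,
                         quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  put <- function(name, path) artifacts[[name]] <<- path

  seqs <- config_sequence(config)
  frags <- fragment_sequence(seqs, config$fragment_lengths, config$overlap)
  log_stage("fragment", sprintf("%d fragments over %d residues",
                                nrow(frags), nrow(seqs)), quiet)
  utils::write.table(as.data.frame(frags), file.path(outdir, "fragments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  put("fragments", file.path(outdir, "fragments.tsv"))

  # libraries
  libs <- vector("list", nrow(frags))
  for (m in seq_len(nrow(frags))) {
    if (identical(config$library$source, "synthetic")) {
      libs[[m]] <- generate_library(
        seqs, frags, n = config$library$n_pool,
        seed = config$seed + 1000L * m,
        clash_threshold = config$library$clash_threshold,
        index = m - 1L)
    } else {
      libs[[m]] <- read_ensemble_pdb(config$library$paths[[m]])
      libs[[m]]$fragment_index <- m - 1L
    }
    path <- file.path(outdir, sprintf("library_f%d.pdb", m))
    write_ensemble_pdb(libs[[m]], path)
    put(sprintf("library_f%d", m), path)
  }
  log_stage("libraries", sprintf("sizes: %s",
                                 paste(vapply(libs, n_conformers, integer(1)),
                                       collapse = ", ")), quiet)

  # clustering
  ex <- lapply(libs, function(lib) {
    select_exemplars(lib,
                     preference = config$clustering$preference,
                     damping = config$clustering$damping,
                     stride = config$clustering$stride,
                     max_iter = config$clustering$max_iter,
                     convergence_iter = config$clustering$convergence_iter)
  })
  ex_sizes <- vapply(ex, n_conformers, integer(1))
  log_stage("cluster", sprintf("exemplars per fragment: %s (preference %g, damping %g)",
                               paste(ex_sizes, collapse = ", "),
                               config$clustering$preference,
                               config$clustering$damping), quiet)
  for (m in seq_along(ex)) {
    path <- file.path(outdir, sprintf("exemplars_f%d.pdb", m))
    write_ensemble_pdb(ex[[m]], path)
    put(sprintf("exemplars_f%d", m), path)
  }

  # assembly
  plan <- assembly_plan(ex, frags)
  raw <- enumerate_assemblies(plan)
  log_stage("assemble", sprintf("raw ensemble: %d conformers",
                                n_conformers(raw)), quiet)

  # energy gate
  scores <- score_ensemble(raw)
  fit <- fit_lognormal(scores)
  cutoff <- coverage_cutoff(fit, config$gating$coverage)
  sparse <- gate_ensemble(raw, scores, cutoff)
  gate_rep <- attr(sparse, "gate_report")
  log_stage("gate", sprintf("cutoff %.4g keeps %d / %d (%.1f%%)",
                            cutoff, gate_rep$n_out, gate_rep$n_in,
                            100 * gate_rep$retention), quiet)
  utils::write.table(
    data.frame(model = seq_along(scores), score = scores),
    file.path(outdir, "raw_scores.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  put("raw_scores", file.path(outdir, "raw_scores.tsv"))

  # refinement
  sparse <- refine_ensemble(sparse, n_steps = config$refinement$n_steps,
                            max_step = config$refinement$max_step)
  log_stage("refine", sprintf("%d-step descent done; mean residual score %.4g",
                              config$refinement$n_steps,
                              mean(sparse$energies)), quiet)
  sparse_path <- file.path(outdir, "sparse_ensemble.pdb")
  write_ensemble_pdb(sparse, sparse_path, weights = TRUE)
  put("sparse_ensemble", sparse_path)

  # observables
  j3 <- predict_j3_with_consensus(sparse, seq = seqs,
                                  sigma_floor = config$reweighting$sigma_floor)
  rgyr <- ensemble_rgyr(sparse)
  utils::write.table(
    data.frame(model = seq_along(rgyr), rgyr = rgyr),
    file.path(outdir, "rgyr.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  put("rgyr", file.path(outdir, "rgyr.tsv"))

  if (is.null(experimental) && isTRUE(synthetic_experiment)) {
    experimental <- synthetic_experimental_table(sparse, j3, rgyr,
                                                 seed = config$seed + 77L)
  }

  reweight <- NULL
  if (!is.null(experimental)) {
    exp_j3 <- experimental[experimental$kind == "J3", , drop = FALSE]
    keys <- match(exp_j3$res_index, j3$observables$res_index)
    if (anyNA(keys)) {
      stop("experimental J3 table references residues without predictions",
           call. = FALSE)
    }
    problem <- reweight_problem(j3$M[, keys, drop = FALSE],
                                exp_j3$value,
                                j3$observables$sigma[keys],
                                prior = sparse$weights,
                                theta = config$reweighting$theta)
    reweight <- solve_reweight(problem)
    log_stage("reweight", sprintf(
      "theta %g: chi2 %.3g, KL %.3g, ESS %.1f, preservation %.1f%%",
      config$reweighting$theta, reweight$chi2, reweight$kl,
      reweight$kish$ess, reweight$preservation), quiet)
    jsonlite::write_json(
      list(weights = reweight$weights, k = reweight$k,
           diagnostics = as.list(glance(reweight))),
      file.path(outdir, "reweight.json"), auto_unbox = TRUE, digits = NA)
    put("reweight", file.path(outdir, "reweight.json"))
    write_ensemble_pdb(new_ensemble(sparse$template, sparse$xyz,
                                    reweight$weights),
                       file.path(outdir, "reweighted_ensemble.pdb"),
                       weights = TRUE)
    put("reweighted_ensemble", file.path(outdir, "reweighted_ensemble.pdb"))
    utils::write.table(as.data.frame(experimental),
                       file.path(outdir, "experimental.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    put("experimental", file.path(outdir, "experimental.tsv"))
  }

  manifest <- structure(list(
    config = unclass(config),
    outdir = outdir,
    stages = list(
      fragments = as.data.frame(frags),
      library_sizes = vapply(libs, n_conformers, integer(1)),
      exemplar_sizes = ex_sizes,
      raw_size = n_conformers(raw),
      gate = gate_rep,
      lognormal = unclass(fit),
      cutoff = cutoff,
      sparse_size = n_conformers(sparse)
    ),
    artifacts = artifacts,
    checksums = vapply(artifacts, function(p) unname(tools::md5sum(p)),
                       character(1)),
    has_reweight = !is.null(reweight)
  ), class = "erf_manifest")
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest$reweight <- reweight
  manifest$sparse <- sparse
  manifest$j3 <- j3
  manifest$rgyr <- rgyr
  manifest$experimental <- experimental
  invisible(manifest)
}

#' Synthetic experimental observables from a compactness-biased posterior
#'
#' Defines a target posterior over the gated ensemble that exponentially
#' favours compact conformers (Boltzmann weights on the radius of
#' gyration), then sets the "experimental" coupling values to the target
#' posterior's ensemble averages. Reweighting against this table should
#' therefore pull the radius-of-gyration mode down - the qualitative
#' behaviour real NMR restraints produced on the tau peptide. Synthetic
#' stand-in: it makes no claim about measured couplings.
#'
#' @param sparse The gated `erf_ensemble`.
#' @param j3 An `erf_j3` prediction for it.
#' @param rgyr Per-conformer radii of gyration.
#' @param bias Inverse-scale (1/Angstrom) of the compactness bias.
#' @param seed Seed for the small jitter applied to the targets.
#' @param jitter_sd Gaussian jitter (Hz) emulating measurement noise.
#' @return Tibble with `res_index`, `kind`, `label`, `value`.
#' @export
synthetic_experimental_table <- function(sparse, j3, rgyr, bias = 1.0,
                                         seed = 1L, jitter_sd = 0.05) {
  wt <- sparse$weights * exp(-bias * (rgyr - min(rgyr)))
  wt <- wt / sum(wt)
  target <- as.vector(wt %*% j3$M)
  with_seed_local(seed, {
    tibble::tibble(
      res_index = j3$observables$res_index,
      kind = "J3",
      label = j3$observables$label,
      value = target + stats::rnorm(length(target), 0, jitter_sd)
    )
  })
}

#' Analysis report of a completed run
#'
#' A pure function of the manifest: per-kind RMSD to experiment before and
#' after reweighting, prior and posterior radius-of-gyration densities with
#' their modes, Kish effective sample size, ensemble preservation, and the
#' gate retention. Written as JSON next to the other artifacts when
#' `write = TRUE`.
#'
#' @param manifest Manifest returned by [run_pipeline()] (with reweighting).
#' @param write Also write `report.json` into the run directory.
#' @return List of class `erf_report`.
#' @export
report <- function(manifest, write = TRUE) {
  stopifnot(inherits(manifest, "erf_manifest"))
  if (!isTRUE(manifest$has_reweight) || is.null(manifest$reweight)) {
    stop("manifest is incomplete: missing stage 'reweight'", call. = FALSE)
  }
  rw <- manifest$reweight
  j3 <- manifest$j3
  rgyr <- manifest$rgyr
  sparse <- manifest$sparse
  exp_tab <- manifest$experimental

  pred_before <- tibble::tibble(
    res_index = j3$observables$res_index, kind = "J3",
    label = j3$observables$label,
    value = ensemble_average(j3$M, sparse$weights))
  keys <- match(exp_tab$res_index[exp_tab$kind == "J3"],
                j3$observables$res_index)
  pred_after <- pred_before
  pred_after$value <- ensemble_average(j3$M, rw$weights)
  rmsd_before <- rmsd_to_experiment(pred_before, exp_tab)
  rmsd_after <- rmsd_to_experiment(pred_after, exp_tab)

  dens_prior <- weighted_density(rgyr, sparse$weights)
  dens_post <- weighted_density(rgyr, rw$weights)

  out <- structure(list(
    rmsd = list(before = as.data.frame(rmsd_before),
                after = as.data.frame(rmsd_after)),
    rgyr = list(prior_mode = dens_prior$mode,
                posterior_mode = dens_post$mode,
                prior = dens_prior, posterior = dens_post),
    kish = rw$kish,
    preservation = rw$preservation,
    kl = rw$kl,
    chi2 = rw$chi2,
    gate = manifest$stages$gate,
    sizes = list(raw = manifest$stages$raw_size,
                 sparse = manifest$stages$sparse_size,
                 exemplars = manifest$stages$exemplar_sizes)
  ), class = "erf_report")
  if (isTRUE(write)) {
    ser <- out
    ser$rgyr$prior <- NULL; ser$rgyr$posterior <- NULL
    jsonlite::write_json(ser, file.path(manifest$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' @export
print.erf_report <- function(x, ...) {
  cat("<erf_report>\n")
  cat(sprintf("  sizes: raw %d -> sparse %d (retention %.1f%%)\n",
              x$sizes$raw, x$sizes$sparse, 100 * x$gate$retention))
  cat(sprintf("  J3 RMSD: %.3f -> %.3f Hz\n",
              x$rmsd$before$rmsd[x$rmsd$before$kind == "J3"],
              x$rmsd$after$rmsd[x$rmsd$after$kind == "J3"]))
  cat(sprintf("  RGYR mode: %.2f -> %.2f Angstrom\n",
              x$rgyr$prior_mode, x$rgyr$posterior_mode))
  cat(sprintf("  Kish ESS %.1f (ratio %.3f), preservation %.1f%%\n",
              x$kish$ess, x$kish$ratio, x$preservation))
  invisible(x)
}
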