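# Small fixtures built in code. The 9-residue toy peptide keeps geometric
# stages fast while exercising proline (no amide H) and glycine (no CB).

TOY_SEQ_TEXT <- "SRTPGLKAV"

# a restrained "true" posterior whose restraint centres equal its own
# ensemble averages (fixed-point iteration), so the reweighting family
# centred at the experimental targets contains it exactly
self_consistent_target <- function(M, k_true, sigma, iters = 500) {
  c_t <- colMeans(M)
  for (i in seq_len(iters)) {
    pr <- reweight_problem(M, c_t, sigma = sigma)
    w <- restraint_weights(k_true, pr)
    c_new <- as.vector(w %*% M)
    if (max(abs(c_new - c_t)) < 1e-12) break
    c_t <- c_new
  }
  stopifnot(max(abs(c_new - c_t)) < 1e-10)
  list(target = c_new, weights = w)
}

select_atoms_for_test <- function(tpl) {
  which(tpl$atom_name %in% c("N", "CA", "C", "O", "CB") & !tpl$is_cap)
}

# absolute angular difference on the circle (degrees)
wrap_delta <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

toy_sequence <- function() parse_sequence(TOY_SEQ_TEXT, 1)

toy_fragments <- function() fragment_sequence(toy_sequence(), c(5, 5), 1)

# one random capped conformer of an arbitrary window
random_conformer <- function(seq = toy_sequence(), seed = 1) {
  build_conformer(seq, sample_dihedrals(seq, seed = seed))
}

# small fragment libraries for assembly tests (built once per test run)
toy_libraries <- function(sizes = c(2, 3), seed = 11) {
  frags <- toy_fragments()
  seqs <- toy_sequence()
  lapply(seq_along(sizes), function(m) {
    generate_library(seqs, frags, n = sizes[m], seed = seed + m, index = m - 1L)
  })
}

# a quick low-volume pipeline configuration for end-to-end tests
toy_config <- function(seed = 3L, ...) {
  default_config(
    sequence = "SRTPSLPTPPTREPKK",
    numbering_offset = 210L,
    fragment_lengths = c(6L, 6L, 6L),
    library = list(n_pool = 25L),
    clustering = list(preference = -10),
    seed = seed,
    ...
  )
}
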