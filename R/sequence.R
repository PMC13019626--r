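## one-letter -> PDB three-letter residue component codes; lowercase marks
## a phosphosite (SEP/TPO/PTR)
AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
PHOSPHO3 <- c(S = "SEP", T = "TPO", Y = "PTR")
AA3TO1 <- c(stats::setNames(names(AA1TO3), AA1TO3),
            SEP = "s", TPO = "t", PTR = "y")
CAP_NAMES <- c("ACE", "NME")

#' Parse an annotated peptide sequence
#'
#' Reads a one-letter amino-acid string in which a lowercase letter marks a
#' phosphosite (allowed on S, T and Y only), and attaches author numbering.
#' The tau fragment studied throughout the package documentation is residues
#' 210-240, `SRTPSLPTPPTREPKKVAVVRTPPKSPSSAK`, optionally phosphorylated at
#' T212, T217, T231 and S235.
#'
#' @param text One-letter sequence; lowercase s/t/y marks a phosphosite.
#' @param numbering_offset Author number of the first residue (e.g. 210).
#' @return A tibble of class `erf_sequence` with columns `index` (0-based),
#'   `author_number`, `code` (uppercase one-letter), `res_name` (PDB
#'   three-letter component code, `SEP`/`TPO`/`PTR` for phosphosites) and
#'   `phospho` (logical).
#' @examples
#' seq <- parse_sequence("SRtPSLPtPPTREPKKVAVVRtPPKsPSSAK", 210)
#' sum(seq$phospho)  # 4
#' @export
parse_sequence <- function(text, numbering_offset = 1L) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  if (length(chars) < 2L) {
    stop("sequence must have at least 2 residues", call. = FALSE)
  }
  upper <- toupper(chars)
  bad <- which(!upper %in% names(AA1TO3))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  phospho <- chars != upper
  bad_p <- which(phospho & !upper %in% names(PHOSPHO3))
  if (length(bad_p)) {
    stop(sprintf(
      "phospho-annotation at position %d ('%s') is only valid on S/T/Y",
      bad_p[1], chars[bad_p[1]]), call. = FALSE)
  }
  out <- tibble::tibble(
    index = seq_along(chars) - 1L,
    author_number = as.integer(numbering_offset) + seq_along(chars) - 1L,
    code = upper,
    res_name = ifelse(phospho, PHOSPHO3[upper], AA1TO3[upper]),
    phospho = phospho
  )
  class(out) <- c("erf_sequence", class(out))
  attr(out, "numbering_offset") <- as.integer(numbering_offset)
  out
}

#' Split a sequence into overlapping fragments
#'
#' Tiles the parent sequence with fragments of the given lengths such that
#' consecutive fragments share exactly `overlap` residues. The tiling must be
#' arithmetically exact: `sum(lengths) - overlap * (n - 1)` has to equal the
#' sequence length, otherwise an error reports the deficit rather than
#' silently adjusting any span. Every cut end receives a cap flag: the first
#' fragment is N-acetylated, the last C-amidated (N-methyl), and interior
#' fragments are capped at both ends.
#'
#' @param seq An `erf_sequence` from [parse_sequence()].
#' @param lengths Integer vector of fragment lengths (each `> overlap`).
#' @param overlap Number of residues shared by consecutive fragments.
#' @return A tibble of class `erf_fragments` with one row per fragment:
#'   `index`, `start`, `end` (0-based half-open span), `n_cap`, `c_cap`,
#'   `overlap_with_next`.
#' @examples
#' seq <- parse_sequence("SRTPSLPTPPTREPKKVAVVRTPPKSPSSAK", 210)
#' fragment_sequence(seq, c(11, 11, 11), overlap = 1)
#' @export
fragment_sequence <- function(seq, lengths, overlap = 1L) {
  stopifnot(inherits(seq, "erf_sequence"), length(lengths) >= 1L)
  lengths <- as.integer(lengths)
  overlap <- as.integer(overlap)
  if (any(lengths < overlap + 1L)) {
    stop("every fragment length must exceed the overlap", call. = FALSE)
  }
  n <- nrow(seq)
  covered <- sum(lengths) - overlap * (length(lengths) - 1L)
  if (covered != n) {
    stop(sprintf(
      paste0("fragment lengths are inconsistent with the sequence: ",
             "sum(lengths) - overlap*(k-1) = %d - %d = %d != %d residues"),
      sum(lengths), overlap * (length(lengths) - 1L), covered, n),
      call. = FALSE)
  }
  starts <- cumsum(c(0L, lengths[-length(lengths)] - overlap))
  k <- length(lengths)
  out <- tibble::tibble(
    index = seq_len(k) - 1L,
    start = starts,
    end = starts + lengths,
    n_cap = TRUE,
    c_cap = TRUE,
    overlap_with_next = c(rep(overlap, k - 1L), 0L)
  )
  class(out) <- c("erf_fragments", class(out))
  out
}

#' Extract one fragment's residue window from a sequence
#' @param seq An `erf_sequence`.
#' @param frag One row of an `erf_fragments` table (or the table plus `index`).
#' @param index Fragment index when `frag` is the full table.
#' @return The `erf_sequence` rows of the fragment, indices re-based to 0.
#' @export
fragment_window <- function(seq, frag, index = NULL) {
  if (!is.null(index)) frag <- frag[frag$index == index, , drop = FALSE]
  stopifnot(nrow(frag) == 1L)
  win <- seq[seq$index >= frag$start & seq$index < frag$end, , drop = FALSE]
  win$index <- win$index - frag$start
  attr(win, "n_cap") <- isTRUE(frag$n_cap)
  attr(win, "c_cap") <- isTRUE(frag$c_cap)
  win
}
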