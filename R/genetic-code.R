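#' @useDynLib phylosel, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Nucleotides in codeml-style order; transitions are T<->C and A<->G.
NUCS <- c("T", "C", "A", "G")
PURINES <- c("A", "G")

#' Construct a genetic code table
#'
#' A genetic code maps the 64 nucleotide triplets to amino acids, partitions
#' them into sense and stop codons, and indexes the sense codons so they can
#' serve as the state space of a codon substitution model.
#'
#' @param codon_to_aa Named character vector of length 64 mapping codons
#'   (triplets over T, C, A, G) to one-letter amino-acid codes, with `"*"`
#'   marking stop codons.  Defaults to the universal code.
#' @return An object of class `genetic_code` with elements:
#'   \describe{
#'     \item{codons}{all 64 codons, in TCAG enumeration order}
#'     \item{aa}{amino acid per codon (named)}
#'     \item{stop_codons}{stop triplets}
#'     \item{sense_codons}{sense triplets, in enumeration order}
#'     \item{codon_index}{named integer vector: sense codon -> 1..n_sense}
#'     \item{pair_type}{n_sense x n_sense integer matrix classifying ordered
#'       single-nucleotide changes: 0 = not reachable in one change, 1 =
#'       synonymous transversion, 2 = synonymous transition, 3 = nonsynonymous
#'       transversion, 4 = nonsynonymous transition}
#'   }
#' @export
genetic_code <- function(codon_to_aa = universal_code_table()) {
  if (length(codon_to_aa) != 64 || is.null(names(codon_to_aa))) {
    stop("codon_to_aa must be a named vector over all 64 codons")
  }
  # enumeration order: first base slowest (TTT, TTC, TTA, TTG, TCT, ...)
  all_codons <- apply(expand.grid(n3 = NUCS, n2 = NUCS, n1 = NUCS)[, 3:1], 1L,
                      paste0, collapse = "")
  if (!setequal(names(codon_to_aa), all_codons)) {
    stop("codon_to_aa names must be the 64 triplets over {T,C,A,G}")
  }
  aa <- codon_to_aa[all_codons]
  stops <- all_codons[aa == "*"]
  sense <- all_codons[aa != "*"]
  n <- length(sense)
  idx <- stats::setNames(seq_len(n), sense)

  nuc_mat <- do.call(rbind, strsplit(sense, ""))
  is_transition <- function(a, b) {
    (a %in% c("T", "C") && b %in% c("T", "C")) ||
      (a %in% PURINES && b %in% PURINES)
  }
  pair_type <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff_pos <- which(nuc_mat[i, ] != nuc_mat[j, ])
      if (length(diff_pos) != 1L) next
      ts <- is_transition(nuc_mat[i, diff_pos], nuc_mat[j, diff_pos])
      syn <- aa[sense[i]] == aa[sense[j]]
      pair_type[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L else
        if (!syn && !ts) 3L else 4L
    }
  }
  structure(
    list(codons = all_codons, aa = aa, stop_codons = stops,
         sense_codons = sense, codon_index = idx, pair_type = pair_type),
    class = "genetic_code"
  )
}

#' The universal genetic code as a codon -> amino-acid table
#'
#' @return Named character vector of length 64; stops are `"*"`.
#' @export
universal_code_table <- function() {
  aa_string <- paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIIMTTTTNNKKSSRR",  # ATT..AGG
    "VVVVAAAADDEEGGGG"   # GTT..GGG
  )
  codons <- apply(expand.grid(n3 = NUCS, n2 = NUCS, n1 = NUCS)[, 3:1], 1L,
                  paste0, collapse = "")
  stats::setNames(strsplit(aa_string, "")[[1]], codons)
}

.code_cache <- new.env(parent = emptyenv())

#' The universal genetic code (memoized)
#'
#' @return A `genetic_code` object with 61 sense codons and 3 stops
#'   (TAA, TAG, TGA).
#' @export
universal_code <- function() {
  if (is.null(.code_cache$universal)) {
    .code_cache$universal <- genetic_code()
  }
  .code_cache$universal
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stops (", paste(x$stop_codons, collapse = ", "),
      ")\n")
  invisible(x)
}
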