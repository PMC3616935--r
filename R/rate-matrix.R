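#' Build a Goldman-Yang codon rate matrix
#'
#' Constructs the instantaneous rate matrix Q of a GY94-style codon model over
#' the sense codons of `code`.  For codons i != j differing at exactly one
#' nucleotide position, the rate is `pi[j]` times a multiplier: 1 for a
#' synonymous transversion, `kappa` for a synonymous transition, `omega` for a
#' nonsynonymous transversion and `kappa * omega` for a nonsynonymous
#' transition.  Codon pairs differing at more than one position have rate 0.
#' The diagonal is set so rows sum to zero and the whole matrix is rescaled so
#' that the expected substitution rate at equilibrium, `-sum(pi * diag(Q))`,
#' equals 1; branch lengths are then in expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Equilibrium sense-codon frequencies (length = number of sense
#'   codons, nonnegative, summing to 1).
#' @param code A `genetic_code`; defaults to the universal code.
#' @param scale If `TRUE` (default) rescale to unit expected rate.
#' @return Object of class `codon_rate_matrix`: list with `Q`, `kappa`,
#'   `omega`, `pi`, and `scale` (the pre-normalization expected rate).
#' @export
build_rate_matrix <- function(kappa, omega, pi, code = universal_code(),
                              scale = TRUE) {
  n <- length(code$sense_codons)
  if (length(kappa) != 1L || !is.finite(kappa) || kappa < 0) {
    stop("kappa must be a single nonnegative number")
  }
  if (length(omega) != 1L || !is.finite(omega) || omega < 0) {
    stop("omega must be a single nonnegative number")
  }
  if (length(pi) != n || any(pi < 0)) {
    stop("pi must be a nonnegative vector over the ", n, " sense codons")
  }
  if (abs(sum(pi) - 1) > 1e-8) {
    stop("pi must sum to 1 (got ", format(sum(pi)), ")")
  }
  mult <- c(1, kappa, omega, kappa * omega)  # indexed by pair_type 1..4
  Q <- matrix(0, n, n)
  nz <- code$pair_type > 0L
  Q[nz] <- mult[code$pair_type[nz]]
  Q <- Q * rep(pi, each = n)        # column-wise pi_j
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale) {
    if (rate <= 0) stop("degenerate rate matrix: zero expected rate")
    Q <- Q / rate
  }
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi, scale = rate),
            class = "codon_rate_matrix")
}

# Symmetric eigendecomposition of a reversible Q (or of an unscaled Q divided
# by an external scale).  Returns C1, C2 with P(t) = C1 %*% diag(exp(lam t)) %*% C2.
codon_eigen <- function(Q, pi) {
  pos <- pi > 0
  if (any(!pos)) stop("eigendecomposition requires strictly positive pi")
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2  # symmetric up to rounding by reversibility
  e <- eigen(B, symmetric = TRUE)
  list(lam = e$values,
       C1 = e$vectors / sq,          # diag(1/sq) %*% V
       C2 = t(e$vectors * sq))       # t(V) %*% diag(sq) ... = t(V) diag(sq)
}

#' Transition probability matrix of a codon model
#'
#' Computes `P(t) = exp(Q t)` through the symmetric eigendecomposition the
#' model's time-reversibility affords.
#'
#' @param rm A `codon_rate_matrix`.
#' @param t Branch length (expected substitutions per codon, >= 0).
#' @return Row-stochastic matrix over sense codons.
#' @export
transition_probs <- function(rm, t) {
  stopifnot(inherits(rm, "codon_rate_matrix"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length t must be a single nonnegative number")
  }
  e <- codon_eigen(rm$Q, rm$pi)
  P <- e$C1 %*% (exp(e$lam * t) * e$C2)
  # clip tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Position-specific (F3x4) codon frequencies from an alignment
#'
#' Estimates nucleotide frequencies separately at the three codon positions
#' from all non-missing codons, forms product frequencies for every sense
#' codon and renormalizes.  A small pseudocount keeps all frequencies strictly
#' positive, which the symmetric eigendecomposition requires.
#'
#' @param alignment A `codon_alignment`.
#' @param code A `genetic_code`.
#' @param mode One of "F3x4" (default), "F61" (empirical codon frequencies),
#'   or "uniform".
#' @return Frequency vector over sense codons.
#' @export
codon_frequencies <- function(alignment, code = universal_code(),
                              mode = c("F3x4", "F61", "uniform")) {
  mode <- match.arg(mode)
  n <- length(code$sense_codons)
  if (mode == "uniform") return(rep(1 / n, n))
  states <- alignment$sites[!is.na(alignment$sites)]
  if (length(states) == 0L) return(rep(1 / n, n))
  nuc_mat <- do.call(rbind, strsplit(code$sense_codons, ""))
  if (mode == "F61") {
    counts <- tabulate(states, nbins = n) + 0.5
    return(counts / sum(counts))
  }
  pos_freq <- matrix(0, 3, 4, dimnames = list(NULL, NUCS))
  for (p in 1:3) {
    tab <- table(factor(nuc_mat[states, p], levels = NUCS))
    pos_freq[p, ] <- (tab + 0.5) / sum(tab + 2)
  }
  pi <- pos_freq[1, nuc_mat[, 1]] * pos_freq[2, nuc_mat[, 2]] *
    pos_freq[3, nuc_mat[, 3]]
  pi / sum(pi)
}
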