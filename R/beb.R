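# Bayes Empirical Bayes site posteriors of positive selection.
#
# The BEB posterior for each codon site integrates the per-site class
# posterior over a uniform prior grid on the model's mixture parameters
# (proportions and the positive-selection omega), with the remaining
# parameters (kappa, branch lengths, and for M8 the beta shapes, for the
# branch-site model omega0) held at their maximum-likelihood estimates.
# The naive empirical Bayes (NEB) posterior plugs in the MLEs directly.

# eigen structures for a set of omegas at a fixed, externally chosen scale
omega_eigens <- function(kappa, pi, omegas, S, code = universal_code()) {
  lapply(omegas, function(w) {
    Q <- build_rate_matrix(kappa, w, pi, code, scale = FALSE)$Q / S
    codon_eigen(Q, pi)
  })
}

beb_grid_centers <- function(n) (seq_len(n) - 0.5) / n

#' Bayes Empirical Bayes posteriors that sites evolve with omega > 1
#'
#' @param alignment A `codon_alignment`.
#' @param tree The tree used for the fit (foreground marking included for
#'   branch-site fits).
#' @param fit A `model_fit` under M2a, M8 or branch_site_A (an alternative
#'   model; null fits are rejected).
#' @param grid_n Grid points per free dimension (default 10).
#' @param omega2_max Upper end of the positive-selection omega grid.
#' @param code Genetic code.
#' @return Object of class `site_posterior`: data frame with `site`
#'   (1-based codon position), `neb` and `beb` (posterior P(omega > 1)),
#'   and `map_class` (most probable class index under BEB averaging);
#'   `gene_id` and `method` details as attributes.
#' @export
beb_site_posteriors <- function(alignment, tree, fit, grid_n = 10,
                                omega2_max = 11, code = universal_code()) {
  stopifnot(inherits(fit, "model_fit"))
  if (!fit$model %in% c("M2a", "M8", "branch_site_A")) {
    stop("BEB needs an alternative-model fit (M2a, M8 or branch_site_A), got ",
         fit$model)
  }
  td <- tree_data(tree, alignment$taxa)
  pat <- alignment_patterns(alignment)
  pi <- fit$pi
  kappa <- fit$kappa
  # postorder branch lengths of the fitted tree
  tdf <- tree_data(fit$tree, alignment$taxa)
  bl <- tdf$bl
  S <- class_matrices(fit$model_spec, kappa, pi, tdf$fg, code)$scale
  n_edge <- length(bl)
  wts <- pat$wts
  npat <- length(wts)
  centers <- beb_grid_centers(grid_n)

  # --- per-omega site log-likelihood columns --------------------------
  if (fit$model == "branch_site_A") {
    om0 <- fit$params$omega0
    om2_grid <- 1 + centers * (omega2_max - 1)
    omegas <- c(om0, 1, om2_grid)
    eigs <- omega_eigens(kappa, pi, omegas, S, code)
    # class columns: [F0, F1, F2a_k (bg om0/fg om2_k), F2b_k (bg 1/fg om2_k)]
    ncfg <- 2 + 2 * grid_n
    edge_eig <- matrix(0L, n_edge, ncfg)
    edge_eig[, 1] <- 1L
    edge_eig[, 2] <- 2L
    for (k in seq_len(grid_n)) {
      edge_eig[, 2 + k] <- ifelse(tdf$fg, 2L + k, 1L)
      edge_eig[, 2 + grid_n + k] <- ifelse(tdf$fg, 2L + k, 2L)
    }
    F <- pruning_sitelik(tdf, pat, bl, eigs, edge_eig, pi)$sitelik
    props <- prop_triangle(grid_n)             # (p0, p1) pairs
    n_class <- 4
    # pass 1: log marginal per grid point (p0, p1, k)
    logm <- matrix(NA_real_, nrow(props), grid_n)
    for (k in seq_len(grid_n)) {
      Fk <- cbind(F[, 1], F[, 2], F[, 2 + k], F[, 2 + grid_n + k])
      logm[, k] <- grid_logmarg_bs(Fk, props, wts)
    }
    W <- exp(logm - max(logm))
    W <- W / sum(W)
    post_pos <- numeric(npat)
    post_class <- matrix(0, npat, n_class)
    for (k in seq_len(grid_n)) {
      Fk <- cbind(F[, 1], F[, 2], F[, 2 + k], F[, 2 + grid_n + k])
      for (g in seq_len(nrow(props))) {
        w <- bs_weights(props[g, 1], props[g, 2])
        sc <- site_class_post(Fk, w)
        post_pos <- post_pos + W[g, k] * (sc[, 3] + sc[, 4])
        post_class <- post_class + W[g, k] * sc
      }
    }
    neb <- {
      w <- fit$model_spec$weights
      FmL <- cbind(F[, 1], F[, 2],
                   bs_neb_cols(tdf, pat, bl, kappa, pi, S, fit, code))
      sc <- site_class_post(FmL, w)
      sc[, 3] + sc[, 4]
    }
  } else if (fit$model == "M2a") {
    om0_grid <- centers
    om2_grid <- 1 + centers * (omega2_max - 1)
    omegas <- c(om0_grid, 1, om2_grid)
    eigs <- omega_eigens(kappa, pi, omegas, S, code)
    edge_eig <- matrix(rep(seq_along(omegas), each = n_edge), n_edge)
    F <- pruning_sitelik(tdf, pat, bl, eigs, edge_eig, pi)$sitelik
    props <- prop_triangle(grid_n)
    logm <- array(NA_real_, c(nrow(props), grid_n, grid_n))  # (props, i0, i2)
    for (i0 in seq_len(grid_n)) {
      for (i2 in seq_len(grid_n)) {
        Fk <- cbind(F[, i0], F[, grid_n + 1], F[, grid_n + 1 + i2])
        logm[, i0, i2] <- grid_logmarg3(Fk, props, wts)
      }
    }
    W <- exp(logm - max(logm))
    W <- W / sum(W)
    post_pos <- numeric(npat)
    post_class <- matrix(0, npat, 3)
    for (i0 in seq_len(grid_n)) {
      for (i2 in seq_len(grid_n)) {
        Fk <- cbind(F[, i0], F[, grid_n + 1], F[, grid_n + 1 + i2])
        for (g in seq_len(nrow(props))) {
          p0 <- props[g, 1]; p1 <- props[g, 2]
          sc <- site_class_post(Fk, c(p0, p1, max(0, 1 - p0 - p1)))
          post_pos <- post_pos + W[g, i0, i2] * sc[, 3]
          post_class <- post_class + W[g, i0, i2] * sc
        }
      }
    }
    neb <- {
      p <- fit$params
      eigsN <- omega_eigens(kappa, pi, c(p$omega0, 1, p$omega2), S, code)
      edgeN <- matrix(rep(1:3, each = n_edge), n_edge)
      Fn <- pruning_sitelik(tdf, pat, bl, eigsN, edgeN, pi)$sitelik
      sc <- site_class_post(Fn, c(p$p0, p$p1, 1 - p$p0 - p$p1))
      sc[, 3]
    }
  } else {  # M8
    p <- fit$params
    db <- discretize_beta(p$p, p$q, fit$K)
    ws_grid <- 1 + centers * (omega2_max - 1)
    omegas <- c(db$omega, ws_grid)
    eigs <- omega_eigens(kappa, pi, omegas, S, code)
    edge_eig <- matrix(rep(seq_along(omegas), each = n_edge), n_edge)
    F <- pruning_sitelik(tdf, pat, bl, eigs, edge_eig, pi)$sitelik
    K <- fit$K
    p0_grid <- centers
    logm <- matrix(NA_real_, grid_n, grid_n)   # (p0, ws)
    beta_part <- log_mean_exp_rows(F[, seq_len(K), drop = FALSE])
    for (i0 in seq_len(grid_n)) {
      for (iw in seq_len(grid_n)) {
        logL <- two_part_mix(beta_part, F[, K + iw], p0_grid[i0])
        logm[i0, iw] <- sum(wts * logL)
      }
    }
    W <- exp(logm - max(logm))
    W <- W / sum(W)
    post_pos <- numeric(npat)
    post_class <- matrix(0, npat, 2)           # (beta bulk, positive class)
    for (i0 in seq_len(grid_n)) {
      for (iw in seq_len(grid_n)) {
        logL <- two_part_mix(beta_part, F[, K + iw], p0_grid[i0])
        s2 <- (1 - p0_grid[i0]) * exp(F[, K + iw] - logL)
        post_pos <- post_pos + W[i0, iw] * s2
        post_class[, 2] <- post_class[, 2] + W[i0, iw] * s2
        post_class[, 1] <- post_class[, 1] + W[i0, iw] * (1 - s2)
      }
    }
    neb <- {
      logL <- two_part_mix(beta_part, {
        eigsN <- omega_eigens(kappa, pi, p$omega_s, S, code)
        pruning_sitelik(tdf, pat, bl, eigsN,
                        matrix(1L, n_edge, 1), pi)$sitelik[, 1]
      }, p$p0)
      fs <- pruning_sitelik(tdf, pat, bl,
                            omega_eigens(kappa, pi, p$omega_s, S, code),
                            matrix(1L, n_edge, 1), pi)$sitelik[, 1]
      (1 - p$p0) * exp(fs - logL)
    }
  }

  map_class <- max.col(post_class, ties.method = "first")
  sites <- seq_along(pat$pattern_of_site)
  out <- data.frame(
    site = sites,
    neb = pmin(pmax(neb[pat$pattern_of_site], 0), 1),
    beb = pmin(pmax(post_pos[pat$pattern_of_site], 0), 1),
    map_class = map_class[pat$pattern_of_site])
  attr(out, "gene_id") <- fit$gene_id
  attr(out, "model") <- fit$model
  class(out) <- c("site_posterior", class(out))
  out
}

# (p0, p1) grid over the triangle p0 + p1 <= 1, cell centers
prop_triangle <- function(n) {
  centers <- beb_grid_centers(n)
  grid <- expand.grid(p0 = centers, p1 = centers)
  grid <- grid[grid$p0 + grid$p1 <= 1 + 1e-9, ]
  as.matrix(grid)
}

# branch-site A weights from (p0, p1)
bs_weights <- function(p0, p1) {
  p2 <- max(0, 1 - p0 - p1)
  c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
}

# per-site class posteriors given class log-liks (npat x n_class) and weights
site_class_post <- function(F, w) {
  w <- pmax(w, 0)
  lw <- ifelse(w > 0, log(w), -Inf)
  A <- sweep(F, 2, lw, "+")
  m <- apply(A, 1, max)
  E <- exp(A - m)
  E / rowSums(E)
}

# log marginal likelihood for each (p0, p1) row given 3 class columns
grid_logmarg3 <- function(F3, props, wts) {
  m <- apply(F3, 1, max)
  E <- exp(F3 - m)                            # npat x 3
  vapply(seq_len(nrow(props)), function(g) {
    p0 <- props[g, 1]; p1 <- props[g, 2]
    L <- E[, 1] * p0 + E[, 2] * p1 + E[, 3] * max(0, 1 - p0 - p1)
    sum(wts * (log(L) + m))
  }, numeric(1))
}

# same, branch-site: 4 class columns with weights from (p0, p1)
grid_logmarg_bs <- function(F4, props, wts) {
  m <- apply(F4, 1, max)
  E <- exp(F4 - m)
  vapply(seq_len(nrow(props)), function(g) {
    w <- bs_weights(props[g, 1], props[g, 2])
    L <- as.numeric(E %*% w)
    sum(wts * (log(L) + m))
  }, numeric(1))
}

log_mean_exp_rows <- function(F) {
  m <- apply(F, 1, max)
  m + log(rowMeans(exp(F - m)))
}

# log(p0 exp(a) + (1 - p0) exp(b)) element-wise
two_part_mix <- function(a, b, p0) {
  m <- pmax(a, b)
  m + log(p0 * exp(a - m) + (1 - p0) * exp(b - m))
}

# NEB class columns 3 and 4 for branch-site A at the MLEs
bs_neb_cols <- function(tdf, pat, bl, kappa, pi, S, fit, code) {
  p <- fit$params
  eigs <- omega_eigens(kappa, pi, c(p$omega0, 1, p$omega2), S, code)
  n_edge <- length(bl)
  edge_eig <- cbind(ifelse(tdf$fg, 3L, 1L), ifelse(tdf$fg, 3L, 2L))
  pruning_sitelik(tdf, pat, bl, eigs, edge_eig, pi)$sitelik
}

#' @export
print.site_posterior <- function(x, ...) {
  cat("Site posteriors (", attr(x, "model"), ", gene ",
      attr(x, "gene_id") %||% "?", "): ", nrow(x), " sites, max BEB = ",
      format(max(x$beb), digits = 3), "\n", sep = "")
  top <- x[x$beb > 0.5, , drop = FALSE]
  if (nrow(top) > 0) {
    cat("Sites with BEB P(omega>1) > 0.5:\n")
    print(utils::head(top, 20), row.names = FALSE, digits = 3)
  }
  invisible(x)
}
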