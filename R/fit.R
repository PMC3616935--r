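# Maximum-likelihood fitting of codon site-class models.

#' Fitting configuration
#'
#' @param start_omega Starting omega values for the multi-start search.
#' @param n_replicates Independent optimizer replicates per start value
#'   (consistency checks; replicates differ only in jittered starting branch
#'   lengths).
#' @param pi_mode Codon-frequency model: "F3x4" (default), "F61", "uniform".
#' @param K Beta categories for M7/M8.
#' @param init_kappa Starting transition/transversion ratio.
#' @param init_bl Starting branch length when the tree carries none.
#' @param optimize_bl If `FALSE`, branch lengths are held at the tree's values
#'   (e.g. at the M0 estimates) instead of being co-optimized.
#' @param omega_max Upper box constraint on any omega during optimization.
#' @param max_iter Maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B convergence factor (times machine epsilon gives the
#'   relative log-likelihood tolerance).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(start_omega = c(0.1, 1.0, 2.0), n_replicates = 1,
                       pi_mode = "F3x4", K = 10, init_kappa = 2,
                       init_bl = 0.1, optimize_bl = TRUE, omega_max = 50,
                       max_iter = 500, factr = 1e8) {
  stopifnot(all(start_omega > 0), n_replicates >= 1, omega_max > 1)
  structure(list(start_omega = start_omega, n_replicates = n_replicates,
                 pi_mode = pi_mode, K = K, init_kappa = init_kappa,
                 init_bl = init_bl, optimize_bl = optimize_bl,
                 omega_max = omega_max, max_iter = max_iter, factr = factr),
            class = "fit_config")
}

#' Fit a codon site-class model by maximum likelihood
#'
#' Maximizes the pruning likelihood over kappa, the model's class parameters
#' and (by default) all branch lengths, using L-BFGS-B on log/logit-transformed
#' parameters.  Branch-length gradients are analytic (two-pass pruning);
#' remaining gradients use central differences.  The search is repeated from
#' each starting omega in `config$start_omega` and the best replicate is kept.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylo`; branch-site models need a foreground marking.
#' @param model Model name: "M0", "M1a", "M2a", "M7", "M8", "branch_site_A",
#'   "branch_site_A_null".
#' @param config A [fit_config()].
#' @param init Optional named list of natural-parameter starting values
#'   (e.g. a previous fit's `params`), used in place of the model defaults
#'   for every start.
#' @param code Genetic code.
#' @return Object of class `model_fit`: `lnL`, `kappa`, `params`, `model`
#'   (realized `site_class_model`), `tree` (with fitted branch lengths),
#'   `restarts`, `converged`, `degenerate`, `pi`, `gene_id`.
#' @export
fit_model <- function(alignment, tree, model = "M0", config = fit_config(),
                      init = NULL, code = universal_code()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  td <- tree_data(tree, alignment$taxa, default_bl = config$init_bl)
  needs_fg <- grepl("^branch_site", model)
  if (needs_fg && !any(td$fg)) {
    stop("branch-site model requires a foreground branch; use tag_foreground()")
  }
  if (needs_fg && all(td$fg)) stop("foreground cannot be the entire tree")
  pat <- alignment_patterns(alignment)
  pi <- codon_frequencies(alignment, code, config$pi_mode)
  info <- model_par_info(model, config$omega_max)
  npar_m <- length(info$names)
  n_edge <- length(td$bl)
  opt_bl <- isTRUE(config$optimize_bl)

  bl0 <- pmax(td$bl, 1e-6)
  lower <- c(info$lower, log(0.05), if (opt_bl) rep(log(1e-7), n_edge))
  upper <- c(info$upper, log(500), if (opt_bl) rep(log(20), n_edge))

  decode <- function(theta) {
    par <- model_par_unpack(model, theta[seq_len(npar_m)])
    kappa <- exp(theta[npar_m + 1])
    bl <- if (opt_bl) exp(theta[npar_m + 1 + seq_len(n_edge)]) else bl0
    list(par = par, kappa = kappa, bl = bl)
  }
  build <- function(d) {
    m <- model_realize(model, d$par, config$K)
    mx <- class_matrices(m, d$kappa, pi, td$fg, code)
    list(m = m, mx = mx)
  }
  cache <- new.env(parent = emptyenv())
  nll <- function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) {
      return(cache$value)
    }
    d <- decode(theta)
    b <- build(d)
    out <- pruning_sitelik(td, pat, d$bl, b$mx$eigs, b$mx$edge_eig, pi)
    v <- -mix_loglik(out$sitelik, b$m$weights, pat$wts)
    cache$theta <- theta
    cache$value <- v
    v
  }
  ngr <- function(theta) {
    d <- decode(theta)
    b <- build(d)
    g <- numeric(length(theta))
    if (opt_bl) {
      out <- pruning_sitelik(td, pat, d$bl, b$mx$eigs, b$mx$edge_eig, pi,
                             want_grad = TRUE, weights = b$m$weights)
      gt <- as.numeric(out$grad_per_pattern %*% pat$wts)  # d lnL / d t
      g[npar_m + 1 + seq_len(n_edge)] <- -gt * d$bl       # chain rule, log t
    }
    # forward differences for model parameters and kappa (f0 is cached from
    # the optimizer's paired objective call)
    f0 <- nll(theta)
    h <- 1e-6
    for (i in seq_len(npar_m + 1)) {
      tp <- theta
      tp[i] <- theta[i] + h
      g[i] <- (nll(tp) - f0) / h
    }
    cache$theta <- theta
    cache$value <- f0
    g
  }

  restarts <- list()
  best <- NULL
  for (s in config$start_omega) {
    par0 <- init %||% model_start_par(model, s)
    if (!is.null(init) && model == "M0") par0$omega <- s
    for (rep in seq_len(config$n_replicates)) {
      bl_start <- if (rep == 1) bl0 else bl0 * exp(stats::runif(n_edge, -.3, .3))
      theta0 <- c(model_par_pack(model, par0), log(config$init_kappa),
                  if (opt_bl) log(bl_start))
      theta0 <- pmin(pmax(theta0, lower), upper)
      opt <- tryCatch(
        stats::optim(theta0, nll, ngr, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = config$max_iter,
                                    factr = config$factr)),
        error = function(e) NULL)
      if (is.null(opt)) {
        restarts[[length(restarts) + 1]] <-
          data.frame(start_omega = s, replicate = rep, lnL = NA_real_,
                     convergence = NA_integer_)
        next
      }
      restarts[[length(restarts) + 1]] <-
        data.frame(start_omega = s, replicate = rep, lnL = -opt$value,
                   convergence = opt$convergence)
      if (is.null(best) || -opt$value > best$lnL + 1e-12) {
        best <- list(lnL = -opt$value, theta = opt$par,
                     convergence = opt$convergence)
      }
    }
  }
  restarts <- do.call(rbind, restarts)
  if (is.null(best)) {
    stop("model fit failed to converge from every start; diagnostics: ",
         paste(utils::capture.output(print(restarts)), collapse = "\n"))
  }
  d <- decode(best$theta)
  realized <- model_realize(model, d$par, config$K)
  fitted_tree <- td$tree
  # map postorder branch lengths back onto the tree's edge order
  tr_post <- ape::reorder.phylo(td$tree, "postorder")
  perm <- match(paste(td$tree$edge[, 1], td$tree$edge[, 2]),
                paste(tr_post$edge[, 1], tr_post$edge[, 2]))
  fitted_tree$edge.length <- d$bl[perm]
  degenerate <- sum(d$bl) < 1e-4
  if (degenerate) {
    warning("tree length collapsed to ~0: no substitutions observed; ",
            "omega is not identifiable")
  }
  structure(list(
    gene_id = alignment$gene_id,
    model = model,
    model_spec = realized,
    lnL = best$lnL,
    kappa = d$kappa,
    params = d$par,
    branch_lengths = d$bl,
    tree = fitted_tree,
    pi = pi,
    restarts = restarts,
    converged = best$convergence == 0,
    degenerate = degenerate,
    K = config$K,
    n_sites = ncol(alignment$sites)
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Codon model fit:", x$model,
      if (!is.null(x$gene_id)) paste0("(", x$gene_id, ")"), "\n")
  cat("  lnL =", format(x$lnL, digits = 10), " kappa =",
      format(x$kappa, digits = 4), "\n")
  cat("  params:", paste(names(x$params), "=",
                         vapply(x$params, function(p) format(p, digits = 4),
                                character(1)), collapse = ", "), "\n")
  cat("  tree length =", format(sum(x$branch_lengths), digits = 4),
      if (x$degenerate) "(degenerate)", "\n")
  invisible(x)
}

#' Choose among candidate trees by M0 likelihood
#'
#' Fits the one-ratio model on every candidate topology and returns the tree
#' with the highest maximized log-likelihood; ties are broken by input order
#' with a message.
#'
#' @param alignment A `codon_alignment`.
#' @param candidate_trees List of `phylo` trees (e.g. species tree and gene
#'   tree), each containing the alignment's taxa.
#' @param config A [fit_config()].
#' @param code Genetic code.
#' @return List with `tree` (the winner), `index`, `lnL` (per candidate),
#'   and `fits` (the per-candidate M0 fits).
#' @export
choose_tree <- function(alignment, candidate_trees, config = fit_config(),
                        code = universal_code()) {
  if (length(candidate_trees) == 0) stop("no candidate trees supplied")
  fits <- lapply(candidate_trees, function(tr)
    fit_model(alignment, tr, "M0", config, code = code))
  lnL <- vapply(fits, function(f) f$lnL, numeric(1))
  top <- which(lnL >= max(lnL) - 1e-8)
  if (length(top) > 1) {
    message("tree choice tied (", paste(top, collapse = ", "),
            "); keeping the first")
  }
  idx <- top[1]
  list(tree = candidate_trees[[idx]], index = idx, lnL = lnL, fits = fits)
}

#' Tree-wide substitution rates from an M0 fit
#'
#' Derives dN and dS totals over the tree from the fitted one-ratio model.
#' The fitted tree length T is in expected substitutions per codon.  The
#' expected fractions of synonymous vs nonsynonymous substitutions come from
#' the fitted Q at equilibrium; the proportions of synonymous and
#' nonsynonymous *sites* are evaluated at omega = 1 (mutational opportunity),
#' so that dN/dS equals the fitted omega.  dN and dS are per nucleotide site
#' (the per-codon totals divided by 3 times the site proportion).
#'
#' @param fit A converged M0 `model_fit`.
#' @param code Genetic code.
#' @return Object of class `rate_estimates`: list/data.frame with `gene_id`,
#'   `omega`, `dN`, `dS`, `tree_length`.
#' @export
estimate_rates <- function(fit, code = universal_code()) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$model != "M0") stop("estimate_rates needs an M0 fit")
  omega <- fit$params$omega
  if (fit$degenerate) {
    warning("degenerate fit: omega not identifiable; rates are zero")
    out <- list(gene_id = fit$gene_id, omega = NA_real_, dN = 0, dS = 0,
                tree_length = sum(fit$branch_lengths))
    class(out) <- "rate_estimates"
    return(out)
  }
  pi <- fit$pi
  Tlen <- sum(fit$branch_lengths)
  # substitution flux split under the fitted model (scaled Q: total flux 1)
  rm_fit <- build_rate_matrix(fit$kappa, omega, pi, code, scale = TRUE)
  syn <- code$pair_type == 1L | code$pair_type == 2L
  flux <- pi * rm_fit$Q
  rho_S <- sum(flux[syn])
  rho_N <- sum(flux[code$pair_type >= 3L])
  # site proportions at omega = 1 (mutational opportunity, codeml convention)
  rm1 <- build_rate_matrix(fit$kappa, 1, pi, code, scale = FALSE)
  flux1 <- pi * rm1$Q
  S_prop <- sum(flux1[syn]) / rm1$scale
  N_prop <- 1 - S_prop
  dS <- if (S_prop > 0) Tlen * rho_S / (3 * S_prop) else 0
  dN <- if (N_prop > 0) Tlen * rho_N / (3 * N_prop) else 0
  if (dS == 0) warning("dS is zero; omega reported from the fit")
  out <- list(gene_id = fit$gene_id, omega = omega, dN = dN, dS = dS,
              tree_length = Tlen)
  class(out) <- "rate_estimates"
  out
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("Rates %s: omega = %.4f, dN = %.4f, dS = %.4f (tree length %.3f)\n",
              x$gene_id %||% "", x$omega, x$dN, x$dS, x$tree_length))
  invisible(x)
}
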