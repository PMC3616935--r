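# Likelihood ratio tests of positive selection and multiple-testing
# correction.

#' Likelihood ratio test between nested model fits
#'
#' The statistic is 2(lnL_alt - lnL_null), clamped at zero when optimizer
#' noise leaves it slightly negative; the p-value comes from the chi-square
#' upper tail.
#'
#' @param fit_alt,fit_null `model_fit` objects (or bare lnL numbers).
#' @param df Degrees of freedom; 2 for the site-model comparisons, 1 for the
#'   branch-site comparison.  Other values require `allow_any_df = TRUE`.
#' @param allow_any_df Permit df outside \{1, 2\}.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt <- function(fit_alt, fit_null, df, allow_any_df = FALSE) {
  lnL_alt <- if (inherits(fit_alt, "model_fit")) fit_alt$lnL else fit_alt
  lnL_null <- if (inherits(fit_null, "model_fit")) fit_null$lnL else fit_null
  if (!allow_any_df && !df %in% c(1, 2)) {
    stop("df must be 1 or 2 (use allow_any_df to override)")
  }
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < 0) {
    if (stat < -1e-2) {
      warning("alternative fit below null (2*dlnL = ", format(stat),
              "); statistic clamped to 0 - consider refitting")
    }
    stat <- 0
  }
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Fit alt warm-started on the null's fitted branch lengths; if it lands
# below the null, refit once starting from the null's optimum (standard
# remedy for a failed nested inequality).
fit_with_floor <- function(alignment, tree, model, config, null_fit, code) {
  base_tree <- tree
  if (!is.null(null_fit)) {
    base_tree <- null_fit$tree
    attr(base_tree, "foreground") <- attr(tree, "foreground")
  }
  fit <- fit_model(alignment, base_tree, model, config, code = code)
  if (!is.null(null_fit) && fit$lnL < null_fit$lnL - 5e-3) {
    cfg2 <- config
    cfg2$start_omega <- 1.0
    init <- augment_null_params(model, null_fit$params)
    refit <- fit_model(alignment, base_tree, model, cfg2, init = init,
                       code = code)
    if (refit$lnL > fit$lnL) fit <- refit
  }
  fit
}

# embed a null model's parameters in the alternative's parameter space
augment_null_params <- function(alt_model, null_params) {
  switch(alt_model,
    M2a = c(null_params[c("p0", "omega0")],
            list(p1 = max(1e-3, 1 - null_params$p0 - 1e-3), omega2 = 1 + 1e-6)),
    M8 = list(p0 = 1 - 1e-3, p = null_params$p, q = null_params$q,
              omega_s = 1 + 1e-6),
    branch_site_A = c(null_params[c("p0", "p1", "omega0")],
                      list(omega2 = 1 + 1e-6)),
    null_params
  )
}

#' Site-model tests of positive selection for one gene
#'
#' Runs the two nested comparisons, M1a vs M2a and M7 vs M8, each a
#' likelihood ratio test with 2 degrees of freedom.  M2a vs M1a tends to be
#' the more robust comparison, M8 vs M7 the more sensitive.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylo`.
#' @param config A [fit_config()].
#' @param tests Which comparisons to run (default both).
#' @param m0_fit Optional M0 `model_fit` whose fitted branch lengths seed
#'   the null-model searches.
#' @param code Genetic code.
#' @return Data frame of class `selection_test_result` rows: `gene_id`,
#'   `test`, `branch`, `lnL_alt`, `lnL_null`, `statistic`, `df`, `p_raw`
#'   (`p_adjusted` is NA until [adjust_pvalues()] over the gene family),
#'   plus the fits in `attr(, "fits")`.
#' @export
site_model_tests <- function(alignment, tree, config = fit_config(),
                             tests = c("M1a_vs_M2a", "M7_vs_M8"),
                             m0_fit = NULL, code = universal_code()) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (!is.null(m0_fit)) {
    fg <- attr(tree, "foreground")
    tree <- m0_fit$tree
    attr(tree, "foreground") <- fg
  }
  rows <- list()
  fits <- list()
  if ("M1a_vs_M2a" %in% tests) {
    f1 <- fit_model(alignment, tree, "M1a", config, code = code)
    f2 <- fit_with_floor(alignment, tree, "M2a", config, f1, code)
    t12 <- lrt(f2, f1, df = 2)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = alignment$gene_id %||% NA_character_, test = "M1a_vs_M2a",
      branch = NA_character_, lnL_alt = f2$lnL, lnL_null = f1$lnL,
      statistic = t12$statistic, df = 2L, p_raw = t12$p,
      p_adjusted = NA_real_)
    fits$M1a <- f1; fits$M2a <- f2
  }
  if ("M7_vs_M8" %in% tests) {
    f7 <- fit_model(alignment, tree, "M7", config, code = code)
    f8 <- fit_with_floor(alignment, tree, "M8", config, f7, code)
    t78 <- lrt(f8, f7, df = 2)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = alignment$gene_id %||% NA_character_, test = "M7_vs_M8",
      branch = NA_character_, lnL_alt = f8$lnL, lnL_null = f7$lnL,
      statistic = t78$statistic, df = 2L, p_raw = t78$p,
      p_adjusted = NA_real_)
    fits$M7 <- f7; fits$M8 <- f8
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("selection_test_result", class(out))
  out
}

#' Branch-site test of positive selection on one foreground branch
#'
#' Fits branch-site model A (omega2 free, >= 1) against its null (omega2
#' fixed at 1) and tests by chi-square with 1 degree of freedom.
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylo`.
#' @param foreground_branch Node label identifying the branch (see
#'   [tag_foreground()]); may be omitted if the tree is already tagged.
#' @param config A [fit_config()].
#' @param m0_fit Optional M0 `model_fit` seeding the null's branch lengths.
#' @param code Genetic code.
#' @return One-row data frame as in [site_model_tests()] with `df = 1`;
#'   fits in `attr(, "fits")`.
#' @export
branch_site_test <- function(alignment, tree, foreground_branch = NULL,
                             config = fit_config(), m0_fit = NULL,
                             code = universal_code()) {
  if (!is.null(m0_fit)) {
    fg <- attr(tree, "foreground")
    tree2 <- m0_fit$tree
    attr(tree2, "foreground") <- fg
    tree <- tree2
  }
  if (!is.null(foreground_branch)) {
    tree <- tag_foreground(tree, foreground_branch)
  }
  if (length(foreground_nodes(tree)) == 0) {
    stop("no foreground branch; supply foreground_branch or tag the tree")
  }
  f0 <- fit_model(alignment, tree, "branch_site_A_null", config, code = code)
  f1 <- fit_with_floor(alignment, tree, "branch_site_A", config, f0, code)
  tt <- lrt(f1, f0, df = 1)
  out <- data.frame(
    gene_id = alignment$gene_id %||% NA_character_, test = "branch_site",
    branch = foreground_branch %||%
      paste(node_labels_of(tree, foreground_nodes(tree)), collapse = "+"),
    lnL_alt = f1$lnL, lnL_null = f0$lnL, statistic = tt$statistic, df = 1L,
    p_raw = tt$p, p_adjusted = NA_real_)
  attr(out, "fits") <- list(branch_site_A_null = f0, branch_site_A = f1)
  class(out) <- c("selection_test_result", class(out))
  out
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up FDR by default; Holm and Bonferroni are
#' available.  The correction family should match the study design: all
#' genes for the site tests, all gene-by-branch combinations for the
#' branch-site tests.
#'
#' @param p_values Numeric vector in [0, 1].
#' @param method "BH" (default), "holm", or "bonferroni".
#' @return Adjusted p-values, monotone in the input.
#' @export
adjust_pvalues <- function(p_values, method = c("BH", "holm", "bonferroni")) {
  method <- match.arg(method)
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}
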