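# The statistical layer: Spearman rank correlations, Kruskal-Wallis tests,
# neighbor-rate correlations, and the combined association report.

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of average ranks (ties averaged).  The
#' two-sided p-value uses the t approximation for n >= `exact_below`, full
#' enumeration of all n! orderings for n <= 8, and `n_perm` sampled
#' permutations for intermediate n.
#'
#' @param x,y Paired numeric vectors; pairs with a missing member are
#'   dropped listwise.
#' @param exact_below Sample size below which a permutation p-value replaces
#'   the t approximation (default 10).
#' @param n_perm Number of sampled permutations when exact enumeration is
#'   infeasible.
#' @return List with `rho`, `p`, `n`, and `method`.
#' @export
spearman <- function(x, y, exact_below = 10, n_perm = 2e4) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= exact_below) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else if (n <= 8) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    rho_perm <- replicate(n_perm, stats::cor(rx, sample(ry)))
    p <- (sum(abs(rho_perm) >= abs(rho) - 1e-12) + 1) / (n_perm + 1)
    method <- "sampled permutation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- if (pos > 1) sub[, seq_len(pos - 1), drop = FALSE] else NULL
    right <- if (pos < n) sub[, pos:(n - 1), drop = FALSE] else NULL
    cbind(left, n, right)
  }))
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper over `stats::kruskal.test` (tie-corrected H, chi-square
#' p-value with k - 1 degrees of freedom) that drops empty groups with a
#' warning and reports group medians.  If all values are tied the statistic
#' is reported as 0 with a warning.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 nonempty groups after missing-value
#'   removal).
#' @return List with `H`, `df`, `p`, `group_medians`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 nonempty groups")
  if (length(keep) != sum(keep)) {
    # silently dropped missing pairs; empty-group warning below if triggered
  }
  med <- c(tapply(values, groups, stats::median))
  if (stats::sd(values) == 0) {
    warning("all values tied: Kruskal-Wallis H reported as 0")
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1,
                group_medians = med, n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, group_medians = med, n = length(values))
}

#' Run the full association battery
#'
#' Joins per-gene rate estimates with network centralities and gene
#' annotations and computes, per rate variable (omega, dN, dS):
#' Spearman correlations against closeness, betweenness, degree and protein
#' length; Kruskal-Wallis tests across the cell-type, process and function
#' classifications; and the Spearman correlation of each network gene's rate
#' with the mean rate of its immediate interaction partners.  Genes outside
#' the network enter only the non-topology analyses (listwise deletion per
#' statistic).  P-values are reported uncorrected.
#'
#' @param rates Data frame with columns `gene_id`, `omega`, `dN`, `dS`.
#' @param centrality_table Data frame from [centralities()] (column `node`
#'   matching `gene_id`).
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param network A `pathway_network` (for neighbor means).
#' @return Object of class `association_report`: list with data frames
#'   `spearman_results`, `kruskal_results`, `neighbor_results`, and the
#'   joined `table`.
#' @export
run_associations <- function(rates, centrality_table, annotations, network) {
  df <- merge(rates, annotations, by = "gene_id", all.x = TRUE)
  df <- merge(df, centrality_table, by.x = "gene_id", by.y = "node",
              all.x = TRUE)
  if (nrow(df) == 0) stop("empty join between rates and annotations")
  df <- df[order(df$gene_id), , drop = FALSE]

  rate_vars <- c("omega", "dN", "dS")
  topo_vars <- c("closeness", "betweenness", "degree", "protein_length")
  class_vars <- c("cell_type", "process", "fun")

  sp <- list()
  for (rv in rate_vars) {
    for (tv in topo_vars) {
      res <- tryCatch(spearman(df[[tv]], df[[rv]]),
                      warning = function(w) {
                        suppressWarnings(spearman(df[[tv]], df[[rv]]))
                      })
      sp[[length(sp) + 1]] <- data.frame(
        x = tv, y = rv, rho = res$rho, p = res$p, n = res$n)
    }
  }
  sp <- do.call(rbind, sp)

  kw <- list()
  for (rv in rate_vars) {
    for (cv in class_vars) {
      res <- kruskal_wallis(df[[rv]], df[[cv]])
      kw[[length(kw) + 1]] <- data.frame(
        classification = cv, y = rv, H = res$H, df = res$df, p = res$p,
        n = res$n)
    }
  }
  kw <- do.call(rbind, kw)

  nb <- list()
  for (rv in rate_vars) {
    vals <- stats::setNames(df[[rv]], df$gene_id)[network$nodes]
    names(vals) <- network$nodes
    nbm <- neighbor_mean(network, vals)
    res <- tryCatch(spearman(vals, nbm), warning = function(w) {
      suppressWarnings(spearman(vals, nbm))
    })
    nb[[length(nb) + 1]] <- data.frame(
      y = rv, rho = res$rho, p = res$p, n = res$n)
  }
  nb <- do.call(rbind, nb)

  structure(list(spearman_results = sp, kruskal_results = kw,
                 neighbor_results = nb, table = df),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  cat("Association report over", nrow(x$table), "genes\n")
  cat("Spearman correlations:\n")
  print(x$spearman_results, row.names = FALSE, digits = 4)
  cat("Kruskal-Wallis tests:\n")
  print(x$kruskal_results, row.names = FALSE, digits = 4)
  cat("Neighbor-mean rate correlations:\n")
  print(x$neighbor_results, row.names = FALSE, digits = 4)
  invisible(x)
}
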