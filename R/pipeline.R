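# Pipeline orchestration: per-gene fits -> rates -> selection tests ->
# corrections -> network topology -> associations -> report bundle.

#' Pipeline run configuration
#'
#' Either real inputs (`alignments`, `tree`/`candidate_trees`, `network`,
#' `annotations`) or a [simulation_spec()] — not both.
#'
#' @param alignments List of `codon_alignment` objects.
#' @param tree A `phylo` used for every gene.
#' @param candidate_trees Optional list of trees; the per-gene M0 likelihood
#'   picks one (species-vs-gene-tree choice).
#' @param network A `pathway_network` (optional; topology analyses skipped
#'   without it).
#' @param annotations Annotation data frame.
#' @param sim_spec A `simulation_spec`; mutually exclusive with real inputs.
#' @param fit `fit_config()` used for all model fits.
#' @param run_site_tests Run M1a/M2a and M7/M8 per gene.
#' @param run_branch_site Run branch-site tests.
#' @param foreground_branches Node labels of foreground branches for the
#'   branch-site family; defaults to all labelled internal branches.
#' @param correction "BH", "holm" or "bonferroni".
#' @param compute_beb Compute BEB site posteriors for significant
#'   (adjusted p < `beb_alpha`) alternative fits.
#' @param beb_alpha Significance cutoff for triggering BEB.
#' @param outdir Output directory for the report bundle (optional).
#' @param checkpoint_dir Directory for per-gene fit checkpoints (optional);
#'   reruns reuse existing checkpoints.
#' @param seed Seed for any randomized step.
#' @return List of class `run_config`.
#' @export
run_config <- function(alignments = NULL, tree = NULL, candidate_trees = NULL,
                       network = NULL, annotations = NULL, sim_spec = NULL,
                       fit = fit_config(), run_site_tests = TRUE,
                       run_branch_site = TRUE, foreground_branches = NULL,
                       correction = "BH", compute_beb = FALSE,
                       beb_alpha = 0.05, outdir = NULL,
                       checkpoint_dir = NULL, seed = 1L) {
  has_real <- !is.null(alignments)
  if (has_real && !is.null(sim_spec)) {
    stop("supply real inputs or a simulation spec, not both")
  }
  if (!has_real && is.null(sim_spec)) {
    stop("supply alignments (+ tree) or a simulation spec")
  }
  if (has_real && is.null(tree) && is.null(candidate_trees)) {
    stop("real inputs need a tree or candidate_trees")
  }
  structure(list(alignments = alignments, tree = tree,
                 candidate_trees = candidate_trees, network = network,
                 annotations = annotations, sim_spec = sim_spec, fit = fit,
                 run_site_tests = run_site_tests,
                 run_branch_site = run_branch_site,
                 foreground_branches = foreground_branches,
                 correction = correction, compute_beb = compute_beb,
                 beb_alpha = beb_alpha, outdir = outdir,
                 checkpoint_dir = checkpoint_dir, seed = as.integer(seed)),
            class = "run_config")
}

# labelled internal nodes (excluding the root) -> default branch-site family
labelled_internal_branches <- function(tree) {
  if (is.null(tree$node.label)) return(character(0))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ids <- ntip + seq_len(tree$Nnode)
  ok <- ids != root & nzchar(tree$node.label)
  tree$node.label[ok]
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) per-gene M0 fit (with tree choice if candidates are
#' given) and rate estimation; (2) site-model tests (df = 2 each), corrected
#' across genes per test; (3) branch-site tests (df = 1) for every
#' configured foreground branch, corrected across gene-by-branch
#' combinations; (4) optional BEB site posteriors for significant
#' alternatives; (5) network centralities; (6) the association battery;
#' (7) report bundle via [write_report()] when `outdir` is set.  Per-gene
#' failures are quarantined into the `failures` table rather than aborting
#' the batch.
#'
#' @param config A [run_config()].
#' @param code Genetic code.
#' @return List of class `pipeline_result` with `per_gene`,
#'   `selection_tests`, `associations`, `centralities`, `network`, `failures`,
#'   `fits` (per-gene M0 fits), `truth` (for simulated studies), and
#'   `site_posteriors`.
#' @export
run_pipeline <- function(config, code = universal_code()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (!is.null(config$sim_spec)) {
    study <- simulate_study(config$sim_spec, code)
    alignments <- study$alignments
    tree <- study$tree
    network <- study$network
    annotations <- study$annotations
    truth <- study$truth
    candidate_trees <- NULL
  } else {
    alignments <- config$alignments
    tree <- config$tree
    network <- config$network
    annotations <- config$annotations
    truth <- NULL
    candidate_trees <- config$candidate_trees
  }
  gene_ids <- vapply(alignments, function(a) a$gene_id, character(1))
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids in alignments")
  names(alignments) <- gene_ids
  failures <- data.frame(gene_id = character(0), stage = character(0),
                         message = character(0))
  note_failure <- function(gene, stage, e) {
    failures[nrow(failures) + 1L, ] <<- list(gene, stage, conditionMessage(e))
  }

  # ---- stage 1: M0 fits and rates -----------------------------------
  fits <- list()
  rates_rows <- list()
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    fit <- tryCatch({
      cp <- checkpoint_path(config, aln$gene_id, "M0")
      if (!is.null(cp) && file.exists(cp)) {
        fit_from_json(cp, aln, code)
      } else {
        f <- if (!is.null(candidate_trees)) {
          choice <- choose_tree(aln, candidate_trees, config$fit, code)
          choice$fits[[choice$index]]
        } else {
          fit_model(aln, tree, "M0", config$fit, code = code)
        }
        if (!is.null(cp)) fit_to_json(f, cp)
        f
      }
    }, error = function(e) {
      note_failure(aln$gene_id, "M0", e)
      NULL
    })
    if (is.null(fit)) next
    fits[[aln$gene_id]] <- fit
    r <- suppressWarnings(estimate_rates(fit, code))
    rates_rows[[aln$gene_id]] <- data.frame(
      gene_id = aln$gene_id, omega = r$omega, dN = r$dN, dS = r$dS,
      tree_length = r$tree_length)
  }
  rates <- do.call(rbind, c(rates_rows, list(make.row.names = FALSE)))
  if (is.null(rates) || nrow(rates) == 0) stop("every gene failed the M0 stage")

  # ---- stages 2-3: selection tests ----------------------------------
  test_rows <- list()
  if (isTRUE(config$run_site_tests)) {
    for (aln in alignments[names(fits)]) {
      st <- tryCatch(site_model_tests(aln, tree, config$fit,
                                      m0_fit = fits[[aln$gene_id]], code = code),
                     error = function(e) {
                       note_failure(aln$gene_id, "site_tests", e)
                       NULL
                     })
      if (!is.null(st)) test_rows[[length(test_rows) + 1]] <- as.data.frame(st)
    }
  }
  bs_rows <- list()
  bs_fits <- list()
  if (isTRUE(config$run_branch_site)) {
    fg <- config$foreground_branches %||% labelled_internal_branches(tree)
    for (aln in alignments[names(fits)]) {
      for (br in fg) {
        bs <- tryCatch(branch_site_test(aln, tree, br, config$fit,
                                        m0_fit = fits[[aln$gene_id]],
                                        code = code),
                       error = function(e) {
                         note_failure(aln$gene_id,
                                      paste0("branch_site:", br), e)
                         NULL
                       })
        if (!is.null(bs)) {
          bs_rows[[length(bs_rows) + 1]] <- as.data.frame(bs)
          bs_fits[[paste(aln$gene_id, br, sep = "|")]] <-
            attr(bs, "fits")$branch_site_A
        }
      }
    }
  }
  site_tests <- if (length(test_rows)) do.call(rbind, test_rows) else NULL
  bs_tests <- if (length(bs_rows)) do.call(rbind, bs_rows) else NULL
  # correction families: per site test across genes; branch-site across
  # all gene x branch combinations
  if (!is.null(site_tests)) {
    for (tt in unique(site_tests$test)) {
      sel <- site_tests$test == tt
      site_tests$p_adjusted[sel] <-
        adjust_pvalues(site_tests$p_raw[sel], config$correction)
    }
  }
  if (!is.null(bs_tests)) {
    bs_tests$p_adjusted <- adjust_pvalues(bs_tests$p_raw, config$correction)
  }
  selection_tests <- rbind(site_tests, bs_tests)

  # ---- stage 4: BEB for significant alternatives --------------------
  site_posteriors <- NULL
  if (isTRUE(config$compute_beb) && !is.null(bs_tests)) {
    sp_rows <- list()
    sig <- bs_tests[!is.na(bs_tests$p_adjusted) &
                      bs_tests$p_adjusted < config$beb_alpha, , drop = FALSE]
    for (j in seq_len(nrow(sig))) {
      key <- paste(sig$gene_id[j], sig$branch[j], sep = "|")
      fitj <- bs_fits[[key]]
      if (is.null(fitj)) next
      tr <- tag_foreground(tree, sig$branch[j])
      sp <- tryCatch(
        beb_site_posteriors(alignments[[sig$gene_id[j]]], tr, fitj,
                            code = code),
        error = function(e) {
          note_failure(sig$gene_id[j], "BEB", e)
          NULL
        })
      if (!is.null(sp)) {
        sp_rows[[length(sp_rows) + 1]] <- data.frame(
          gene_id = sig$gene_id[j], branch = sig$branch[j],
          site = sp$site, neb = sp$neb, beb = sp$beb)
      }
    }
    if (length(sp_rows)) site_posteriors <- do.call(rbind, sp_rows)
  }

  # ---- stages 5-6: topology and associations ------------------------
  cent <- NULL
  associations <- NULL
  per_gene <- rates
  if (!is.null(annotations)) {
    per_gene <- merge(per_gene, annotations, by = "gene_id", all.x = TRUE)
  }
  if (!is.null(network)) {
    cent <- centralities(network)
    per_gene <- merge(per_gene, cent, by.x = "gene_id", by.y = "node",
                      all.x = TRUE)
    if (!is.null(annotations)) {
      associations <- run_associations(rates, cent, annotations, network)
    }
  }
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL

  result <- structure(list(
    per_gene = per_gene, selection_tests = selection_tests,
    associations = associations, centralities = cent, network = network,
    failures = failures, fits = fits, truth = truth,
    site_posteriors = site_posteriors), class = "pipeline_result")
  if (!is.null(config$outdir)) {
    write_report(result, config$outdir)
    if (nrow(failures) > 0) {
      utils::write.table(failures, file.path(config$outdir, "failures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", nrow(x$per_gene), "genes,",
      if (!is.null(x$selection_tests)) nrow(x$selection_tests) else 0,
      "selection tests,", nrow(x$failures), "failures\n")
  invisible(x)
}

# ---- checkpointing ----------------------------------------------------

checkpoint_path <- function(config, gene_id, model) {
  if (is.null(config$checkpoint_dir)) return(NULL)
  if (!dir.exists(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  file.path(config$checkpoint_dir, paste0(gene_id, "_", model, ".json"))
}

#' Serialize a model fit to JSON (for pipeline checkpointing)
#'
#' @param fit A `model_fit`.
#' @param path Output JSON file.
#' @export
fit_to_json <- function(fit, path) {
  payload <- list(
    gene_id = fit$gene_id, model = fit$model, lnL = fit$lnL,
    kappa = fit$kappa, params = fit$params,
    branch_lengths = fit$branch_lengths,
    tree = write_tree(fit$tree), pi = fit$pi,
    restarts = fit$restarts, converged = fit$converged,
    degenerate = fit$degenerate, K = fit$K, n_sites = fit$n_sites)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model fit from JSON
#'
#' @param path JSON file from [fit_to_json()].
#' @param alignment The alignment the fit belongs to (consistency check).
#' @param code Genetic code.
#' @return A `model_fit`.
#' @export
fit_from_json <- function(path, alignment = NULL, code = universal_code()) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(alignment) && !identical(p$gene_id, alignment$gene_id)) {
    stop("checkpoint gene_id ", p$gene_id, " does not match alignment ",
         alignment$gene_id)
  }
  tree <- read_tree(text = p$tree)
  structure(list(
    gene_id = p$gene_id, model = p$model,
    model_spec = model_realize(p$model, as.list(p$params), p$K %||% 10),
    lnL = p$lnL, kappa = p$kappa, params = as.list(p$params),
    branch_lengths = p$branch_lengths, tree = tree, pi = p$pi,
    restarts = as.data.frame(p$restarts), converged = p$converged,
    degenerate = p$degenerate, K = p$K %||% 10, n_sites = p$n_sites),
    class = "model_fit")
}
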