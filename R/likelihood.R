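# Tree bookkeeping and the pruning likelihood.

# Postorder indexing of an ape phylo for the C++ core.  Drops tree tips absent
# from `taxa`, reorders edges postorder, and returns 0-based parent/child ids,
# branch lengths, the foreground flag per edge, and the tip row order.
tree_data <- function(tree, taxa, default_bl = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(taxa %in% tree$tip.label)) {
    stop("alignment taxa absent from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  }
  fg_nodes <- attr(tree, "foreground")
  extra <- setdiff(tree$tip.label, taxa)
  if (length(extra) > 0) {
    fg_labels <- node_labels_of(tree, fg_nodes)
    tree <- ape::drop.tip(tree, extra)
    attr(tree, "foreground") <- nodes_by_label(tree, fg_labels)
    fg_nodes <- attr(tree, "foreground")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_bl, nrow(tree$edge))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(
    tree = tree,
    parent = tr$edge[, 1] - 1L,
    child = tr$edge[, 2] - 1L,
    n_node = ntip + tr$Nnode,
    root = ntip,                       # ape convention: root id = ntip + 1
    bl = tr$edge.length,
    fg = tr$edge[, 2] %in% (fg_nodes %||% integer(0)),
    ntip = ntip,
    tip_label = tr$tip.label
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label of nodes by ape id (tips by tip.label, internals by node.label).
node_labels_of <- function(tree, ids) {
  if (is.null(ids) || length(ids) == 0) return(character(0))
  ntip <- length(tree$tip.label)
  vapply(ids, function(i) {
    if (i <= ntip) tree$tip.label[i]
    else (tree$node.label %||% rep("", tree$Nnode))[i - ntip]
  }, character(1))
}

nodes_by_label <- function(tree, labels) {
  if (length(labels) == 0) return(integer(0))
  ntip <- length(tree$tip.label)
  all_labels <- c(tree$tip.label, tree$node.label %||% rep("", tree$Nnode))
  idx <- match(labels, all_labels)
  if (anyNA(idx)) stop("label not found in tree: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Mark a branch as foreground by the label of its child node
#'
#' Branch-site models distinguish one "foreground" branch, on which a class of
#' sites may evolve with omega >= 1, from the "background" rest of the tree.
#' A branch is addressed by the label of the node (tip or internal) below it.
#'
#' @param tree A `phylo` tree with tip and/or node labels.
#' @param labels Character vector of node labels; the branches above these
#'   nodes become the foreground.  `character(0)` clears the marking.
#' @return The tree with its foreground attribute set.
#' @export
tag_foreground <- function(tree, labels) {
  attr(tree, "foreground") <- nodes_by_label(tree, labels)
  tree
}

#' @rdname tag_foreground
#' @export
foreground_nodes <- function(tree) attr(tree, "foreground") %||% integer(0)

# Compress alignment columns into unique site patterns.
alignment_patterns <- function(alignment) {
  sites <- alignment$sites                      # ntaxa x nsite, NA = missing
  key <- apply(sites, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat_id <- match(key, key[first])
  states <- sites[, first, drop = FALSE]
  states[is.na(states)] <- -1L
  storage.mode(states) <- "integer"
  list(states = states - ifelse(states >= 0, 1L, 0L),  # 0-based, -1 missing
       wts = as.numeric(tabulate(pat_id, nbins = sum(first))),
       pattern_of_site = pat_id)
}

# Low-level mixture likelihood: returns per-pattern per-class log-likelihoods
# (and optionally the analytic branch-length gradient contracted with class
# responsibilities).  `eigs` is a list of codon_eigen structures sharing `pi`;
# `edge_eig` maps (edge, class) -> eigen index.
pruning_sitelik <- function(td, pat, bl, eigs, edge_eig, pi,
                            want_grad = FALSE, weights = numeric(0)) {
  # tipstate rows must follow ape tip numbering 1..ntip
  row_order <- match(td$tip_label, rownames(pat$states))
  states <- pat$states[row_order, , drop = FALSE]
  cpp_pruning(states, td$parent, td$child, td$n_node, td$root,
              bl, eigs, edge_eig, pi, want_grad, weights)
}

# log-sum-exp mixture of per-class site log-likelihoods
mix_loglik <- function(sitelik, weights, wts) {
  lw <- ifelse(weights > 0, log(weights), -Inf)
  m <- apply(sitelik, 1, max)
  keep <- is.finite(m)
  site_log <- rep(-Inf, nrow(sitelik))
  site_log[keep] <- m[keep] +
    log(rowSums(exp(sitelik[keep, , drop = FALSE] - m[keep] +
                      rep(lw, each = sum(keep)))))
  sum(wts * site_log)
}

#' Log-likelihood of a single alignment site under per-branch rate matrices
#'
#' Computes the pruning likelihood of one codon site.  The root placement is
#' immaterial because the model is time-reversible (pulley principle).
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylo` tree containing the alignment's taxa.
#' @param rate_matrix A single `codon_rate_matrix` applied to every branch, or
#'   a list with one entry per row of `tree$edge` (per-branch matrices must
#'   share the equilibrium distribution).
#' @param site 1-based codon site index.
#' @return The log-likelihood of that site.
#' @export
site_log_likelihood <- function(alignment, tree, rate_matrix, site) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (site < 1 || site > ncol(alignment$sites)) stop("site index out of range")
  td <- tree_data(tree, alignment$taxa)
  sub <- alignment
  sub$sites <- alignment$sites[, site, drop = FALSE]
  pat <- alignment_patterns(sub)
  if (inherits(rate_matrix, "codon_rate_matrix")) {
    eigs <- list(codon_eigen(rate_matrix$Q, rate_matrix$pi))
    edge_eig <- matrix(1L, length(td$bl), 1)
    pi <- rate_matrix$pi
  } else {
    stopifnot(is.list(rate_matrix), length(rate_matrix) == length(td$bl))
    # rate_matrix is in tree$edge order of the *pruned* tree; recompute the
    # postorder permutation to align with td
    tr <- ape::reorder.phylo(td$tree, "postorder")
    perm <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                  paste(td$tree$edge[, 1], td$tree$edge[, 2]))
    eigs <- lapply(rate_matrix[perm], function(rm) codon_eigen(rm$Q, rm$pi))
    edge_eig <- matrix(seq_along(eigs), ncol = 1)
    pi <- rate_matrix[[1]]$pi
  }
  out <- pruning_sitelik(td, pat, td$bl, eigs, edge_eig, pi)
  as.numeric(out$sitelik[1, 1])
}

#' Log-likelihood of an alignment under a site-class model
#'
#' Evaluates the mixture likelihood sum over sites: each site's likelihood is
#' the class-weight-weighted sum of pruning likelihoods under the class-
#' specific omega (with foreground branches using the class's foreground
#' omega for branch-site models).
#'
#' @param alignment A `codon_alignment`.
#' @param tree A `phylo`; branch-site models require a foreground marking
#'   (see [tag_foreground()]).
#' @param model A `site_class_model` (see [site_class_model()]).
#' @param kappa Transition/transversion ratio.
#' @param pi Sense-codon frequencies.
#' @param code Genetic code.
#' @return Total log-likelihood.
#' @export
model_log_likelihood <- function(alignment, tree, model, kappa, pi,
                                 code = universal_code()) {
  stopifnot(inherits(model, "site_class_model"))
  td <- tree_data(tree, alignment$taxa)
  if (model$needs_foreground && !any(td$fg)) {
    stop("branch-site model requires a foreground branch; use tag_foreground()")
  }
  pat <- alignment_patterns(alignment)
  mx <- class_matrices(model, kappa, pi, td$fg, code)
  out <- pruning_sitelik(td, pat, td$bl, mx$eigs, mx$edge_eig, pi)
  mix_loglik(out$sitelik, model$weights, pat$wts)
}

# Build eigen structures and the (edge, class) -> eigen map for a realized
# site-class model.  All class rate matrices share kappa and pi and a common
# scale so branch lengths stay in expected substitutions per codon under the
# background mixture.
class_matrices <- function(model, kappa, pi, fg_edges, code = universal_code()) {
  om_bg <- model$omega_bg
  om_fg <- model$omega_fg %||% om_bg
  omegas <- sort(unique(c(om_bg, om_fg)))
  mu <- vapply(omegas, function(w)
    build_rate_matrix(kappa, w, pi, code, scale = FALSE)$scale, numeric(1))
  S <- sum(model$weights * mu[match(om_bg, omegas)])
  if (S <= 0) stop("degenerate model: zero expected substitution rate")
  eigs <- lapply(omegas, function(w) {
    Q <- build_rate_matrix(kappa, w, pi, code, scale = FALSE)$Q / S
    codon_eigen(Q, pi)
  })
  n_edge <- length(fg_edges)
  nclass <- length(om_bg)
  edge_eig <- matrix(0L, n_edge, nclass)
  for (c in seq_len(nclass)) {
    bg_i <- match(om_bg[c], omegas)
    fg_i <- match(om_fg[c], omegas)
    edge_eig[, c] <- ifelse(fg_edges, fg_i, bg_i)
  }
  list(eigs = eigs, edge_eig = edge_eig, scale = S, omegas = omegas)
}
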