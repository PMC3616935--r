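# Forward simulation of codon alignments and synthetic study generation:
# pathway networks with planted topology-rate structure and classified gene
# sets, for end-to-end validation of the pipeline.

#' The nine-mammal fixture tree
#'
#' A binary unrooted topology (root trifurcation) over human, chimpanzee,
#' gorilla, orangutan, macaque, marmoset, mouse, rat and dog, with branch
#' lengths in expected substitutions per codon chosen to resemble mammalian
#' coding-sequence divergence (tree length ~1.85).  Internal nodes carry
#' stable labels; the branches above the nodes labelled `hominid` (the
#' great-ape ancestor) and `rodent` (the mouse-rat ancestor) are the usual
#' foreground candidates for branch-site tests.
#'
#' @param foreground Optional node label(s) to mark as foreground.
#' @return A `phylo` with node labels and a foreground attribute.
#' @export
mammal9_fixture <- function(foreground = NULL) {
  txt <- paste0(
    "((((((human:0.02,chimpanzee:0.02)hc:0.012,gorilla:0.035)hcg:0.03,",
    "orangutan:0.07)hominid:0.03,macaque:0.11)catarrhine:0.04,",
    "marmoset:0.16)primate:0.12,(mouse:0.26,rat:0.26)rodent:0.28,dog:0.4);")
  tree <- read_tree(text = txt)
  if (!is.null(foreground)) tree <- tag_foreground(tree, foreground)
  tree
}

#' Simulation specification
#'
#' Bundles everything the study generator needs.  Defaults mirror the study
#' design the package targets: a nine-mammal tree, 54 genes of which 30 form
#' a connected 81-edge signaling network, purifying selection throughout
#' (true omega clamped below 1), and a negative dependence of omega on
#' network closeness plus functional-class shifts.
#'
#' @param tree Phylogeny for sequence simulation.
#' @param n_genes Total genes in the study.
#' @param n_network Genes inside the interaction network.
#' @param n_edges Network edge count.
#' @param n_codons Codon sites per gene alignment.
#' @param kappa Transition/transversion ratio used in simulation.
#' @param base_omega Intercept of the true-omega model.
#' @param closeness_slope Slope on (centered) closeness; positive values
#'   plant the negative omega-closeness relationship.
#' @param group_shifts Named numeric vector of functional-class omega shifts.
#' @param noise_sd Standard deviation of gene-level omega noise.
#' @param omega_range Clamp for true omegas (purifying regime).
#' @param seed Mandatory integer seed.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(tree = mammal9_fixture(), n_genes = 54,
                            n_network = 30, n_edges = 81, n_codons = 300,
                            kappa = 2, base_omega = 0.5,
                            closeness_slope = 2.5,
                            group_shifts = c(enzyme = 0.2,
                                             ion_channel_exchanger = 0.18,
                                             chaperone = -0.2,
                                             g_protein = -0.15,
                                             opsin = -0.08),
                            noise_sd = 0.05,
                            omega_range = c(0.005, 0.95), seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  stopifnot(n_codons >= 1, noise_sd >= 0, n_genes >= 1,
            n_network >= 2, n_genes >= n_network)
  structure(list(tree = tree, n_genes = n_genes, n_network = n_network,
                 n_edges = n_edges, n_codons = n_codons, kappa = kappa,
                 base_omega = base_omega, closeness_slope = closeness_slope,
                 group_shifts = group_shifts, noise_sd = noise_sd,
                 omega_range = omega_range, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a codon alignment under a site-class model
#'
#' Per site: draw a class by its weight, draw the root codon from pi, and
#' evolve down the tree with the class's transition probabilities (foreground
#' branches use the class's foreground omega).  Deterministic given the seed.
#'
#' @param tree A `phylo` (foreground-tagged for branch-site models).
#' @param model A `site_class_model` (from [site_class_model()]).
#' @param kappa Transition/transversion ratio.
#' @param pi Sense-codon frequencies (default uniform).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @param gene_id Identifier stored on the alignment.
#' @param code Genetic code.
#' @return A `codon_alignment` (with the per-site true class in
#'   `attr(, "site_class")`).
#' @export
simulate_alignment <- function(tree, model, kappa, pi = NULL, n_codons,
                               seed, gene_id = "sim", code = universal_code()) {
  stopifnot(inherits(model, "site_class_model"), n_codons >= 1)
  set.seed(seed)
  ns <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / ns, ns)
  td <- tree_data(tree, tree$tip.label)
  if (model$needs_foreground && !any(td$fg)) {
    stop("branch-site model requires a foreground-tagged tree")
  }
  mx <- class_matrices(model, kappa, pi, td$fg, code)
  # P matrices per (edge, class), cached per eigen index
  n_edge <- length(td$bl)
  P_cache <- new.env(parent = emptyenv())
  getP <- function(e, cls) {
    key <- paste(mx$edge_eig[e, cls], format(td$bl[e], digits = 15))
    if (is.null(P_cache[[key]])) {
      eg <- mx$eigs[[mx$edge_eig[e, cls]]]
      P <- eg$C1 %*% (exp(eg$lam * td$bl[e]) * eg$C2)
      P[P < 0] <- 0
      P_cache[[key]] <- P / rowSums(P)
    }
    P_cache[[key]]
  }
  site_class <- sample.int(length(model$weights), n_codons, replace = TRUE,
                           prob = model$weights)
  states <- matrix(NA_integer_, td$n_node, n_codons)
  root_1b <- td$root + 1L
  states[root_1b, ] <- sample.int(ns, n_codons, replace = TRUE, prob = pi)
  # preorder = reverse postorder: parents before children
  for (e in rev(seq_len(n_edge))) {
    par <- td$parent[e] + 1L
    chi <- td$child[e] + 1L
    for (cls in unique(site_class)) {
      cols <- which(site_class == cls)
      P <- getP(e, cls)
      ps <- states[par, cols]
      for (s in unique(ps)) {
        sel <- cols[ps == s]
        states[chi, sel] <- sample.int(ns, length(sel), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  }
  tip_states <- states[seq_len(td$ntip), , drop = FALSE]
  rownames(tip_states) <- td$tip_label
  # restore the original taxon order of the input tree
  tip_states <- tip_states[tree$tip.label, , drop = FALSE]
  aln <- codon_alignment(gene_id, tree$tip.label, tip_states)
  attr(aln, "site_class") <- site_class
  aln
}

#' Random connected simple network
#'
#' A uniform random spanning tree over the nodes plus random extra edges up
#' to the target edge count; guarantees connectedness.
#'
#' @param nodes Node names.
#' @param n_edges Total edges (between n-1 and n(n-1)/2).
#' @return A `pathway_network`.
#' @export
random_connected_network <- function(nodes, n_edges) {
  n <- length(nodes)
  if (n_edges < n - 1 || n_edges > n * (n - 1) / 2) {
    stop("edge count ", n_edges, " infeasible for ", n, " nodes")
  }
  # random recursive tree for connectedness
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  have <- matrix(FALSE, n, n)
  have[edges] <- TRUE
  have[edges[, c(2, 1)]] <- TRUE
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  free <- all_pairs[!have[all_pairs], , drop = FALSE]
  extra <- n_edges - (n - 1)
  if (extra > 0) {
    pick <- free[sample.int(nrow(free), extra), , drop = FALSE]
    edges <- rbind(edges, pick)
  }
  pathway_network(cbind(nodes[edges[, 1]], nodes[edges[, 2]]))
}

#' Simulate a complete study
#'
#' Builds a connected random pathway network, assigns gene classifications,
#' plants a true-omega structure (negative in network closeness, shifted by
#' functional class, plus noise, clamped into the purifying regime), then
#' simulates one codon alignment per gene under M0 at its true omega.  Genes
#' beyond the network represent the retinoid-cycle/developmental periphery
#' and receive no topology term.
#'
#' @param spec A [simulation_spec()].
#' @param code Genetic code.
#' @return List with `alignments` (list of `codon_alignment`), `network`,
#'   `annotations` (data frame), `truth` (data frame with true omegas and
#'   closeness), and `tree`.
#' @export
simulate_study <- function(spec, code = universal_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  gene_ids <- sprintf("G%02d", seq_len(n))
  in_net <- seq_len(spec$n_network)
  network <- random_connected_network(gene_ids[in_net], spec$n_edges)
  cent <- centralities(network)
  clo <- stats::setNames(cent$closeness, cent$node)

  funs <- FUNCTIONS
  fun_assign <- factor(
    funs[1 + (seq_len(n) - 1) %% length(funs)], levels = funs)
  cell_assign <- factor(
    CELL_TYPES[1 + (seq_len(n) - 1) %% 3], levels = CELL_TYPES)
  process_assign <- factor(
    ifelse(seq_len(n) %in% in_net, "phototransduction",
           ifelse(seq_len(n) %% 2 == 0, "retinoid_cycle", "development")),
    levels = PROCESSES)

  shifts <- rep(0, n)
  if (length(spec$group_shifts) > 0) {
    sh <- spec$group_shifts[as.character(fun_assign)]
    sh[is.na(sh)] <- 0
    shifts <- as.numeric(sh)
  }
  clo_term <- rep(0, n)
  clo_term[in_net] <- spec$closeness_slope *
    (clo[gene_ids[in_net]] - mean(clo))
  noise <- stats::rnorm(n, 0, spec$noise_sd)
  true_omega <- pmin(pmax(spec$base_omega - clo_term + shifts + noise,
                          spec$omega_range[1]), spec$omega_range[2])

  protein_length <- pmax(50L, as.integer(round(
    spec$n_codons * exp(stats::rnorm(n, 0, 0.3)))))
  annotations <- data.frame(
    gene_id = gene_ids, cell_type = cell_assign, process = process_assign,
    fun = fun_assign, protein_length = protein_length,
    stringsAsFactors = FALSE)

  gene_seeds <- spec$seed + 1000L * seq_len(n)   # per-gene substreams
  alignments <- vector("list", n)
  names(alignments) <- gene_ids
  for (i in seq_len(n)) {
    m <- site_class_model("M0", omega = true_omega[i])
    alignments[[i]] <- simulate_alignment(
      spec$tree, m, spec$kappa, pi = NULL, n_codons = spec$n_codons,
      seed = gene_seeds[i], gene_id = gene_ids[i], code = code)
  }
  truth <- data.frame(
    gene_id = gene_ids, true_omega = true_omega,
    in_network = seq_len(n) %in% in_net,
    closeness = unname(clo[gene_ids]),
    fun = fun_assign, stringsAsFactors = FALSE)
  list(alignments = alignments, network = network,
       annotations = annotations, truth = truth, tree = spec$tree)
}
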