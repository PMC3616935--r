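test_that("the nine-mammal fixture has the right taxa and structure", {
  tree <- mammal9_fixture()
  expect_length(tree$tip.label, 9)
  expect_setequal(tree$tip.label,
                  c("human", "chimpanzee", "gorilla", "orangutan", "macaque",
                    "marmoset", "mouse", "rat", "dog"))
  # hominid and rodent ancestors are addressable by stable labels
  hom <- nodes_by_label(tree, "hominid")
  rod <- nodes_by_label(tree, "rodent")
  ntip <- length(tree$tip.label)
  expect_true(all(c(hom, rod) > ntip))
  desc <- ape::extract.clade(tree, hom)$tip.label
  expect_setequal(desc, c("human", "chimpanzee", "gorilla", "orangutan"))
  desc_r <- ape::extract.clade(tree, rod)$tip.label
  expect_setequal(desc_r, c("mouse", "rat"))
  # unrooted convention: a root trifurcation, binary elsewhere
  expect_identical(tree$Nnode, 7L)
  tagged <- mammal9_fixture(foreground = "hominid")
  expect_identical(node_labels_of(tagged, foreground_nodes(tagged)),
                   "hominid")
})

test_that("simulation is deterministic and zero-length trees copy the root", {
  tree <- mammal9_fixture()
  m <- site_class_model("M0", omega = 0.3)
  a1 <- simulate_alignment(tree, m, 2, NULL, 50, seed = 80)
  a2 <- simulate_alignment(tree, m, 2, NULL, 50, seed = 80)
  expect_identical(a1$sites, a2$sites)
  a3 <- simulate_alignment(tree, m, 2, NULL, 50, seed = 81)
  expect_false(identical(a1$sites, a3$sites))

  frozen <- tree
  frozen$edge.length[] <- 0
  a0 <- simulate_alignment(frozen, m, 2, NULL, 30, seed = 82)
  for (i in 2:9) expect_identical(a0$sites[i, ], a0$sites[1, ])
})

test_that("equilibrium simulation reproduces pi within sampling error", {
  tree <- read_tree(text = "(A:0.05,B:0.05);")
  m <- site_class_model("M0", omega = 0.5)
  n <- 6000
  aln <- simulate_alignment(tree, m, 2, NULL, n, seed = 83)
  counts <- tabulate(aln$sites, nbins = 61)
  p_hat <- counts / sum(counts)
  se <- sqrt((1 / 61) * (1 - 1 / 61) / (2 * n))
  expect_lt(max(abs(p_hat - 1 / 61)), 3.5 * se)
})

test_that("realized substitutions per branch match the branch length", {
  # one long branch: expected substitutions per codon = t under unit scaling
  tree <- read_tree(text = "(A:0.0,B:0.5);")
  m <- site_class_model("M0", omega = 0.4)
  n <- 4000
  aln <- simulate_alignment(tree, m, 2, NULL, n, seed = 84)
  # count realized state changes between the two tips (lower bound on
  # substitution events, close at moderate t)
  changed <- mean(aln$sites[1, ] != aln$sites[2, ])
  # expected proportion of sites with at least one visible change
  rm <- build_rate_matrix(2, 0.4, uniform_pi())
  P <- transition_probs(rm, 0.5)
  p_change <- 1 - mean(diag(P))
  se <- sqrt(p_change * (1 - p_change) / n)
  expect_lt(abs(changed - p_change), 4 * se)
})

test_that("simulated alignments round-trip through the FASTA parser", {
  tree <- mammal9_fixture()
  m <- site_class_model("M1a", p0 = 0.8, omega0 = 0.25)
  aln <- simulate_alignment(tree, m, 2, NULL, 40, seed = 85, gene_id = "rt")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path, gene_id = "rt")
  expect_identical(back$sites, aln$sites)
  expect_identical(back$taxa, aln$taxa)
})

test_that("random networks are connected with the exact edge count", {
  set.seed(86)
  for (i in 1:5) {
    net <- random_connected_network(sprintf("n%02d", 1:30), 81)
    expect_identical(nrow(net$edges), 81L)
    expect_length(net$nodes, 30)
    expect_equal(igraph::components(net$graph)$no, 1)
  }
  expect_error(random_connected_network(paste0("n", 1:10), 5), "infeasible")
  expect_error(random_connected_network(paste0("n", 1:4), 20), "infeasible")
})

test_that("simulate_study plants the topology-rate structure it reports", {
  spec <- simulation_spec(n_genes = 12, n_network = 8, n_edges = 12,
                          n_codons = 30, noise_sd = 0, group_shifts = c(),
                          seed = 87)
  study <- simulate_study(spec)
  expect_length(study$alignments, 12)
  expect_identical(nrow(study$truth), 12L)
  expect_identical(sum(study$truth$in_network), 8L)
  # noise-free: true omega is a decreasing function of closeness
  tn <- study$truth[study$truth$in_network, ]
  expect_equal(suppressWarnings(spearman(tn$closeness, tn$true_omega))$rho, -1)
  # all alignments valid and inside the purifying regime
  expect_true(all(study$truth$true_omega < 1))
  expect_true(all(vapply(study$alignments, function(a) ncol(a$sites),
                         numeric(1)) == 30))
  # annotations validate against the schema
  expect_silent(phylosel:::validate_annotations(study$annotations))
})

test_that("zero-slope, zero-shift studies carry no planted structure", {
  spec <- simulation_spec(n_genes = 10, n_network = 8, n_edges = 10,
                          n_codons = 20, closeness_slope = 0,
                          group_shifts = c(), noise_sd = 0, seed = 88)
  study <- simulate_study(spec)
  expect_equal(diff(range(study$truth$true_omega)), 0)
})

test_that("study generation is reproducible per gene", {
  spec <- simulation_spec(n_genes = 6, n_network = 4, n_edges = 5,
                          n_codons = 25, seed = 89)
  s1 <- simulate_study(spec)
  s2 <- simulate_study(spec)
  for (g in names(s1$alignments)) {
    expect_identical(s1$alignments[[g]]$sites, s2$alignments[[g]]$sites)
  }
  expect_identical(s1$truth$true_omega, s2$truth$true_omega)
  key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_identical(key(s1$network$edges), key(s2$network$edges))
})
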