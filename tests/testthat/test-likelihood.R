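test_that("two-taxon site likelihood equals the closed form", {
  tree <- read_tree(text = "(A:0.1,B:0.15);")
  rm <- build_rate_matrix(2, 0.3, uniform_pi())
  aln <- codon_alignment("pair", c("A", "B"), matrix(c(5L, 37L), 2, 1))
  got <- site_log_likelihood(aln, tree, rm, 1)
  P <- transition_probs(rm, 0.25)   # total path length between the tips
  expect_equal(got, log(rm$pi[5] * P[5, 37]), tolerance = 1e-10)
})

test_that("per-branch rate matrices are honored (two-taxon closed form)", {
  tree <- read_tree(text = "(A:0.1,B:0.15);")
  pi <- uniform_pi()
  rm1 <- build_rate_matrix(2, 0.2, pi)
  rm2 <- build_rate_matrix(2, 1.5, pi)
  aln <- codon_alignment("pair", c("A", "B"), matrix(c(5L, 37L), 2, 1))
  # map matrices onto tree$edge rows by their child tip
  ntip <- 2
  per_branch <- lapply(tree$edge[, 2], function(chi) {
    if (tree$tip.label[chi] == "A") rm1 else rm2
  })
  got <- site_log_likelihood(aln, tree, per_branch, 1)
  PA <- transition_probs(rm1, 0.1)
  PB <- transition_probs(rm2, 0.15)
  want <- log(sum(pi * PA[, 5] * PB[, 37]))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("pruning equals exhaustive state enumeration on a quartet", {
  tree <- quartet_tree()
  rm <- build_rate_matrix(2, 0.4, uniform_pi())
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.4),
                            2, NULL, 5, seed = 42, gene_id = "quartet")
  for (s in 1:5) {
    got <- site_log_likelihood(aln, tree, rm, s)
    states <- aln$sites[, s]
    expect_equal(got, brute_quartet_loglik(states, rm), tolerance = 1e-8)
  }
})

test_that("a missing cell marginalizes over that tip's states", {
  tree <- read_tree(text = "((A:0.1,B:0.2):0.1,C:0.25);")
  rm <- build_rate_matrix(1.8, 0.5, uniform_pi())
  base <- codon_alignment("toy", c("A", "B", "C"),
                          matrix(c(4L, 18L, NA), 3, 1))
  got <- site_log_likelihood(base, tree, rm, 1)
  per_state <- vapply(1:61, function(s) {
    a <- base
    a$sites[3, 1] <- s
    site_log_likelihood(a, tree, rm, 1)
  }, numeric(1))
  m <- max(per_state)
  expect_equal(got, m + log(sum(exp(per_state - m))), tolerance = 1e-8)
})

test_that("a missing tip is likelihood-equivalent to pruning that tip", {
  tree <- read_tree(text = "((A:0.1,B:0.2):0.1,C:0.25);")
  rm <- build_rate_matrix(1.8, 0.5, uniform_pi())
  with_missing <- codon_alignment("toy", c("A", "B", "C"),
                                  matrix(c(4L, 18L, NA), 3, 1))
  l3 <- site_log_likelihood(with_missing, tree, rm, 1)
  dropped <- ape::drop.tip(tree, "C")
  pair <- codon_alignment("toy", c("A", "B"), matrix(c(4L, 18L), 2, 1))
  l2 <- site_log_likelihood(pair, dropped, rm, 1)
  expect_equal(l3, l2, tolerance = 1e-8)
})

test_that("log-likelihood is invariant under re-rooting (pulley principle)", {
  tree <- quartet_tree()
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.3),
                            2, NULL, 20, seed = 9, gene_id = "root")
  m <- site_class_model("M0", omega = 0.3)
  ll <- model_log_likelihood(aln, tree, m, kappa = 2, pi = uniform_pi())
  for (og in c("A", "C", "D")) {
    rerooted <- ape::root(ape::unroot(tree), og, resolve.root = TRUE)
    ll2 <- model_log_likelihood(aln, rerooted, m, kappa = 2,
                                pi = uniform_pi())
    expect_equal(ll2, ll, tolerance = 1e-6)
  }
})

test_that("M0 mixture reduces to summed single-class site likelihoods", {
  tree <- quartet_tree()
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.2),
                            2, NULL, 8, seed = 3, gene_id = "m0")
  m <- site_class_model("M0", omega = 0.2)
  total <- model_log_likelihood(aln, tree, m, kappa = 2, pi = uniform_pi())
  rm <- build_rate_matrix(2, 0.2, uniform_pi())
  per_site <- vapply(1:8, function(s) site_log_likelihood(aln, tree, rm, s),
                     numeric(1))
  expect_equal(total, sum(per_site), tolerance = 1e-8)
})

test_that("branch-site null collapses class 2b into the neutral class", {
  tree <- tag_foreground(quartet_tree(), "A")
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.5),
                            2, NULL, 15, seed = 11, gene_id = "bs")
  p0 <- 0.55; p1 <- 0.25; om0 <- 0.2
  null <- site_class_model("branch_site_A_null", p0 = p0, p1 = p1,
                           omega0 = om0)
  l_null <- model_log_likelihood(aln, tree, null, kappa = 2,
                                 pi = uniform_pi())
  # same model rewritten with 3 classes: class 2b (bg 1 / fg 1) folded into
  # the neutral class
  w <- null$weights
  collapsed <- structure(list(
    name = "manual", omega_bg = c(om0, 1, om0), omega_fg = c(om0, 1, 1),
    weights = c(w[1], w[2] + w[4], w[3]), needs_foreground = TRUE),
    class = "site_class_model")
  l_collapsed <- model_log_likelihood(aln, tree, collapsed, kappa = 2,
                                      pi = uniform_pi())
  expect_equal(l_null, l_collapsed, tolerance = 1e-8)
})

test_that("with a zero-length foreground branch the null collapses to M1a", {
  tree <- tag_foreground(read_tree(
    text = "((A:0.0,B:0.2):0.1,C:0.25);"), "A")
  aln <- codon_alignment("z", c("A", "B", "C"),
                         matrix(c(4L, 18L, 25L, 4L, 4L, 4L), 3, 2))
  p0 <- 0.6; p1 <- 0.3; om0 <- 0.15
  null <- site_class_model("branch_site_A_null", p0 = p0, p1 = p1,
                           omega0 = om0)
  w <- null$weights
  m1a_like <- site_class_model("M1a", p0 = w[1] + w[3], omega0 = om0)
  l_bs <- model_log_likelihood(aln, tree, null, kappa = 2, pi = uniform_pi())
  l_m1a <- model_log_likelihood(aln, tree, m1a_like, kappa = 2,
                                pi = uniform_pi())
  expect_equal(l_bs, l_m1a, tolerance = 1e-8)
})

test_that("taxa absent from the tree are rejected", {
  tree <- read_tree(text = "(A:0.1,B:0.1);")
  aln <- codon_alignment("bad", c("A", "Z"), matrix(c(1L, 2L), 2, 1))
  rm <- build_rate_matrix(2, 1, uniform_pi())
  expect_error(site_log_likelihood(aln, tree, rm, 1), "absent from tree")
})

test_that("branch-site models demand a tagged tree", {
  tree <- quartet_tree()
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.5),
                            2, NULL, 4, seed = 2, gene_id = "fg")
  m <- site_class_model("branch_site_A", p0 = 0.5, p1 = 0.3, omega0 = 0.2,
                        omega2 = 2)
  expect_error(model_log_likelihood(aln, tree, m, 2, uniform_pi()),
               "foreground")
})
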