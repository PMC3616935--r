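test_that("spearman matches hand-derived rank correlations", {
  expect_equal(spearman(1:3, 3:1)$rho, -1)
  # d^2 = (0,1,1,0): rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman(1:4, c(1, 3, 2, 4))$rho, 0.8)
  self <- spearman(c(2, 9, 4, 7, 5), c(2, 9, 4, 7, 5))
  expect_equal(self$rho, 1)
  expect_lt(self$p, 0.05)
})

test_that("spearman p-values: exact enumeration agrees with cor.test", {
  set.seed(700)
  for (i in 1:5) {
    x <- rnorm(7)
    y <- rnorm(7)
    ours <- spearman(x, y)
    expect_identical(ours$method, "exact permutation")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    # cor.test uses the exact null distribution of rho for n < 10, no ties
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("spearman exact p matches a sampled-permutation estimate", {
  set.seed(701)
  x <- rnorm(8)
  y <- 0.7 * x + rnorm(8, 0, 0.6)
  exact <- spearman(x, y)$p
  rx <- rank(x); ry <- rank(y)
  rho0 <- cor(rx, ry)
  mc <- mean(replicate(1e4, abs(cor(rx, sample(ry))) >= abs(rho0) - 1e-12))
  se <- sqrt(mc * (1 - mc) / 1e4)
  expect_lt(abs(exact - mc), 4 * se + 1e-4)
})

test_that("spearman uses the t approximation for larger n", {
  set.seed(702)
  x <- rnorm(30)
  y <- x + rnorm(30)
  ours <- spearman(x, y)
  expect_identical(ours$method, "t-approximation")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_lt(ours$p, 0.01)
})

test_that("spearman guards degenerate input", {
  expect_error(spearman(1:2, 2:1), "at least 3")
  expect_warning(res <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_true(is.na(res$rho))
  # listwise deletion of incomplete pairs
  r <- spearman(c(1, 2, 3, NA, 5), c(5, 4, 3, 2, NA))
  expect_identical(r$n, 3L)
})

test_that("kruskal_wallis reproduces the hand-computed H = 27/7", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                        factor(rep(c("a", "b"), each = 3)))
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  expect_equal(res$p, pchisq(27 / 7, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(unname(res$group_medians), c(2, 5))
})

test_that("kruskal_wallis df is k - 1 and degenerate ties are handled", {
  set.seed(703)
  v <- rnorm(30)
  g3 <- factor(rep(c("x", "y", "z"), 10))
  expect_identical(kruskal_wallis(v, g3)$df, 2L)
  g8 <- factor(rep(letters[1:8], length.out = 32))
  expect_identical(kruskal_wallis(rnorm(32), g8)$df, 7L)
  expect_warning(res <- kruskal_wallis(rep(2, 6), g3[1:6]), "tied")
  expect_equal(res$H, 0)
  expect_error(kruskal_wallis(v, factor(rep("only", 30))), "2 nonempty")
})

test_that("two-group kruskal_wallis is monotone in the rank-sum statistic", {
  set.seed(704)
  for (i in 1:10) {
    v <- rnorm(16)
    g <- factor(rep(c("a", "b"), each = 8))
    kw <- kruskal_wallis(v, g)$H
    w <- wilcox.test(v[g == "a"], v[g == "b"], exact = FALSE,
                     correct = FALSE)$statistic
    # H is a monotone transform of |W - n1 n2 / 2|
    expect_equal(kw, 12 / (16 * 17) * 2 * (unname(w) - 32)^2 / 8 + 0,
                 tolerance = 1e-8)
  }
})

make_assoc_fixture <- function(seed = 1, n_extra = 10) {
  set.seed(seed)
  net <- random_connected_network(sprintf("g%02d", 1:20), 40)
  ct <- centralities(net)
  ids <- c(ct$node, sprintf("x%02d", seq_len(n_extra)))
  n <- length(ids)
  omega <- pmin(pmax(0.6 - 0.8 * c(ct$closeness, rep(mean(ct$closeness),
                                                     n_extra)) +
                       rnorm(n, 0, 0.03), 0.01), 0.95)
  rates <- data.frame(gene_id = ids, omega = omega, dN = omega * 0.5,
                      dS = rep(0.5, n) + rnorm(n, 0, 0.01))
  ann <- data.frame(
    gene_id = ids,
    cell_type = factor(phylosel:::CELL_TYPES[1 + seq_len(n) %% 3],
                       levels = phylosel:::CELL_TYPES),
    process = factor(phylosel:::PROCESSES[1 + seq_len(n) %% 3],
                     levels = phylosel:::PROCESSES),
    fun = factor(phylosel:::FUNCTIONS[1 + seq_len(n) %% 9],
                 levels = phylosel:::FUNCTIONS),
    protein_length = 200 + (seq_len(n) * 37) %% 500)
  list(rates = rates, cent = ct, ann = ann, net = net)
}

test_that("the association battery has the full 12 + 9 + 3 layout", {
  fx <- make_assoc_fixture(710)
  rep <- run_associations(fx$rates, fx$cent, fx$ann, fx$net)
  expect_identical(nrow(rep$spearman_results), 12L)
  expect_identical(nrow(rep$kruskal_results), 9L)
  expect_identical(nrow(rep$neighbor_results), 3L)
  expect_setequal(unique(rep$spearman_results$x),
                  c("closeness", "betweenness", "degree", "protein_length"))
  expect_setequal(unique(rep$kruskal_results$classification),
                  c("cell_type", "process", "fun"))
  # genes outside the network only enter non-topology statistics
  sp <- rep$spearman_results
  expect_true(all(sp$n[sp$x == "closeness"] == 20))
  expect_true(all(sp$n[sp$x == "protein_length"] == 30))
})

test_that("a planted closeness effect is recovered with the right sign", {
  fx <- make_assoc_fixture(711)
  rep <- run_associations(fx$rates, fx$cent, fx$ann, fx$net)
  row <- rep$spearman_results[rep$spearman_results$x == "closeness" &
                                rep$spearman_results$y == "omega", ]
  expect_lt(row$rho, -0.4)
  expect_lt(row$p, 0.05)
})

test_that("randomly permuted rates show no spurious association", {
  set.seed(712)
  fx <- make_assoc_fixture(712)
  fx$rates$omega <- sample(fx$rates$omega)
  fx$rates$dN <- fx$rates$omega * 0.5
  rep <- run_associations(fx$rates, fx$cent, fx$ann, fx$net)
  row <- rep$spearman_results[rep$spearman_results$x == "closeness" &
                                rep$spearman_results$y == "omega", ]
  expect_gt(row$p, 0.01)
})

test_that("association output is invariant to gene row order", {
  fx <- make_assoc_fixture(713)
  rep1 <- run_associations(fx$rates, fx$cent, fx$ann, fx$net)
  perm <- sample(nrow(fx$rates))
  rep2 <- run_associations(fx$rates[perm, ], fx$cent, fx$ann, fx$net)
  expect_equal(rep1$spearman_results, rep2$spearman_results)
  expect_equal(rep1$kruskal_results, rep2$kruskal_results)
  expect_equal(rep1$neighbor_results, rep2$neighbor_results)
})
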