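write_fasta_tmp <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(records)), records)), path)
  path
}

test_that("a clean two-record FASTA parses into codon states", {
  path <- write_fasta_tmp(c(t1 = "ATGAAA", t2 = "ATGAAG"))
  aln <- read_codon_alignment(path)
  code <- universal_code()
  expect_s3_class(aln, "codon_alignment")
  expect_identical(aln$taxa, c("t1", "t2"))
  expect_identical(dim(aln$sites), c(2L, 2L))
  expect_false(anyNA(aln$sites))
  expect_identical(aln$sites[1, ], unname(code$codon_index[c("ATG", "AAA")]))
  expect_identical(unname(aln$sites[2, 2]), code$codon_index[["AAG"]])
})

test_that("stop codons and malformed alignments are rejected with context", {
  p1 <- write_fasta_tmp(c(t1 = "ATGTAAAAA", t2 = "ATGAAGCCC"))
  expect_error(read_codon_alignment(p1), "TAA.*t1.*site 2")
  p2 <- write_fasta_tmp(c(t1 = "ATGAAA", t2 = "ATGAAGGGG"))
  expect_error(read_codon_alignment(p2), "length mismatch")
  p3 <- write_fasta_tmp(c(t1 = "ATGA", t2 = "ATGA"))
  expect_error(read_codon_alignment(p3), "divisible by 3")
  p4 <- write_fasta_tmp(c(t1 = "ATGAAA"))
  expect_error(read_codon_alignment(p4), "at least 2")
})

test_that("gap and ambiguity codons become missing cells, others parse", {
  path <- write_fasta_tmp(c(t1 = "ATGAT-AAA", t2 = "ATGNNNAAA",
                            t3 = "ATGATAAAA"))
  aln <- read_codon_alignment(path)
  expect_true(is.na(aln$sites[1, 2]))
  expect_true(is.na(aln$sites[2, 2]))
  expect_false(anyNA(aln$sites[3, ]))
  expect_false(anyNA(aln$sites[, c(1, 3)]))
})

test_that("alignments round-trip through FASTA exactly", {
  tree <- mammal9_fixture()
  aln <- simulate_alignment(tree, site_class_model("M0", omega = 0.3),
                            2, NULL, 40, seed = 5, gene_id = "rt")
  aln$sites[2, 7] <- NA  # plant a missing cell
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, path)
  back <- read_codon_alignment(path, gene_id = "rt")
  expect_identical(back$taxa, aln$taxa)
  expect_identical(back$sites, aln$sites)
})

test_that("newick trees parse with branch lengths and foreground tags", {
  t1 <- read_tree(text = "((A:0.1,B:0.1):0.05,C:0.2);")
  expect_length(t1$tip.label, 3)
  expect_equal(sort(t1$edge.length), c(0.05, 0.1, 0.1, 0.2))
  expect_length(foreground_nodes(t1), 0)

  t2 <- read_tree(text = "((A,B)#1,C);")
  fg <- foreground_nodes(t2)
  expect_length(fg, 1)
  ntip <- length(t2$tip.label)
  expect_gt(fg, ntip)            # internal node above (A,B)
  expect_equal(t2$edge.length, rep(0.1, nrow(t2$edge)))  # default lengths

  t3 <- read_tree(text = "((A#1:0.1,B:0.1):0.05,C:0.2);")
  expect_identical(t3$tip.label, c("A", "B", "C"))
  expect_identical(foreground_nodes(t3), 1L)
})

test_that("bad newick input errors", {
  expect_error(read_tree(text = "((A,B,C);"), "malformed|parse")
  expect_error(read_tree(text = "((A,B),A);"), "duplicate")
})

test_that("trees round-trip including the foreground marking", {
  tree <- mammal9_fixture("rodent")
  txt <- write_tree(tree)
  back <- read_tree(text = txt)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(sum(back$edge.length), sum(tree$edge.length))
  expect_identical(node_labels_of(back, foreground_nodes(back)), "rodent")
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
})

test_that("edge lists parse to simple undirected graphs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tB", "B\tA", "B\tC"), path)
  net <- read_network(path)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_identical(nrow(net$edges), 2L)

  writeLines(c("A\tA", "A\tB"), path)
  expect_warning(net2 <- read_network(path), "self-loop")
  expect_identical(nrow(net2$edges), 1L)

  writeLines(character(0), path)
  expect_error(read_network(path), "empty")
  writeLines(c("A\tB", "Conly"), path)
  expect_error(read_network(path), "line 2")
})

test_that("networks round-trip through TSV", {
  net <- random_connected_network(paste0("g", 1:12), 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_identical(key(back$edges), key(net$edges))
})

test_that("annotation tables are validated against the enumerations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g2"), cell_type = c("rod", "shared"),
                   process = c("phototransduction", "development"),
                   fun = c("opsin", "miscellaneous"),
                   protein_length = c(348L, 210L))
  write_annotations(df, path)
  back <- read_annotations(path)
  expect_identical(as.character(back$cell_type), c("rod", "shared"))
  expect_identical(levels(back$fun), phylosel:::FUNCTIONS)

  df_bad <- df
  df_bad$cell_type[1] <- "bipolar"
  write_annotations(df_bad, path)
  expect_error(read_annotations(path), "invalid cell_type")
  df_bad2 <- df
  df_bad2$protein_length[2] <- 0L
  write_annotations(df_bad2, path)
  expect_error(read_annotations(path), "protein_length")
})

test_that("report tables round-trip numeric values to machine precision", {
  pg <- data.frame(gene_id = c("g1", "g2", "g3"),
                   omega = c(1 / 3, sqrt(2) / 10, 0.1234567890123456),
                   dN = c(0.01, NA, 1e-9), dS = c(0.03, 0.2, 2.5))
  st <- data.frame(gene_id = "g1", test = "M1a_vs_M2a", branch = NA,
                   lnL_alt = -1234.56789012345, lnL_null = -1240.1,
                   statistic = 11.06621, df = 2L, p_raw = 0.003953,
                   p_adjusted = 0.011859)
  dir <- withr::local_tempdir()
  write_report(list(per_gene = pg, selection_tests = st), dir)
  back <- read_report_table(file.path(dir, "per_gene.tsv"))
  expect_identical(nrow(back), 3L)
  expect_identical(back$omega, pg$omega)
  expect_identical(back$dN, pg$dN)
  st_back <- read_report_table(file.path(dir, "selection_tests.tsv"))
  expect_true(all(c("p_raw", "p_adjusted") %in% names(st_back)))
  expect_identical(st_back$lnL_alt, st$lnL_alt)
})
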