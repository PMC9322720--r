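test_that("newick parsing handles rooted, unrooted, and malformed input", {
  r <- parse_newick("((A,B),C);")
  expect_s3_class(r, "phylo")
  expect_true(ape::is.rooted(r))
  expect_equal(length(r$tip.label), 3L)

  u <- parse_newick("(A,B,C);")
  expect_false(ape::is.rooted(u))
  expect_equal(nrow(u$edge), 3L)            # 2*3 - 3

  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("((A,B)),C;"), "unbalanced|empty|parse")
  expect_error(parse_newick("((A,A),B);"), "duplicate")
  expect_error(parse_newick("((A,B),(C,D),(E,F),G);", "rooted"), "polytomy|rooted")
  # quoted labels and comments are accepted and stripped
  q <- parse_newick("(('A x'[note],B),C);")
  expect_true("A x" %in% q$tip.label)
})

test_that("write-parse round trip preserves topology and labels", {
  for (seed in 1:10) {
    n <- sample(4:40, 1)
    nwk <- random_newick(n, seed)
    phy <- parse_newick(nwk)
    expect_true(ape::all.equal.phylo(phy, ape::read.tree(text = ape::write.tree(phy)),
                                     use.edge.length = FALSE))
  }
})

test_that("species_tree indexes 2L-1 postorder branches with a stem", {
  st <- st3()
  expect_equal(st$M, 5L)
  expect_equal(st$root, st$M)               # stem branch is last in postorder
  expect_true(all(st$child1[st$root] > 0))
  # children precede parents
  for (v in seq_len(st$M))
    if (st$child1[v] > 0) expect_true(st$child1[v] < v && st$child2[v] < v)
  expect_error(species_tree("(A,B,C);"), "rooted")
  expect_error(species_tree("((A,B),C);", missing = c(Z = 0.1)), "not in tree")
  expect_error(species_tree("((A,B),C);", missing = c(A = 1.2)), "\\[0, 1\\]")
})

test_that("root-branch enumeration returns 2L-3 distinct rootings", {
  for (L in c(3, 4, 7, 31, 64)) {
    ut <- unrooted_species_tree(parse_newick(random_newick(L, L), "unrooted"))
    expect_length(enumerate_root_branches(ut), 2 * L - 3)
  }
  # the headline dataset size: 31 leaves -> 59 candidate roots
  ut31 <- unrooted_species_tree(parse_newick(random_newick(31, 1), "unrooted"))
  expect_length(enumerate_root_branches(ut31), 59L)
})

test_that("rerooting bisects the chosen branch and inverts cleanly", {
  ut <- unrooted_species_tree("(A,(B,C),D);")
  for (b in enumerate_root_branches(ut)) {
    st <- reroot_on_branch(ut, b)
    expect_true(ape::is.rooted(st$phy))
    expect_true(ape::all.equal.phylo(ape::unroot(st$phy), ut$phy,
                                     use.edge.length = FALSE))
  }
  # all 5 rootings of a 4-leaf tree are pairwise distinct edge-rooted trees
  roots <- lapply(enumerate_root_branches(ut), function(b)
    reroot_on_branch(ut, b)$phy)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(ape::all.equal.phylo(roots[[i]], roots[[j]],
                                      use.edge.length = FALSE))
  expect_error(reroot_on_branch(ut, 99), "invalid branch")
})

test_that("true_root_branch recovers the branch matching a root split", {
  phy <- simulate_species_tree(10, seed = 7)
  ut <- unrooted_species_tree(ape::unroot(phy))
  b <- true_root_branch(ut, phy)
  st <- reroot_on_branch(ut, b)
  # rooting there recovers the original root bipartition
  expect_equal(true_root_branch(ut, st), b)
})

test_that("leaf-to-species mapping by delimiter and by table", {
  st <- st3()
  g <- map_leaves_to_species("((A_1,B_7),C_2);", species = st$species)
  expect_equal(sort(unique(g$leaf_species)), c("A", "B", "C"))
  expect_equal(as.integer(g$copy_counts), c(1L, 1L, 1L))

  expect_error(map_leaves_to_species("((orphan,B_1),C_1);"), "orphan")
  expect_error(map_leaves_to_species("((A_1,Z_1),C_1);", species = st$species),
               "Z")
  tab <- data.frame(leaf = c("x1", "x2", "x3"), species = c("A", "A", "B"))
  g2 <- map_leaves_to_species("((x1,x2),x3);", table = tab,
                              species = st$species)
  expect_equal(as.integer(g2$copy_counts[["A"]]), 2L)
  # table overrides delimiter parsing
  tab2 <- data.frame(leaf = c("A_1", "B_1", "C_1"),
                     species = c("C", "C", "A"))
  g3 <- map_leaves_to_species("((A_1,B_1),C_1);", table = tab2,
                              species = st$species)
  expect_equal(as.integer(g3$copy_counts[["C"]]), 2L)
})

test_that("gene-tree file reading maps every line", {
  tf <- withr::local_tempfile(lines = c("((A_1,B_1),C_1);",
                                        "(A_1,(A_2,C_1));"))
  fams <- read_gene_trees(tf, species = c("A", "B", "C"))
  expect_length(fams, 2L)
  expect_equal(fams[[2]]$id, "F0002")
  expect_equal(as.integer(fams[[2]]$copy_counts[["A"]]), 2L)
})

test_that("missing-fraction TSV reader validates ranges", {
  tf <- withr::local_tempfile(lines = c("A\t0.1", "B\t0"))
  m <- read_missing_fractions(tf)
  expect_equal(m, c(A = 0.1, B = 0))
  tf2 <- withr::local_tempfile(lines = c("A\t1.5"))
  expect_error(read_missing_fractions(tf2), "\\[0, 1\\]")
})
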