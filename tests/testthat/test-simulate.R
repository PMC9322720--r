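test_that("simulated species trees are ultrametric, unit depth, deterministic", {
  phy <- simulate_species_tree(31, seed = 5)
  expect_equal(length(phy$tip.label), 31L)
  expect_equal(phy$Nnode, 30L)
  depths <- ape::node.depth.edgelength(phy)[1:31]
  expect_true(all(abs(depths - 1) < 1e-12))
  # unrooting exposes 59 candidate root branches
  ut <- unrooted_species_tree(ape::unroot(phy))
  expect_equal(ut$n_branches, 59L)
  expect_identical(ape::write.tree(simulate_species_tree(31, seed = 5)),
                   ape::write.tree(phy))
  expect_false(identical(ape::write.tree(simulate_species_tree(31, seed = 6)),
                         ape::write.tree(phy)))
  expect_error(simulate_species_tree(2, seed = 1), "at least 3")
})

test_that("regime presets satisfy their defining ratios", {
  b <- sim_config("bacteria", seed = 1)
  expect_equal(b$tau / b$delta, 50)
  expect_equal(b$lambda, 1.05 * (b$delta + b$tau))
  b100 <- sim_config("bacteria", td = 100, seed = 1)
  expect_equal(b100$tau / b100$delta, 100)
  expect_error(sim_config("bacteria", td = 10, seed = 1), "\\[50, 100\\]")
  e <- sim_config("eukaryote", seed = 1)
  expect_gte(e$delta / e$tau, 2)
  expect_error(sim_config("custom", seed = 1), "delta")
  expect_error(sim_config("bacteria"), "seed")
})

test_that("a rate-free family is congruent with the species tree", {
  phy <- simulate_species_tree(8, seed = 2)
  cfg <- sim_config("custom", n_species = 8, delta = 0, tau = 0, lambda = 0,
                    origination = "stem", seed = 2)
  sf <- simulate_family(phy, cfg, seed = 7)
  expect_equal(sf$n_leaves, 8L)
  expect_true(all(sf$truth == 0))
  expect_equal(sort(sf$family$leaf_species), sort(phy$tip.label))
  # observed topology matches the species topology
  g <- sf$family$phy
  g$tip.label <- sub("_.*$", "", g$tip.label)
  expect_true(ape::all.equal.phylo(ape::unroot(g), ape::unroot(phy),
                                   use.edge.length = FALSE))
})

test_that("event truth counts respect the generating process", {
  phy <- simulate_species_tree(8, seed = 3)
  # transfers only: no duplication can ever be recorded
  cfgT <- sim_config("custom", n_species = 8, delta = 0, tau = 0.8,
                     lambda = 0.2, seed = 3)
  for (s in 1:10) {
    sf <- simulate_family(phy, cfgT, seed = s)
    expect_equal(sf$truth[["D_all"]], 0L)
  }
  # duplications only: no transfer
  cfgD <- sim_config("custom", n_species = 8, delta = 0.8, tau = 0,
                     lambda = 0.2, seed = 3)
  sums <- c(D = 0L, T = 0L)
  for (s in 1:10) {
    sf <- simulate_family(phy, cfgD, seed = s)
    expect_equal(sf$truth[["T_all"]], 0L)
    sums["D"] <- sums["D"] + sf$truth[["D_all"]]
  }
  expect_gt(sums[["D"]], 0L)
  # observed-history counts never exceed full-history counts
  cfgB <- sim_config("bacteria", n_species = 8, seed = 3)
  for (s in 1:10) {
    sf <- simulate_family(phy, cfgB, seed = s)
    expect_lte(sf$truth[["T_obs"]], sf$truth[["T_all"]])
    expect_lte(sf$truth[["D_obs"]], sf$truth[["D_all"]])
    expect_lte(sf$truth[["L_obs"]], sf$truth[["L_all"]])
  }
})

test_that("transfer recipients are uniform among contemporaneous branches", {
  phy <- simulate_species_tree(10, seed = 4)
  times <- dtlroot:::.node_times(phy, stem_length = 0.2)
  for (tq in c(0.3, 0.7, 0.95)) {
    alive <- dtlroot:::.alive_branches(times, tq)
    donor <- alive[1]
    pool <- setdiff(alive, donor)
    set.seed(99)
    draws <- replicate(10000, dtlroot:::.pick_recipient(times, tq, donor))
    expect_true(all(draws %in% pool))
    tab <- table(factor(draws, levels = pool))
    expect_gt(chisq.test(tab)$p.value, 0.01)
  }
})

test_that("loss-dominated regimes leave fewer than one copy per species", {
  cfg <- sim_config("custom", n_species = 10, n_families = 150,
                    delta = 0.05, tau = 0.25, lambda = 0.9,
                    min_leaves = 2L, seed = 12)
  expect_gt(cfg$lambda, cfg$delta + cfg$tau)
  ds <- simulate_dataset(cfg)
  copies <- mean(vapply(ds$families, function(g) g$n_leaves, integer(1))) / 10
  expect_lt(copies, 1)
})

test_that("missing fractions thin observed leaves", {
  cfg0 <- sim_config("custom", n_species = 10, n_families = 60,
                     delta = 0, tau = 0, lambda = 0,
                     origination = "stem", seed = 6)
  cfg5 <- sim_config("custom", n_species = 10, n_families = 60,
                     delta = 0, tau = 0, lambda = 0, missing = 0.5,
                     origination = "stem", seed = 6)
  n0 <- mean(simulate_dataset(cfg0)$truth$n_leaves)
  n5 <- mean(simulate_dataset(cfg5)$truth$n_leaves)
  expect_equal(n0, 10)
  expect_lt(n5, 8)         # half the leaves sampled away on average
  # species labels survive pruning
  ds5 <- simulate_dataset(cfg5)
  for (g in ds5$families[1:5])
    expect_true(all(g$leaf_species %in% ds5$species_phy$tip.label))
})

test_that("datasets are byte-identical under the same config and seed", {
  cfg <- sim_config("bacteria", n_species = 8, n_families = 25, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$newicks, d2$newicks)
  expect_identical(d1$truth, d2$truth)
  expect_identical(ape::write.tree(d1$species_phy),
                   ape::write.tree(d2$species_phy))
  # and written files round-trip
  dir <- withr::local_tempdir()
  p <- write_sim_dataset(d1, dir)
  expect_identical(readLines(p[["fams"]]), unname(d1$newicks))
  fams <- read_gene_trees(p[["fams"]], species = d1$species_phy$tip.label)
  expect_equal(vapply(fams, function(g) g$n_leaves, integer(1)),
               d1$truth$n_leaves)
})

test_that("the single-copy complete subset mirrors its filter", {
  cfg0 <- sim_config("custom", n_species = 6, n_families = 10,
                     delta = 0, tau = 0, lambda = 0,
                     origination = "stem", seed = 9)
  ds0 <- simulate_dataset(cfg0)
  expect_length(ds0$singlecopy_ids, 10L)   # no events: everything qualifies
  cfg <- sim_config("eukaryote", n_species = 6, n_families = 60, seed = 9)
  ds <- simulate_dataset(cfg)
  sc <- ds$truth$family_id %in% ds$singlecopy_ids
  for (i in head(which(sc), 3)) {
    g <- ds$families[[i]]
    expect_equal(length(g$copy_counts), 6L)
    expect_true(all(g$copy_counts == 1))
  }
  # single-copy complete families carry almost no surviving duplications
  if (sum(sc) >= 5)
    expect_lt(mean(ds$truth$n_dup_obs[sc]), mean(ds$truth$n_dup_obs[!sc]))
})

test_that("bacteria-like truth ratios track the configured T:D", {
  # Monte-Carlo expectation check at moderate scale (the full-scale version
  # of this check is what the preset is built for)
  cfg <- sim_config("bacteria", n_species = 16, n_families = 400, seed = 21)
  ds <- simulate_dataset(cfg)
  Tt <- sum(ds$truth$n_trans_obs); Dt <- sum(ds$truth$n_dup_obs)
  expect_gt(Tt, Dt)    # transfer-dominated
  ratio <- Tt / max(Dt, 1)
  expect_gt(ratio, 50 * 0.7 * 0.5)  # generous band at this sample size
})
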