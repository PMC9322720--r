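# AU tests operate on synthetic log-likelihood matrices here; the full
# scan -> AU -> root-set path on simulated data is exercised in
# test-pipeline.R and test-acceptance.R.

test_that("complete separation rejects the inferior root", {
  set.seed(1)
  N <- 100
  base <- rnorm(N)
  ll <- rbind(`1` = base + 1, `2` = base)   # root 1 better by 1 per family
  a <- au_test(ll, B = 2000, seed = 3)
  expect_lt(a$table$au_p[a$table$root == "2"], 1e-3)
  rs <- root_set(a, 0.05)
  expect_true("1" %in% rs$retained)
  expect_equal(rs$rejected, "2")
})

test_that("identical rows are statistically indistinguishable", {
  set.seed(2)
  row <- rnorm(60)
  ll <- rbind(`1` = row, `2` = row, `3` = row)
  a <- au_test(ll, B = 2000, seed = 9)
  # BP splits equally among perfect ties
  expect_equal(unname(a$table$bp), rep(1 / 3, 3), tolerance = 1e-12)
  rs <- root_set(a, 0.05)
  expect_setequal(rs$retained, c("1", "2", "3"))
})

test_that("family-wise rescaling of the matrix leaves the AU test unchanged", {
  set.seed(4)
  ll <- matrix(rnorm(5 * 40), 5, 40, dimnames = list(1:5, NULL))
  shift <- matrix(rnorm(40, sd = 25), 5, 40, byrow = TRUE)  # per-column consts
  a1 <- au_test(ll, B = 1500, seed = 11)
  a2 <- au_test(ll + shift, B = 1500, seed = 11)
  expect_equal(a1$table$bp, a2$table$bp, tolerance = 1e-12)
  expect_equal(a1$table$au_p, a2$table$au_p, tolerance = 1e-9)
})

test_that("AU results are deterministic in the seed", {
  set.seed(5)
  ll <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(1:4, NULL))
  a1 <- au_test(ll, B = 1000, seed = 21)
  a2 <- au_test(ll, B = 1000, seed = 21)
  expect_identical(a1$table, a2$table)
  a3 <- au_test(ll, B = 1000, seed = 22)
  expect_false(identical(a1$table$bp, a3$table$bp))
})

test_that("root never maximal is flagged off-support with p = 0", {
  set.seed(6)
  base <- rnorm(50)
  ll <- rbind(`1` = base + 5, `2` = base, `3` = base - 5)
  a <- au_test(ll, B = 1000, seed = 2)
  expect_equal(a$table$flag[a$table$root == "3"], "off-support")
  expect_equal(a$table$au_p[a$table$root == "3"], 0)
})

test_that("the argmax root is always retained, even below alpha", {
  a <- structure(list(
    table = data.frame(root = c("1", "2"), bp = c(0.6, 0.4),
                       d = c(0, 0), c = c(0, 0),
                       au_p = c(0.04, 0.03), flag = c("", ""),
                       stringsAsFactors = FALSE),
    argmax = "1"), class = "au_result")
  rs <- root_set(a, 0.05)
  expect_equal(rs$retained, "1")
  expect_equal(rs$rejected, "2")
})

test_that("root sets shrink monotonically as alpha rises", {
  set.seed(7)
  base <- matrix(rnorm(6 * 80), 6, 80, dimnames = list(1:6, NULL))
  base[1, ] <- base[1, ] + 0.15
  base[2, ] <- base[2, ] + 0.1
  a <- au_test(base, B = 2000, seed = 13)
  alphas <- c(0.01, 0.05, 0.2, 0.5)
  sets <- lapply(alphas, function(al) root_set(a, al)$retained)
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("a root scan fills the whole matrix and is family-order invariant", {
  cfg <- sim_config("eukaryote", n_species = 6, n_families = 12, seed = 31)
  ds <- simulate_dataset(cfg)
  ut <- unrooted_species_tree(ape::unroot(ds$species_phy))
  sc <- root_scan(ds$families, ut)
  expect_equal(dim(sc$ll), c(9L, 12L))      # 2*6-3 roots
  expect_true(all(is.finite(sc$ll)))
  expect_true(all(is.finite(sc$lambda)))
  # processing order does not matter: same cells after permuting families
  perm <- c(5, 1, 12, 3, 8, 2, 10, 7, 4, 11, 6, 9)
  sc2 <- root_scan(ds$families[perm], ut)
  expect_equal(sc2$ll[, colnames(sc$ll)], sc$ll, tolerance = 1e-10)
})

test_that("constrained scans demand base fits and honour the policy ratio", {
  cfg <- sim_config("eukaryote", n_species = 5, n_families = 6, seed = 17)
  ds <- simulate_dataset(cfg)
  ut <- unrooted_species_tree(ape::unroot(ds$species_phy))
  expect_error(root_scan(ds$families, ut, rate_policy("fixed_ratio", 50)),
               "base_fits")
  free <- root_scan(ds$families, ut)
  scf <- root_scan(ds$families, ut, rate_policy("fixed_ratio", 50),
                   base_fits = free$ref_fits)
  # every family's fixed (delta, tau) satisfies tau/delta = 50 (tau > 0)
  pos <- scf$tau[1, ] > 0
  expect_true(all(abs(scf$tau[1, pos] / scf$delta[1, pos] - 50) < 1e-9))
  # delta and tau identical across roots (only lambda refit)
  expect_true(all(apply(scf$delta, 2, function(x) diff(range(x)) == 0)))
})
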