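# Small builders shared across tests.

# random binary rooted tree as a newick string, labels A1..An
random_newick <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, tip.label = paste0("A", seq_len(n)))
  ape::write.tree(phy)
}

# species tree on 3 leaves used by many model tests
st3 <- function(missing = NULL)
  species_tree("((A:1,B:1):1,C:2);", missing = missing)

fam <- function(nwk, st, id = "g")
  map_leaves_to_species(nwk, species = st$species, id = id)

# an ad-hoc family_fit without running the optimizer
fake_fit <- function(id, delta, tau, lambda, loglik = -1) {
  structure(list(id = id, mode = "free",
                 rates = c(delta = delta, tau = tau, lambda = lambda),
                 loglik = loglik,
                 td = if (delta > 0) tau / delta else structure(NA_real_, undefined = TRUE),
                 converged = TRUE, evals = 0L),
            class = "family_fit")
}
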