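#' Simulation configuration with regime presets
#'
#' Defines the generative conditions for synthetic gene families evolved
#' by duplication, transfer, and loss along a dated species tree. Two
#' presets bracket the biological regimes of interest:
#'
#' * `"bacteria"`: transfer-dominated, `tau:delta = 50` by default
#'   (configurable 50-100 via `td`), with losses slightly exceeding gains
#'   (`lambda = 1.05 * (delta + tau)`), the deletional-bias regime.
#' * `"eukaryote"`: duplication-rich, `delta:tau = 2` (T:D = 1:2).
#'
#' Rates are per unit branch length on a tree of unit root-to-tip depth.
#'
#' @param preset `"bacteria"`, `"eukaryote"`, or `"custom"`.
#' @param n_species Leaf count of the simulated species tree (`>= 3`).
#' @param n_families Number of observed families to generate.
#' @param delta,tau,lambda Simulator rates (required for `"custom"`,
#'   override the preset otherwise).
#' @param td For `"bacteria"`: the tau:delta ratio (50-100).
#' @param missing Named per-species missing fractions, or a single number
#'   applied to all species, or `NULL` for none.
#' @param min_leaves Minimum observed leaves per family; smaller draws are
#'   rejected and redrawn.
#' @param stem_length Length of the stem branch above the root on the
#'   unit-depth tree (gene families may originate there).
#' @param origination `"uniform"` (default: origination branch drawn
#'   uniformly, stem included, so families originating low in the tree
#'   cover only their clade) or `"stem"` (all families originate above the
#'   root and, with zero rates, are congruent with the whole species
#'   tree).
#' @param seed RNG seed (mandatory; every output is deterministic in it).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(preset = c("bacteria", "eukaryote", "custom"),
                       n_species = 16L, n_families = 100L,
                       delta = NULL, tau = NULL, lambda = NULL,
                       td = 50, missing = NULL, min_leaves = 3L,
                       stem_length = 0.2,
                       origination = c("uniform", "stem"), seed) {
  preset <- match.arg(preset)
  origination <- match.arg(origination)
  if (missing(seed)) stop("a seed is mandatory for simulated data")
  if (preset == "bacteria") {
    if (td < 50 || td > 100) stop("bacteria-like preset expects td in [50, 100]")
    if (is.null(tau)) tau <- 0.6
    if (is.null(delta)) delta <- tau / td
    if (is.null(lambda)) lambda <- 1.05 * (delta + tau)
  } else if (preset == "eukaryote") {
    if (is.null(delta)) delta <- 0.3
    if (is.null(tau)) tau <- delta / 2
    if (is.null(lambda)) lambda <- 0.6
    if (delta < 2 * tau) stop("eukaryote-like preset expects delta >= 2 * tau")
  } else {
    if (is.null(delta) || is.null(tau) || is.null(lambda))
      stop("custom preset needs delta, tau, lambda")
  }
  if (any(c(delta, tau, lambda) < 0)) stop("rates must be >= 0")
  if (n_species < 3L) stop("need at least 3 species")
  if (min_leaves < 2L) stop("min_leaves must be at least 2 (a one-leaf family is not a tree)")
  structure(list(preset = preset, n_species = as.integer(n_species),
                 n_families = as.integer(n_families),
                 delta = delta, tau = tau, lambda = lambda,
                 missing = missing, min_leaves = as.integer(min_leaves),
                 stem_length = stem_length, origination = origination,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a dated ultrametric species tree
#'
#' Pure-birth (Yule) tree rescaled to unit root-to-tip depth, species
#' named `S001 ... S{L}`. Deterministic per seed.
#'
#' @param L Leaf count (`>= 3`).
#' @param seed RNG seed.
#' @return A rooted ultrametric `phylo` with `$tip.label = S001...`.
#' @export
simulate_species_tree <- function(L, seed) {
  if (L < 3L) stop("need at least 3 species")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phy <- ape::rphylo(L, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$tip.label <- sprintf("S%03d", seq_len(L))
  phy
}

# node times (distance from root) and branch intervals for a dated tree
.node_times <- function(phy, stem_length) {
  L <- length(phy$tip.label)
  M <- 2L * L - 1L
  tbot <- numeric(M)
  dd <- ape::node.depth.edgelength(phy)
  tbot[seq_along(dd)] <- dd
  parent <- integer(M)
  for (r in seq_len(nrow(phy$edge))) parent[phy$edge[r, 2]] <- phy$edge[r, 1]
  root <- L + 1L
  ttop <- numeric(M)
  for (v in seq_len(M)) ttop[v] <- if (v == root) -stem_length else tbot[parent[v]]
  list(ttop = ttop, tbot = tbot, parent = parent, root = root, L = L, M = M)
}

# branches alive at absolute time t (branch of node v spans (ttop, tbot])
.alive_branches <- function(times, t) {
  which(times$ttop < t & t <= times$tbot)
}

.pick_recipient <- function(times, t, donor) {
  alive <- setdiff(.alive_branches(times, t), donor)
  if (!length(alive)) return(NA_integer_)
  alive[sample.int(length(alive), 1L)]
}

#' Simulate one gene family with ground-truth event counts
#'
#' A single gene copy originates at the top of a uniformly drawn branch
#' (stem included) and evolves forward in time: exponential waiting times
#' to duplication, transfer, and loss per unit branch length; transfers
#' pick a recipient uniformly among branches alive at that instant
#' (excluding the donor; if none exists the transfer cannot occur); at
#' species divergences lineages bifurcate; at the present each surviving
#' copy is observed with probability `1 - m_s`. Extinct and unobserved
#' lineages are pruned; draws with fewer observed leaves than
#' `min_leaves` are rejected and redrawn.
#'
#' Truth counts are recorded for the full history and for the observed
#' history: a duplication or transfer is in the observed history if at
#' least one observed leaf descends from it, a loss if it prunes a
#' lineage whose parent node has observed descendants.
#'
#' @param phy Dated rooted species tree ([simulate_species_tree()]).
#' @param config A [sim_config()].
#' @param seed RNG seed for this family.
#' @param id Family id.
#' @return A list of class `sim_family`: `newick` (pruned observed
#'   tree, leaf labels `SPECIES_counter`), `family` (a `gene_family`),
#'   `n_leaves`, `truth` (named counts, `*_all` and `*_obs` variants),
#'   `origination`, `rejections`.
#' @export
simulate_family <- function(phy, config, seed, id = "fam") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  times <- .node_times(phy, config$stem_length)
  L <- times$L
  msp <- numeric(L)
  if (!is.null(config$missing)) {
    if (is.null(names(config$missing)) && length(config$missing) == 1L)
      msp[] <- config$missing
    else {
      idx <- match(names(config$missing), phy$tip.label)
      if (anyNA(idx)) stop("missing-fraction species not in tree")
      msp[idx] <- config$missing
    }
  }
  child <- vector("list", times$M)
  for (r in seq_len(nrow(phy$edge)))
    child[[phy$edge[r, 1]]] <- c(child[[phy$edge[r, 1]]], phy$edge[r, 2])

  rates <- c(config$delta, config$tau, config$lambda)
  total_rate <- sum(rates)

  for (attempt in seq_len(1000L)) {
    env <- new.env(parent = emptyenv())
    env$counter <- 0L
    # recursive forward simulation; returns a lineage-tree node (list) or
    # NULL if the copy leaves no observed descendant ... pruning is done
    # after the fact so loss events can be attributed, so we return full
    # nodes including dead ones
    sim <- function(v, t0) {
      repeat {
        w <- if (total_rate > 0) rexp(1, total_rate) else Inf
        if (t0 + w < times$tbot[v]) {
          te <- t0 + w
          type <- sample.int(3L, 1L, prob = rates)
          if (type == 1L) {                       # duplication
            a <- sim(v, te); b <- sim(v, te)
            return(list(kind = "D", kids = list(a, b)))
          } else if (type == 2L) {                # transfer
            h <- .pick_recipient(times, te, v)
            if (is.na(h)) { t0 <- te; next }      # no contemporaneous recipient
            stay <- sim(v, te); move <- sim(h, te)
            return(list(kind = "T", kids = list(stay, move)))
          } else {                                # loss
            return(list(kind = "L", kids = list()))
          }
        } else {
          if (is.null(child[[v]])) {              # tip of species v
            if (runif(1) < msp[v]) return(list(kind = "U", kids = list()))
            env$counter <- env$counter + 1L
            lab <- paste0(phy$tip.label[v], "_", env$counter)
            return(list(kind = "leaf", kids = list(), label = lab,
                        species = phy$tip.label[v]))
          }
          a <- sim(child[[v]][1], times$tbot[v])
          b <- sim(child[[v]][2], times$tbot[v])
          return(list(kind = "S", kids = list(a, b)))
        }
      }
    }
    orig <- if (identical(config$origination, "stem")) times$root
            else sample.int(times$M, 1L)
    root_node <- sim(orig, times$ttop[orig])

    counts <- c(D_all = 0L, T_all = 0L, L_all = 0L,
                D_obs = 0L, T_obs = 0L, L_obs = 0L)
    # mark observed-ancestral nodes and count events
    mark <- function(nd) {
      if (nd$kind == "leaf") { nd$obs <- TRUE; return(nd) }
      nd$kids <- lapply(nd$kids, mark)
      nd$obs <- any(vapply(nd$kids, function(k) isTRUE(k$obs), logical(1)))
      nd
    }
    root_node <- mark(root_node)
    count_events <- function(nd, parent_obs) {
      if (nd$kind == "D") {
        counts["D_all"] <<- counts["D_all"] + 1L
        if (nd$obs) counts["D_obs"] <<- counts["D_obs"] + 1L
      } else if (nd$kind == "T") {
        counts["T_all"] <<- counts["T_all"] + 1L
        if (nd$obs) counts["T_obs"] <<- counts["T_obs"] + 1L
      } else if (nd$kind == "L") {
        counts["L_all"] <<- counts["L_all"] + 1L
        if (parent_obs) counts["L_obs"] <<- counts["L_obs"] + 1L
      }
      for (k in nd$kids) count_events(k, isTRUE(nd$obs))
      invisible(NULL)
    }
    count_events(root_node, FALSE)

    # prune to the observed tree and emit newick
    prune <- function(nd) {
      if (nd$kind == "leaf") return(nd$label)
      keep <- Filter(function(k) isTRUE(k$obs), nd$kids)
      subs <- lapply(keep, prune)
      subs <- subs[!vapply(subs, is.null, logical(1))]
      if (length(subs) == 0L) return(NULL)
      if (length(subs) == 1L) return(subs[[1]])
      paste0("(", subs[[1]], ",", subs[[2]], ")")
    }
    nwk <- prune(root_node)
    n_obs <- if (is.null(nwk)) 0L else env$counter
    # env$counter counts observed leaves only (unobserved tips return "U")
    if (n_obs >= config$min_leaves) {
      nwk <- paste0(nwk, ";")
      fam <- map_leaves_to_species(nwk, delimiter = "_",
                                   species = phy$tip.label, id = id)
      return(structure(list(newick = nwk, family = fam, n_leaves = n_obs,
                            truth = counts, origination = orig,
                            rejections = attempt - 1L),
                       class = "sim_family"))
    }
  }
  stop("rejection rate exceeded 99.9%: rates leave almost no family with ",
       config$min_leaves, "+ observed leaves; adjust the configuration")
}

#' Simulate a full dataset of gene families with truth tables
#'
#' Generates the species tree and `n_families` observed families under a
#' [sim_config()], together with the ground-truth event-count table and
#' the subset of families that are single-copy and species-complete (one
#' copy in every species). Byte-identical outputs for identical config
#' and seed.
#'
#' @param config A [sim_config()].
#' @param phy Optional pre-built dated species tree (defaults to
#'   [simulate_species_tree()] under the config's seed).
#' @return An object of class `sim_dataset`: `species_phy` (dated
#'   rooted), `species` (a [species_tree()] carrying the missing
#'   fractions), `families` (list of `gene_family`), `newicks`,
#'   `truth` (data.frame), `singlecopy_ids`, `config`.
#' @export
simulate_dataset <- function(config, phy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(phy)) phy <- simulate_species_tree(config$n_species, config$seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  fam_seeds <- sample.int(.Machine$integer.max - 1L, config$n_families)
  sims <- vector("list", config$n_families)
  for (i in seq_len(config$n_families))
    sims[[i]] <- simulate_family(phy, config, fam_seeds[i],
                                 id = sprintf("F%04d", i))
  truth <- data.frame(
    family_id = vapply(sims, function(s) s$family$id, character(1)),
    n_leaves = vapply(sims, function(s) s$n_leaves, integer(1)),
    n_dup_all = vapply(sims, function(s) s$truth[["D_all"]], integer(1)),
    n_trans_all = vapply(sims, function(s) s$truth[["T_all"]], integer(1)),
    n_loss_all = vapply(sims, function(s) s$truth[["L_all"]], integer(1)),
    n_dup_obs = vapply(sims, function(s) s$truth[["D_obs"]], integer(1)),
    n_trans_obs = vapply(sims, function(s) s$truth[["T_obs"]], integer(1)),
    n_loss_obs = vapply(sims, function(s) s$truth[["L_obs"]], integer(1)),
    origination_branch = vapply(sims, function(s) s$origination, integer(1)),
    rejections = vapply(sims, function(s) s$rejections, integer(1)),
    stringsAsFactors = FALSE
  )
  fams <- lapply(sims, function(s) s$family)
  L <- length(phy$tip.label)
  single <- vapply(fams, function(g)
    length(g$copy_counts) == L && all(g$copy_counts == 1L), logical(1))
  miss <- config$missing
  if (!is.null(miss) && is.null(names(miss)) && length(miss) == 1L)
    miss <- setNames(rep(miss, L), phy$tip.label)
  structure(list(species_phy = phy,
                 species = species_tree(phy, missing = miss),
                 families = fams,
                 newicks = vapply(sims, function(s) s$newick, character(1)),
                 truth = truth,
                 singlecopy_ids = truth$family_id[single],
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset (", x$config$preset, "): ", length(x$families),
      " families on ", x$config$n_species, " species; ",
      length(x$singlecopy_ids), " single-copy complete\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits `species_tree.nwk` (dated, rooted), `families.nwk` (one pruned
#' observed gene tree per line), `truth.tsv`, and `singlecopy_ids.txt`.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(species = file.path(dir, "species_tree.nwk"),
         fams = file.path(dir, "families.nwk"),
         truth = file.path(dir, "truth.tsv"),
         single = file.path(dir, "singlecopy_ids.txt"))
  ape::write.tree(ds$species_phy, file = p[["species"]])
  writeLines(ds$newicks, p[["fams"]])
  write.table(ds$truth, p[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(ds$singlecopy_ids, p[["single"]])
  invisible(p)
}
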