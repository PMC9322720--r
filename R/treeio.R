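#' Parse a newick string into a validated binary tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Square-bracket
#' comments are stripped, quoted labels are accepted, branch lengths are
#' optional. Polytomies other than the basal trifurcation of an unrooted
#' tree are rejected rather than resolved, because the downstream
#' reconciliation dynamic programme assumes binary trees and silent
#' resolution would change likelihoods.
#'
#' @param text A newick string (single tree, terminated by `;`).
#' @param rooted_hint One of `"auto"`, `"rooted"`, `"unrooted"`. With
#'   `"rooted"` the tree must be binary and rooted; with `"unrooted"` it is
#'   unrooted (a rooted input is collapsed); `"auto"` keeps whatever the
#'   string encodes.
#' @return An object of class `phylo`.
#' @examples
#' parse_newick("((A,B),C);")          # rooted, 3 leaves
#' parse_newick("(A,B,C);")            # unrooted, 3 branches
#' @export
parse_newick <- function(text, rooted_hint = c("auto", "rooted", "unrooted")) {
  rooted_hint <- match.arg(rooted_hint)
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("\\[[^]]*\\]", "", text)
  .check_parens(txt)
  phy <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("newick parse error: unreadable tree string", call. = FALSE)
  phy$tip.label <- gsub("^'(.*)'$", "\\1", phy$tip.label)   # unquote
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(phy$tip.label))) stop("empty leaf label", call. = FALSE)
  if (rooted_hint == "rooted") {
    if (!ape::is.rooted(phy)) stop("tree is not rooted", call. = FALSE)
    .check_binary(phy, rooted = TRUE)
  } else if (rooted_hint == "unrooted") {
    if (ape::is.rooted(phy) && phy$Nnode > 1L) phy <- ape::unroot(phy)
    .check_binary(phy, rooted = FALSE)
  } else {
    .check_binary(phy, rooted = ape::is.rooted(phy))
  }
  phy
}

# balanced-parenthesis pre-check so malformed input reports a character position
.check_parens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of string (character ",
         nchar(txt), ")", call. = FALSE)
  if (!grepl(";", txt)) stop("newick parse error: missing ';' terminator", call. = FALSE)
  invisible(TRUE)
}

.check_binary <- function(phy, rooted) {
  n <- length(phy$tip.label)
  tab <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  root <- n + 1L
  kids <- tab[tab > 0]
  if (rooted) {
    if (any(tab[-root] > 0 & tab[-root] != 2) || tab[root] != 2)
      stop("polytomy detected: tree is not strictly binary", call. = FALSE)
  } else {
    if (n == 2L) return(invisible(TRUE))
    if (tab[root] != 3 || any(tab[-root] > 0 & tab[-root] != 2))
      stop("polytomy detected: unrooted tree is not binary (every internal vertex must have degree 3)",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a rooted species tree for reconciliation
#'
#' Builds the indexed representation used by the DTL dynamic programme:
#' every node owns the branch above it (so there are `2L - 1` branches for
#' `L` leaves, including a stem branch above the root), and each species may
#' carry a missing-gene fraction `m_s` in `[0, 1]` — the probability that a
#' truly present gene is absent from the data.
#'
#' @param phy A rooted binary `phylo` object, or a newick string.
#' @param missing A named numeric vector of per-species missing fractions
#'   (names are species labels; species not named get 0), or `NULL` for all
#'   zero.
#' @return An object of class `species_tree` with elements `phy`, `L`
#'   (leaf count), `M` (branch count `2L - 1`), `child1`, `child2`,
#'   `parent`, `postorder`, `root`, `species`, `m`.
#' @export
species_tree <- function(phy, missing = NULL) {
  if (is.character(phy)) phy <- parse_newick(phy, "rooted")
  if (!inherits(phy, "phylo")) stop("phy must be a phylo object or newick string")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  .check_binary(phy, rooted = TRUE)
  L <- length(phy$tip.label)
  if (L < 2L) stop("species tree needs at least 2 leaves")
  M <- 2L * L - 1L
  child1 <- integer(M); child2 <- integer(M); parent <- integer(M)
  for (r in seq_len(nrow(phy$edge))) {
    p <- phy$edge[r, 1]; c <- phy$edge[r, 2]
    parent[c] <- p
    if (child1[p] == 0L) child1[p] <- c else child2[p] <- c
  }
  root <- L + 1L
  # postorder over ape node ids (children before parents)
  stack <- root
  order_stack <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_stack <- c(order_stack, nd)
    if (child1[nd] > 0L) stack <- c(stack, child1[nd], child2[nd])
  }
  po <- rev(order_stack)
  # relabel branches so internal ids 1..M ARE postorder (the DP then sweeps
  # branches sequentially); perm[ape id] = internal id
  perm <- integer(M); perm[po] <- seq_len(M)
  c1 <- integer(M); c2 <- integer(M); par <- integer(M)
  for (v in seq_len(M)) {
    c1[perm[v]] <- if (child1[v] > 0L) perm[child1[v]] else 0L
    c2[perm[v]] <- if (child2[v] > 0L) perm[child2[v]] else 0L
    par[perm[v]] <- if (v == root) 0L else perm[parent[v]]
  }
  m <- numeric(M)
  if (!is.null(missing)) {
    if (is.null(names(missing))) stop("missing fractions must be named by species")
    if (any(missing < 0 | missing > 1)) stop("missing fractions must lie in [0, 1]")
    unknown <- setdiff(names(missing), phy$tip.label)
    if (length(unknown)) stop("missing-fraction species not in tree: ",
                              paste(unknown, collapse = ", "))
    idx <- perm[match(names(missing), phy$tip.label)]
    m[idx] <- unname(missing)
  }
  structure(list(phy = phy, L = L, M = M, child1 = c1, child2 = c2,
                 parent = par, root = perm[root],
                 species = phy$tip.label,
                 leaf_id = setNames(perm[seq_len(L)], phy$tip.label),
                 m = m),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", x$L, "species,", x$M, "branches (incl. stem)\n")
  if (any(x$m > 0)) cat("  nonzero missing fractions for",
                        sum(x$m[seq_len(x$L)] > 0), "species\n")
  invisible(x)
}

#' Construct an unrooted species tree with indexed branches
#'
#' @param phy An unrooted (or rooted, then collapsed) binary `phylo`, or a
#'   newick string. For `L` leaves the tree has `2L - 3` branches, each a
#'   candidate root position.
#' @param missing Optional named per-species missing fractions, carried to
#'   rooted versions produced by [reroot_on_branch()].
#' @return An object of class `unrooted_tree` with elements `phy`,
#'   `L`, `n_branches`, `missing`.
#' @export
unrooted_species_tree <- function(phy, missing = NULL) {
  if (is.character(phy)) phy <- parse_newick(phy, "unrooted")
  if (ape::is.rooted(phy) && phy$Nnode > 1L) phy <- ape::unroot(phy)
  .check_binary(phy, rooted = FALSE)
  L <- length(phy$tip.label)
  if (L < 3L) stop("unrooted handling needs at least 3 leaves")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  structure(list(phy = phy, L = L, n_branches = nrow(phy$edge), missing = missing),
            class = "unrooted_tree")
}

#' @export
print.unrooted_tree <- function(x, ...) {
  cat("unrooted_tree:", x$L, "leaves,", x$n_branches, "candidate root branches\n")
  invisible(x)
}

#' Enumerate candidate root branches of an unrooted species tree
#'
#' Every branch of the unrooted topology is a possible root position; a
#' binary tree on `L` leaves has exactly `2L - 3` of them (59 for 31
#' leaves). Branch indices are rows of the tree's edge matrix and are
#' stable for a given object.
#'
#' @param t An `unrooted_tree`.
#' @return Integer vector of branch indices, length `2L - 3`.
#' @export
enumerate_root_branches <- function(t) {
  stopifnot(inherits(t, "unrooted_tree"))
  seq_len(t$n_branches)
}

#' Root an unrooted species tree on a given branch
#'
#' The new root bisects branch `b`; unrooting the result recovers the
#' original topology.
#'
#' @param t An `unrooted_tree`.
#' @param b A branch index from [enumerate_root_branches()].
#' @return A `species_tree` rooted on branch `b`, inheriting `t`'s
#'   missing fractions.
#' @export
reroot_on_branch <- function(t, b) {
  stopifnot(inherits(t, "unrooted_tree"))
  if (!(b %in% seq_len(t$n_branches))) stop("invalid branch index: ", b)
  child <- t$phy$edge[b, 2]
  len <- t$phy$edge.length[b]
  r <- phytools::reroot(t$phy, node.number = child, position = len / 2)
  species_tree(r, missing = t$missing)
}

#' Leaf bipartition induced by each branch of an unrooted tree
#'
#' For each branch, the set of leaf labels on the child side of the edge.
#' Used to identify a known (true) root branch by its split.
#'
#' @param t An `unrooted_tree`.
#' @return A list of character vectors, one per branch.
#' @export
branch_bipartitions <- function(t) {
  stopifnot(inherits(t, "unrooted_tree"))
  phy <- t$phy
  n <- t$L
  lapply(seq_len(t$n_branches), function(b) {
    child <- phy$edge[b, 2]
    if (child <= n) return(phy$tip.label[child])
    desc <- ape::extract.clade(phy, child)$tip.label
    sort(desc)
  })
}

#' Find the branch of an unrooted tree matching a rooted tree's root split
#'
#' @param t An `unrooted_tree`.
#' @param rooted A rooted `phylo` or `species_tree` on the same leaves.
#' @return The branch index whose bipartition equals the root split of
#'   `rooted`.
#' @export
true_root_branch <- function(t, rooted) {
  if (inherits(rooted, "species_tree")) rooted <- rooted$phy
  n <- length(rooted$tip.label)
  root <- n + 1L
  kid <- rooted$edge[rooted$edge[, 1] == root, 2][1]
  side <- if (kid <= n) rooted$tip.label[kid] else
    sort(ape::extract.clade(rooted, kid)$tip.label)
  all <- sort(rooted$tip.label)
  bips <- branch_bipartitions(t)
  for (b in seq_along(bips)) {
    bb <- sort(bips[[b]])
    if (identical(bb, side) || identical(bb, sort(setdiff(all, side)))) return(b)
  }
  stop("no branch of the unrooted tree matches the root split")
}

#' Map gene-tree leaves to species and build a gene family
#'
#' Leaf labels are resolved to species either by a delimiter rule (the
#' label prefix up to the first occurrence of `delimiter`, the common
#' convention for reconciliation inputs, e.g. `"ECOLI_0042"` -> `"ECOLI"`)
#' or by an explicit two-column table, which overrides the delimiter.
#'
#' @param phy A `phylo` gene tree (or newick string). Trees with 3 or more
#'   leaves are treated as unrooted; 2-leaf trees as trivially rooted.
#' @param delimiter Single character/string delimiter; the species is the
#'   label prefix before its first occurrence.
#' @param table Optional data.frame with columns `leaf` and `species`
#'   giving an explicit mapping.
#' @param species Optional character vector of valid species names (e.g.
#'   `species_tree$species`); leaves mapping outside it raise an error
#'   listing the offenders.
#' @param id Family identifier.
#' @return An object of class `gene_family` with elements `id`, `phy`,
#'   `n_leaves`, `leaf_species` (aligned with `phy$tip.label`),
#'   `copy_counts`.
#' @export
map_leaves_to_species <- function(phy, delimiter = "_", table = NULL,
                                  species = NULL, id = "fam") {
  if (is.character(phy)) phy <- parse_newick(phy, "auto")
  n <- length(phy$tip.label)
  if (n < 2L) stop("gene family needs at least 2 leaves")
  if (n >= 3L && ape::is.rooted(phy)) phy <- ape::unroot(phy)
  .check_binary(phy, rooted = (n == 2L))
  labs <- phy$tip.label
  if (!is.null(table)) {
    if (!all(c("leaf", "species") %in% names(table)))
      stop("mapping table needs columns 'leaf' and 'species'")
    idx <- match(labs, table$leaf)
    if (anyNA(idx))
      stop("leaves missing from mapping table: ",
           paste(labs[is.na(idx)], collapse = ", "))
    sp <- as.character(table$species[idx])
  } else {
    hit <- regexpr(delimiter, labs, fixed = TRUE)
    if (any(hit < 0))
      stop("cannot resolve species for leaves (no '", delimiter, "'): ",
           paste(labs[hit < 0], collapse = ", "))
    sp <- substr(labs, 1L, hit - 1L)
    if (any(!nzchar(sp))) stop("empty species prefix in leaf labels")
  }
  if (!is.null(species)) {
    bad <- setdiff(unique(sp), species)
    if (length(bad))
      stop("species not present in the species tree: ",
           paste(bad, collapse = ", "))
  }
  gf <- structure(list(id = id, phy = phy, n_leaves = n, leaf_species = sp,
                       copy_counts = table(sp)),
                  class = "gene_family")
  gf$skel <- gene_skeleton(gf)   # cached DP skeleton (species-tree free)
  gf
}

#' @export
print.gene_family <- function(x, ...) {
  cat("gene_family '", x$id, "': ", x$n_leaves, " leaves, ",
      length(x$copy_counts), " species\n", sep = "")
  invisible(x)
}

#' Read a collection of gene trees (one newick per line)
#'
#' @param path File with one newick string per line.
#' @param delimiter,table,species Passed to [map_leaves_to_species()].
#' @param ids Optional family ids; defaults to `F0001`, `F0002`, ...
#' @return List of `gene_family` objects.
#' @export
read_gene_trees <- function(path, delimiter = "_", table = NULL,
                            species = NULL, ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(ids)) ids <- sprintf("F%04d", seq_along(lines))
  if (anyDuplicated(ids)) stop("duplicate family ids")
  mapply(function(ln, id)
    map_leaves_to_species(ln, delimiter = delimiter, table = table,
                          species = species, id = id),
    lines, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read per-species missing-gene fractions from a TSV
#'
#' Two columns: species, fraction in `[0, 1]`. No header.
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_missing_fractions <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("missing-fraction table needs 2 columns")
  m <- as.numeric(df[[2]])
  if (any(is.na(m) | m < 0 | m > 1)) stop("fractions must be numeric in [0, 1]")
  setNames(m, as.character(df[[1]]))
}

# --- internal: encode a gene family as directed subtrees for the DP -------

# Directed subtree d = (a -> b): the part of the unrooted gene tree on b's
# side of edge {a,b}. Children of an internal directed subtree are the two
# directed edges leaving b away from a. Rootings pair the two directions of
# each undirected edge. The skeleton is species-tree independent (leaf
# subtrees carry the species NAME); gene_encoding() maps names to a given
# species tree's terminal branch ids. Arrays are in topological order
# (children before parents), 1-based.
gene_skeleton <- function(gf) {
  phy <- gf$phy
  n <- gf$n_leaves
  if (n == 2L) {
    return(list(kind = c(0L, 0L), leaf_species = gf$leaf_species,
                leaf_at = c(1L, 2L), childA = c(0L, 0L),
                childB = c(0L, 0L), rootA = 1L, rootB = 2L))
  }
  E <- phy$edge
  nn <- n + phy$Nnode
  adj <- vector("list", nn)
  for (r in seq_len(nrow(E))) {
    adj[[E[r, 1]]] <- c(adj[[E[r, 1]]], E[r, 2])
    adj[[E[r, 2]]] <- c(adj[[E[r, 2]]], E[r, 1])
  }
  dmap <- new.env(parent = emptyenv())
  kind <- integer(0); leaf_at <- integer(0)
  childA <- integer(0); childB <- integer(0)
  build <- function(a, b) {
    k <- paste0(a, ">", b)
    got <- mget(k, envir = dmap, ifnotfound = list(NULL))[[1]]
    if (!is.null(got)) return(got)
    if (b <= n) {
      kind <<- c(kind, 0L); leaf_at <<- c(leaf_at, b)
      childA <<- c(childA, 0L); childB <<- c(childB, 0L)
      d <- length(kind)
    } else {
      kids <- setdiff(adj[[b]], a)
      if (length(kids) != 2L) stop("gene tree not binary at vertex ", b)
      ca <- build(b, kids[1]); cb <- build(b, kids[2])
      kind <<- c(kind, 1L); leaf_at <<- c(leaf_at, 0L)
      childA <<- c(childA, ca); childB <<- c(childB, cb)
      d <- length(kind)
    }
    assign(k, d, envir = dmap)
    d
  }
  rootA <- integer(nrow(E)); rootB <- integer(nrow(E))
  for (r in seq_len(nrow(E))) {
    rootA[r] <- build(E[r, 1], E[r, 2])
    rootB[r] <- build(E[r, 2], E[r, 1])
  }
  list(kind = kind,
       leaf_species = ifelse(leaf_at > 0L, gf$leaf_species[pmax(leaf_at, 1L)], NA),
       leaf_at = leaf_at, childA = childA, childB = childB,
       rootA = rootA, rootB = rootB)
}

gene_encoding <- function(gf, st) {
  skel <- gf$skel
  if (is.null(skel)) skel <- gene_skeleton(gf)
  ids <- st$leaf_id[skel$leaf_species]
  if (anyNA(ids[skel$kind == 0L]))
    stop("family ", gf$id, ": species not in species tree: ",
         paste(unique(skel$leaf_species[skel$kind == 0L & is.na(ids)]),
               collapse = ", "))
  g_species <- ifelse(skel$kind == 0L, ids, 0L)
  list(kind = skel$kind, g_species = as.integer(g_species),
       childA = skel$childA, childB = skel$childB,
       rootA = skel$rootA, rootB = skel$rootB)
}
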