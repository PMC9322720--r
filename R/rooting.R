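# lean loss-rate optimization used in scan inner loops: Brent on log10
# lambda in [1e-10, 10], fixed (delta0, tau0), precomputed encoding.
# Returns c(delta, tau, lambda, loglik).
.fit_lambda <- function(st, enc, delta0, tau0) {
  obj <- function(x) {
    out <- dtl_loglik_cpp(st$M, st$child1, st$child2, st$m, st$root,
                          enc$kind, enc$g_species, enc$childA, enc$childB,
                          enc$rootA, enc$rootB, delta0, tau0, 10^x)
    if (!out$feasible) -1e300 else out$loglik
  }
  op <- optimize(obj, interval = c(-10, 1), maximum = TRUE, tol = 1e-5)
  c(delta0, tau0, 10^op$maximum, op$objective)
}

#' Reconciliation likelihoods of all candidate roots
#'
#' For every branch of the unrooted species tree, roots the tree there and
#' fits each gene family's DTL rates under the given policy, recording the
#' per-root, per-family log-likelihood matrix that drives the AU root
#' tests.
#'
#' Under the `"free"` policy all three rates are re-optimized per family
#' at every root (1:1-seeded at the reference root, warm-started
#' elsewhere) — what reconciliation software does when run once per rooted
#' tree; `refit = "lambda"` instead holds each family's (delta, tau) at
#' its reference-root free fit and refits only the loss rate per root.
#' Under `"fixed_ratio"` / `"ratio_floor"` the transfer rate comes from
#' `base_fits` (free-mode fits at a reference root), the duplication rate
#' is derived from the policy ([constrain_td()] / [apply_td_floor()]),
#' and only the loss rate is re-optimized per root.
#'
#' @param families List of `gene_family` objects.
#' @param t An `unrooted_tree`.
#' @param policy A [rate_policy()].
#' @param base_fits List of free-mode `family_fit` (same order as
#'   `families`); required for the constrained policies, optional for
#'   `"free"` (computed at `ref_branch` when absent).
#' @param ref_branch Branch index whose rooted tree provides the free
#'   reference fits (default: first branch).
#' @param refit For the free policy: `"full"` (default; all rates
#'   re-optimized per root) or `"lambda"` (loss rate only).
#' @param reltol,maxit Optimizer controls (see [optimize_rates()]).
#' @param verbose Print per-root progress.
#' @return An object of class `root_scan`: `ll` (K x N matrix, rows
#'   named by branch index, columns by family id), `delta`, `tau`,
#'   `lambda` (matched matrices of fitted rates), `policy`, `branches`,
#'   `ref_branch`, `ref_fits` (free fits at the reference root, when
#'   computed), `totals` (per-root summed log-likelihood), `argmax`
#'   (branch index with maximal total).
#' @export
root_scan <- function(families, t, policy = rate_policy("free"),
                      base_fits = NULL, ref_branch = 1L,
                      refit = c("full", "lambda"),
                      reltol = 1e-8, maxit = 500L, verbose = FALSE) {
  stopifnot(inherits(t, "unrooted_tree"), inherits(policy, "rate_policy"))
  refit <- match.arg(refit)
  if (!length(families)) stop("no families supplied")
  branches <- enumerate_root_branches(t)
  K <- length(branches); N <- length(families)
  ids <- vapply(families, function(g) g$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate family ids")
  if (policy$kind != "free" && is.null(base_fits))
    stop("policy '", policy$kind,
         "' needs base_fits (free-mode fits from a reference root)")
  if (!is.null(base_fits) && length(base_fits) != N)
    stop("base_fits must match families")

  ll <- matrix(NA_real_, K, N, dimnames = list(branches, ids))
  dm <- ll; tm <- ll; lm <- ll
  ref_fits <- NULL

  if (policy$kind == "free" && is.null(base_fits)) {
    st_ref <- reroot_on_branch(t, ref_branch)
    base_fits <- lapply(families, function(g)
      optimize_rates(g, st_ref, "free", reltol = reltol, maxit = maxit))
  }
  if (policy$kind == "free") ref_fits <- base_fits

  # per-family (delta, tau) fixed across roots (lambda refit) per policy
  dt <- switch(policy$kind,
    free = lapply(base_fits, function(f) f$rates[c("delta", "tau")]),
    fixed_ratio = lapply(base_fits, function(f)
      suppressWarnings(constrain_td(f$rates[["tau"]], policy$ratio))),
    ratio_floor = lapply(base_fits, function(f)
      apply_td_floor(f, policy$ratio)))

  full_refit <- (policy$kind == "free" && refit == "full")
  if (full_refit) {
    for (k in seq_len(K)) {
      st_k <- reroot_on_branch(t, branches[k])
      for (i in seq_len(N)) {
        g <- families[[i]]
        # warm start at the reference-root optimum with a small simplex;
        # the full search (wide step + restart) already ran there
        f <- tryCatch(
          optimize_rates(g, st_k, "free", init = ref_fits[[i]]$rates,
                         step = 0.15, restart = FALSE,
                         reltol = reltol, maxit = maxit),
          error = function(e)
            stop("reconciliation failed at root branch ", branches[k],
                 ", family ", g$id, ": ", conditionMessage(e), call. = FALSE))
        dm[k, i] <- f$rates[["delta"]]; tm[k, i] <- f$rates[["tau"]]
        lm[k, i] <- f$rates[["lambda"]]; ll[k, i] <- f$loglik
      }
      if (verbose) message("root branch ", branches[k], ": total ll = ",
                           signif(sum(ll[k, ]), 8))
    }
  } else {
    # lambda-only refits, batched per root in compiled code
    skels <- lapply(families, function(g)
      if (is.null(g$skel)) gene_skeleton(g) else g$skel)
    fam_D <- vapply(skels, function(s) length(s$kind), integer(1))
    fam_R <- vapply(skels, function(s) length(s$rootA), integer(1))
    conc <- list(kind = unlist(lapply(skels, `[[`, "kind")),
                 childA = unlist(lapply(skels, `[[`, "childA")),
                 childB = unlist(lapply(skels, `[[`, "childB")),
                 rootA = unlist(lapply(skels, `[[`, "rootA")),
                 rootB = unlist(lapply(skels, `[[`, "rootB")))
    leaf_names <- unlist(lapply(skels, `[[`, "leaf_species"))
    is_leaf <- conc$kind == 0L
    bad <- setdiff(unique(leaf_names[is_leaf]),
                   names(reroot_on_branch(t, branches[1])$leaf_id))
    if (length(bad))
      stop("species not present in the species tree: ",
           paste(bad, collapse = ", "))
    d0 <- vapply(dt, function(x) x[["delta"]], numeric(1))
    t0 <- vapply(dt, function(x) x[["tau"]], numeric(1))
    l0 <- vapply(base_fits, function(f) f$rates[["lambda"]], numeric(1))
    for (k in seq_len(K)) {
      st_k <- reroot_on_branch(t, branches[k])
      g_species <- integer(length(conc$kind))
      g_species[is_leaf] <- st_k$leaf_id[leaf_names[is_leaf]]
      res <- dtl_fit_lambda_batch_cpp(st_k$M, st_k$child1, st_k$child2,
                                      st_k$m, st_k$root, fam_D, fam_R,
                                      conc$kind, g_species, conc$childA,
                                      conc$childB, conc$rootA, conc$rootB,
                                      d0, t0, l0, xtol = 1e-4)
      ll[k, ] <- res$loglik
      dm[k, ] <- d0; tm[k, ] <- t0; lm[k, ] <- res$lambda
      if (any(ll[k, ] < -1e299)) {
        i <- which(ll[k, ] < -1e299)[1]
        stop("reconciliation failed at root branch ", branches[k],
             ", family ", ids[i], ": zero probability under policy rates")
      }
      if (verbose) message("root branch ", branches[k], ": total ll = ",
                           signif(sum(ll[k, ]), 8))
    }
  }
  totals <- rowSums(ll)
  structure(list(ll = ll, delta = dm, tau = tm, lambda = lm,
                 policy = policy, branches = branches,
                 ref_branch = ref_branch, ref_fits = ref_fits,
                 totals = totals,
                 argmax = branches[which.max(totals)]),
            class = "root_scan")
}

#' @export
print.root_scan <- function(x, ...) {
  cat("root_scan (", policy_label(x$policy), "): ",
      nrow(x$ll), " roots x ", ncol(x$ll), " families; argmax branch ",
      x$argmax, "\n", sep = "")
  invisible(x)
}

#' Approximately unbiased root test by multiscale bootstrap
#'
#' Resamples families with replacement at several scales
#' (`n' = round(N / sigma^2)` per replicate), records for each candidate
#' root the fraction of replicates in which its summed log-likelihood is
#' maximal (ties split equally), and fits the signed distance `d` and
#' curvature `c` of the boundary via weighted least squares of
#' `z(sigma) = d * sigma + c / sigma` with `z = qnorm(1 - BP)`. The AU
#' p-value of each root is `1 - pnorm(d - c)`.
#'
#' Roots never (or always) maximal at any scale get p = 0 (or 1) and are
#' flagged rather than extrapolated.
#'
#' @param m A `root_scan` or a numeric K x N log-likelihood matrix with
#'   rownames identifying the roots.
#' @param B Bootstrap replicates per scale (`>= 1000` recommended).
#' @param scales Vector of sigma^2 scales.
#' @param seed RNG seed; results are deterministic given it.
#' @return An object of class `au_result`: data.frame `table` with
#'   `root`, `bp` (naive proportion at scale 1), `d`, `c`, `au_p`,
#'   `flag`; plus `argmax` (root with maximal total log-likelihood) and
#'   the settings.
#' @export
au_test <- function(m, B = 10000L, scales = seq(0.5, 1.4, by = 0.1),
                    seed = 1L) {
  ll <- if (inherits(m, "root_scan")) m$ll else m
  if (is.null(rownames(ll))) rownames(ll) <- seq_len(nrow(ll))
  K <- nrow(ll); N <- ncol(ll)
  if (K < 2L) stop("need at least 2 candidate roots")
  if (N < 2L) stop("need at least 2 families")
  if (B < 1L) stop("B must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  S <- length(scales)
  BP <- matrix(0, K, S)
  sig_actual <- numeric(S)
  for (s in seq_len(S)) {
    nprime <- max(1L, round(N / scales[s]))
    sig_actual[s] <- N / nprime
    counts <- rmultinom(B, nprime, rep(1 / N, N))   # N x B resample counts
    sums <- ll %*% counts                           # K x B root totals
    mx <- do.call(pmax, lapply(seq_len(K), function(k) sums[k, ]))
    ismax <- sums == rep(mx, each = K)
    ntied <- colSums(ismax)
    BP[, s] <- as.vector(ismax %*% (1 / ntied)) / B
  }

  sig <- sqrt(sig_actual)
  # z(sigma) = d / sigma + c * sigma: the signed distance d is read at
  # sigma -> 0 (n' -> infinity), the boundary curvature c grows with sigma
  X <- cbind(1 / sig, sig)
  d <- numeric(K); cc <- numeric(K); p <- numeric(K)
  flag <- character(K)
  for (k in seq_len(K)) {
    bp_raw <- BP[k, ]
    if (all(bp_raw <= 0)) { p[k] <- 0; d[k] <- Inf; cc[k] <- 0; flag[k] <- "off-support"; next }
    if (all(bp_raw >= 1)) { p[k] <- 1; d[k] <- -Inf; cc[k] <- 0; flag[k] <- "degenerate"; next }
    bp <- pmin(pmax(bp_raw, 1 / (2 * B)), 1 - 1 / (2 * B))
    z <- qnorm(1 - bp)
    w <- B * dnorm(z)^2 / (bp * (1 - bp))
    XtW <- t(X * w)
    beta <- solve(XtW %*% X, XtW %*% z)
    d[k] <- beta[1]; cc[k] <- beta[2]
    p[k] <- 1 - pnorm(d[k] - cc[k])
    flag[k] <- ""
  }
  sc1 <- which.min(abs(sig_actual - 1))
  tab <- data.frame(root = rownames(ll), bp = BP[, sc1], d = d, c = cc,
                    au_p = p, flag = flag, stringsAsFactors = FALSE)
  structure(list(table = tab, BP = BP, scales = scales,
                 sigma2_actual = sig_actual, B = B, seed = seed,
                 argmax = rownames(ll)[which.max(rowSums(ll))]),
            class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat("au_result: ", nrow(x$table), " roots, B = ", x$B, ", ",
      length(x$scales), " scales; argmax root ", x$argmax, "\n", sep = "")
  print(head(x$table[order(-x$table$au_p), ], 10), row.names = FALSE)
  invisible(x)
}

#' Root set retained by the AU test
#'
#' Roots with AU p-value above `alpha` are retained; the rest are
#' rejected. The root with the maximal total log-likelihood is always
#' retained (a root can never be rejected against itself), so the set is
#' never empty.
#'
#' @param a An `au_result`.
#' @param alpha Rejection threshold (default 0.05).
#' @return An object of class `root_set`: `retained`, `rejected`
#'   (character root ids), `alpha`, `argmax`.
#' @export
root_set <- function(a, alpha = 0.05) {
  stopifnot(inherits(a, "au_result"))
  keep <- a$table$au_p > alpha
  retained <- union(a$table$root[keep], a$argmax)
  rejected <- setdiff(a$table$root, retained)
  structure(list(retained = retained, rejected = rejected,
                 alpha = alpha, argmax = a$argmax),
            class = "root_set")
}

#' @export
print.root_set <- function(x, ...) {
  cat("root_set (alpha = ", x$alpha, "): ", length(x$retained),
      " retained of ", length(x$retained) + length(x$rejected),
      " [", paste(x$retained, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Write a root-scan matrix and an AU report to TSV
#'
#' @param scan A `root_scan`.
#' @param a An `au_result` for it.
#' @param set A `root_set`.
#' @param dir Output directory.
#' @param tag File-name tag.
#' @return Invisibly, the paths written.
#' @export
write_scan_tsv <- function(scan, a, set, dir, tag = "scan") {
  p1 <- file.path(dir, paste0(tag, "_loglik_matrix.tsv"))
  write.table(data.frame(root = rownames(scan$ll), scan$ll,
                         check.names = FALSE),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- a$table
  rep$retained <- rep$root %in% set$retained
  p2 <- file.path(dir, paste0(tag, "_au_report.tsv"))
  write.table(rep, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
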