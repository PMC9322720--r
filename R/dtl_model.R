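#' Per-opportunity event probabilities from DTL rates
#'
#' Rates are dimensionless weights relative to the unit speciation weight:
#' with `W = delta + tau + lambda + 1`, the probabilities of duplication,
#' transfer, loss, and speciation-or-observation per opportunity are
#' `delta/W`, `tau/W`, `lambda/W`, `1/W`; they sum to one.
#'
#' @param rates Numeric vector or list with elements `delta`, `tau`,
#'   `lambda` (all `>= 0`).
#' @return An object of class `event_probs`: list with `p_D`, `p_T`,
#'   `p_L`, `p_S`.
#' @examples
#' event_probs(c(delta = 1, tau = 1, lambda = 1))  # all 0.25
#' @export
event_probs <- function(rates) {
  r <- as_rates(rates)
  W <- r[["delta"]] + r[["tau"]] + r[["lambda"]] + 1
  structure(list(p_D = r[["delta"]] / W, p_T = r[["tau"]] / W,
                 p_L = r[["lambda"]] / W, p_S = 1 / W),
            class = "event_probs")
}

as_rates <- function(rates) {
  if (inherits(rates, "event_probs")) {
    # invert: delta = p_D / p_S etc.
    return(c(delta = rates$p_D / rates$p_S, tau = rates$p_T / rates$p_S,
             lambda = rates$p_L / rates$p_S))
  }
  r <- unlist(rates)
  if (is.null(names(r)) || !all(c("delta", "tau", "lambda") %in% names(r))) {
    if (length(r) == 3L) names(r) <- c("delta", "tau", "lambda")
    else stop("rates must have elements delta, tau, lambda")
  }
  r <- r[c("delta", "tau", "lambda")]
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  r
}

#' T:D ratio of a rate triple
#'
#' @param rates Rates as in [event_probs()].
#' @return `tau / delta`, or `NA` flagged via attribute `undefined` when
#'   `delta` is 0.
#' @export
td_ratio <- function(rates) {
  r <- as_rates(rates)
  if (r[["delta"]] == 0)
    return(structure(NA_real_, undefined = TRUE))
  unname(r[["tau"]] / r[["delta"]])
}

#' Per-branch extinction probabilities
#'
#' Probability that a single gene copy entering each species-tree branch
#' leaves no observed descendant, accounting for loss, duplication,
#' transfer, and per-species missing-gene fractions. Solved as a fixed
#' point iterated from all zeros until the maximum absolute change is
#' below `tol` (default 1e-12, capped at `maxit` sweeps).
#'
#' @param s A [species_tree()].
#' @param p An `event_probs` object or a rate vector.
#' @param tol,maxit Fixed-point tolerance and sweep cap.
#' @return Numeric vector of length `s$M` (one entry per branch, stem
#'   included), with attributes `iterations` and `residual`.
#' @export
extinction_probabilities <- function(s, p, tol = 1e-12, maxit = 10000L) {
  stopifnot(inherits(s, "species_tree"))
  r <- as_rates(p)
  out <- dtl_extinction_cpp(s$M, s$child1, s$child2, s$m,
                            r[["delta"]], r[["tau"]], r[["lambda"]],
                            tol, as.integer(maxit))
  structure(out$E, iterations = out$iterations, residual = out$residual)
}

#' Undated DTL reconciliation log-likelihood of a gene family
#'
#' Marginal probability of observing the family's (unrooted) topology and
#' leaf placement given a rooted species tree and a rate triple, summed
#' over all gene-tree rootings and origination branches (stem included by
#' default), and conditioned on the family being observed at all. Computed
#' with per-subtree log scaling, so large families never underflow.
#'
#' @param g A `gene_family` (see [map_leaves_to_species()]).
#' @param s A [species_tree()].
#' @param rates Rate triple (`delta`, `tau`, `lambda`).
#' @param orig_stem Allow origination on the stem branch above the root?
#' @param encoding Optional precomputed `gene_encoding(g, s)` (internal
#'   cache for repeated calls during optimization).
#' @return Log-likelihood (`<= 0`); `-Inf` with attribute
#'   `reason` when the family has probability zero under the rates (e.g. a
#'   multi-copy family with `delta = tau = 0`).
#' @export
family_loglik <- function(g, s, rates, orig_stem = TRUE, encoding = NULL) {
  stopifnot(inherits(g, "gene_family"), inherits(s, "species_tree"))
  r <- as_rates(rates)
  enc <- if (is.null(encoding)) gene_encoding(g, s) else encoding
  out <- dtl_loglik_cpp(s$M, s$child1, s$child2, s$m, s$root,
                        enc$kind, enc$g_species, enc$childA, enc$childB,
                        enc$rootA, enc$rootB,
                        r[["delta"]], r[["tau"]], r[["lambda"]],
                        orig_stem)
  ll <- out$loglik
  if (!out$feasible) attr(ll, "reason") <- out$reason
  ll
}

#' Maximum-likelihood DTL rates for one gene family
#'
#' Free mode maximizes the reconciliation likelihood over
#' `(delta, tau, lambda)` with a Nelder-Mead simplex in log10-rate space
#' (bounds `[1e-10, 10]`, restart once from the best point; deterministic).
#' The search is seeded at `delta = tau` — the 1:1 T:D seed that mirrors
#' the default behaviour of reconciliation software. Fixed-T:D mode holds
#' `delta` and `tau` at supplied values and optimizes only `lambda`
#' (Brent).
#'
#' @param g A `gene_family`.
#' @param s A [species_tree()].
#' @param mode `"free"` or `"fixed_td"`.
#' @param delta0,tau0 Fixed rates for `mode = "fixed_td"`.
#' @param init Starting rates for free mode (named vector); default seeds
#'   `delta = tau = 0.1`, `lambda = 0.2`.
#' @param step Initial simplex step in log10-rate units (free mode); use a
#'   small step when warm-starting from a nearby optimum.
#' @param restart Restart the simplex once from the best point (free
#'   mode).
#' @param reltol Convergence tolerance on the log-likelihood.
#' @param maxit Iteration cap per simplex run.
#' @param orig_stem Passed to [family_loglik()].
#' @return An object of class `family_fit`: list with `id`, `mode`,
#'   `rates`, `loglik`, `td`, `converged`, `evals`.
#' @export
optimize_rates <- function(g, s, mode = c("free", "fixed_td"),
                           delta0 = NULL, tau0 = NULL,
                           init = c(delta = 0.1, tau = 0.1, lambda = 0.2),
                           step = 0.5, restart = TRUE,
                           reltol = 1e-8, maxit = 500L, orig_stem = TRUE) {
  mode <- match.arg(mode)
  enc <- gene_encoding(g, s)
  lo <- -10; hi <- 1  # log10 bounds [1e-10, 10]
  evals <- 0L
  if (mode == "fixed_td") {
    if (is.null(delta0) || is.null(tau0))
      stop("fixed_td mode needs delta0 and tau0")
    if (delta0 < 0 || tau0 < 0) stop("rates must be >= 0")
    f <- function(x) {
      evals <<- evals + 1L
      lam <- 10^min(max(x, lo), hi)
      ll <- family_loglik(g, s, c(delta = delta0, tau = tau0, lambda = lam),
                          orig_stem = orig_stem, encoding = enc)
      if (!is.finite(ll)) -1e300 else as.numeric(ll)
    }
    op <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    rates <- c(delta = delta0, tau = tau0,
               lambda = 10^min(max(op$maximum, lo), hi))
    fit <- list(id = g$id, mode = mode, rates = rates,
                loglik = op$objective, td = td_ratio(rates),
                converged = TRUE, evals = evals)
  } else {
    r0 <- as_rates(init)
    par0 <- pmin(pmax(log10(pmax(r0, 1e-10)), lo), hi)
    op <- dtl_fit_free_cpp(s$M, s$child1, s$child2, s$m, s$root,
                           enc$kind, enc$g_species, enc$childA, enc$childB,
                           enc$rootA, enc$rootB,
                           init_log10 = as.numeric(par0), step = step,
                           reltol = reltol, maxit = as.integer(maxit),
                           restart = restart, orig_stem = orig_stem)
    rates <- c(delta = op$rates[1], tau = op$rates[2], lambda = op$rates[3])
    fit <- list(id = g$id, mode = mode, rates = rates,
                loglik = op$loglik, td = td_ratio(rates),
                converged = TRUE, evals = op$evals)
  }
  class(fit) <- "family_fit"
  fit
}

#' @export
print.family_fit <- function(x, ...) {
  cat("family_fit '", x$id, "' (", x$mode, "): ",
      "delta=", signif(x$rates[["delta"]], 4),
      " tau=", signif(x$rates[["tau"]], 4),
      " lambda=", signif(x$rates[["lambda"]], 4),
      " loglik=", signif(x$loglik, 8),
      if (!x$converged) " [not converged]", "\n", sep = "")
  invisible(x)
}

#' Tabulate a collection of family fits
#'
#' @param fits List of `family_fit` objects.
#' @return data.frame with columns `family_id`, `mode`, `delta`, `tau`,
#'   `lambda`, `loglik`, `td_ratio`, `converged`.
#' @export
fits_table <- function(fits) {
  data.frame(
    family_id = vapply(fits, function(f) f$id, character(1)),
    mode = vapply(fits, function(f) f$mode, character(1)),
    delta = vapply(fits, function(f) f$rates[["delta"]], numeric(1)),
    tau = vapply(fits, function(f) f$rates[["tau"]], numeric(1)),
    lambda = vapply(fits, function(f) f$rates[["lambda"]], numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    td_ratio = vapply(fits, function(f) as.numeric(f$td), numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
}
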