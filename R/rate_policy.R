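#' Construct a T:D rate policy
#'
#' A rate policy controls how duplication and transfer rates are set during
#' root scanning: `"free"` lets both be optimized per family per root (the
#' 1:1-seeded default of reconciliation software); `"fixed_ratio"` pins the
#' transfer:duplication ratio to `ratio` for every family;
#' `"ratio_floor"` only adjusts families whose freely fitted T:D falls
#' below `ratio`.
#'
#' The ratio is always stated as T:D. The literal string form is accepted
#' to avoid inversion bugs: `"50:1"` means transfers 50 times more frequent
#' than duplications (`ratio = 50`), `"1:2"` means duplication-dominated
#' (`ratio = 0.5`).
#'
#' @param kind `"free"`, `"fixed_ratio"`, or `"ratio_floor"`.
#' @param ratio Numeric T:D ratio (`> 0`), or a string like `"50:1"`.
#' @return An object of class `rate_policy`.
#' @examples
#' rate_policy("fixed_ratio", "50:1")
#' rate_policy("ratio_floor", 50)
#' @export
rate_policy <- function(kind = c("free", "fixed_ratio", "ratio_floor"),
                        ratio = NULL) {
  kind <- match.arg(kind)
  if (kind != "free") {
    if (is.null(ratio)) stop(kind, " policy needs a ratio")
    ratio <- parse_td_ratio(ratio)
  } else ratio <- NA_real_
  structure(list(kind = kind, ratio = ratio), class = "rate_policy")
}

#' Parse a T:D ratio given as number or "T:D" literal
#'
#' @param x Numeric or string (`"50:1"`, `"1:2"`, `"50"`).
#' @return Positive numeric ratio tau/delta.
#' @export
parse_td_ratio <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v) || !length(v) %in% 1:2) stop("cannot parse T:D ratio: ", x)
    x <- if (length(v) == 2L) v[1] / v[2] else v[1]
  }
  x <- as.numeric(x)
  if (!is.finite(x) || x <= 0) stop("T:D ratio must be finite and > 0")
  x
}

#' @export
print.rate_policy <- function(x, ...) {
  cat("rate_policy:", x$kind,
      if (x$kind != "free") paste0("(T:D = ", signif(x$ratio, 6), ":1)"), "\n")
  invisible(x)
}

#' Short label for a policy (used in report tables)
#' @param p A `rate_policy`.
#' @return Character scalar.
#' @export
policy_label <- function(p) {
  if (p$kind == "free") return("free")
  if (p$kind == "fixed_ratio") return(sprintf("fixed_%g:1", p$ratio))
  sprintf("floor_%g:1", p$ratio)
}

#' Constrain the duplication rate to a target T:D ratio
#'
#' Given an optimized transfer rate, the duplication rate is defined as
#' that transfer rate divided by the target ratio, so the constrained pair
#' satisfies `tau / delta = ratio` exactly (e.g. transfer 0.5 at 50:1
#' gives duplication 0.01).
#'
#' @param tau_opt Optimized transfer rate (`>= 0`).
#' @param ratio Target T:D ratio (`> 0`), numeric or `"50:1"` form.
#' @return Named vector `c(delta, tau)`; if `tau_opt` is 0 the pair is
#'   degenerate (`delta = 0`) and carries attribute `degenerate = TRUE`.
#' @examples
#' constrain_td(0.5, 50)        # delta = 0.01
#' @export
constrain_td <- function(tau_opt, ratio) {
  ratio <- parse_td_ratio(ratio)
  if (tau_opt < 0) stop("transfer rate must be >= 0")
  out <- c(delta = tau_opt / ratio, tau = tau_opt)
  if (tau_opt == 0) {
    warning("tau_opt = 0: constrained pair is degenerate (delta = 0)")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Apply a T:D floor to a freely fitted family
#'
#' If the fitted T:D ratio is below `ratio_min` (including the case
#' `tau = 0` with `delta > 0`, where the ratio is 0), the duplication rate
#' is replaced by `tau / ratio_min` and the transfer rate kept; otherwise
#' the fitted pair is returned unchanged. Idempotent. A fitted
#' `delta = 0` (ratio undefined or infinite) is never adjusted.
#'
#' @param fit A `family_fit` from free mode, or a named rate vector.
#' @param ratio_min Minimum T:D ratio (numeric or `"50:1"` form).
#' @return Named vector `c(delta, tau)` with attribute `adjusted`.
#' @export
apply_td_floor <- function(fit, ratio_min) {
  ratio_min <- parse_td_ratio(ratio_min)
  r <- if (inherits(fit, "family_fit")) fit$rates else as_rates(fit)
  delta <- r[["delta"]]; tau <- r[["tau"]]
  adjusted <- FALSE
  if (delta > 0 && tau / delta < ratio_min) {
    delta <- tau / ratio_min
    adjusted <- TRUE
  }
  structure(c(delta = delta, tau = tau), adjusted = adjusted)
}

#' Gain/loss summary statistics across family fits
#'
#' Per-family gain is `delta + tau`; the loss:gain ratio L:G is the mean
#' loss rate divided by the mean gain rate (means, not medians). An L:G
#' above one indicates genome reduction, below one genome growth.
#' Medians use the midpoint convention for even counts and the standard
#' deviation uses the sample (n-1) denominator.
#'
#' @param fits List of `family_fit` objects, or a data.frame with columns
#'   `delta`, `tau`, `lambda` (e.g. from [fits_table()]).
#' @return An object of class `rate_summary`: data.frame `stats` with
#'   mean/median/std for transfer, duplication, loss, gain; `loss_gain`
#'   (the L:G ratio, `NA` with flag if all gains are zero); and
#'   `classification` (`"reduction"`, `"growth"`, or `"balanced"`).
#' @export
summarize_rates <- function(fits) {
  df <- if (is.data.frame(fits)) fits else fits_table(fits)
  if (nrow(df) < 1L) stop("need at least one family")
  gain <- df$delta + df$tau
  stat <- function(x) c(mean = mean(x), median = median(x), std = sd(x))
  stats <- rbind(transfer = stat(df$tau), duplication = stat(df$delta),
                 loss = stat(df$lambda), gain = stat(gain))
  stats <- as.data.frame(stats)
  if (nrow(df) == 1L) stats$std <- 0
  lg <- if (mean(gain) == 0) NA_real_ else mean(df$lambda) / mean(gain)
  cls <- if (is.na(lg)) "undefined" else if (lg > 1) "reduction"
         else if (lg < 1) "growth" else "balanced"
  structure(list(stats = stats, loss_gain = lg, classification = cls,
                 n = nrow(df)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("rate_summary over", x$n, "families\n")
  print(signif(as.matrix(x$stats), 4))
  cat("L:G =", if (is.na(x$loss_gain)) "undefined (no gains)"
      else signif(x$loss_gain, 4), "->", x$classification, "\n")
  invisible(x)
}

#' Write a rate summary row to a TSV mirroring the flux tables
#'
#' @param summaries Named list of `rate_summary` objects (names are
#'   dataset/policy tags).
#' @param path Output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_rate_summary_tsv <- function(summaries, path) {
  rows <- lapply(names(summaries), function(tag) {
    s <- summaries[[tag]]
    st <- s$stats
    out <- data.frame(dataset = tag)
    for (nm in rownames(st))
      for (col in colnames(st))
        out[[paste(nm, col, sep = "_")]] <- st[nm, col]
    out$loss_gain_ratio <- s$loss_gain
    out
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
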