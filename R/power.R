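#' Rank families by a fitted rate and cut into consecutive blocks
#'
#' Families are sorted in decreasing order of the chosen fitted rate
#' (ties broken by family id, so blocks are deterministic) and split into
#' consecutive non-overlapping blocks of exactly `block_size`; a trailing
#' remainder is discarded.
#'
#' @param fits List of `family_fit` objects or a [fits_table()]
#'   data.frame.
#' @param key `"duplication"`, `"transfer"`, or `"loss"`.
#' @param block_size Families per block (default 100).
#' @return List with `blocks` (list of character id vectors),
#'   `mean_rate` (per-block mean of the chosen rate, non-increasing),
#'   `key`, `discarded` (ids dropped from the tail).
#' @export
rank_and_block <- function(fits, key = c("duplication", "transfer", "loss"),
                           block_size = 100L) {
  key <- match.arg(key)
  df <- if (is.data.frame(fits)) fits else fits_table(fits)
  if (nrow(df) < block_size)
    stop("need at least ", block_size, " families, got ", nrow(df))
  col <- c(duplication = "delta", transfer = "tau", loss = "lambda")[[key]]
  ord <- order(-df[[col]], df$family_id)
  df <- df[ord, ]
  nb <- nrow(df) %/% block_size
  idx <- seq_len(nb * block_size)
  blocks <- split(df$family_id[idx], rep(seq_len(nb), each = block_size))
  mean_rate <- vapply(split(df[[col]][idx], rep(seq_len(nb), each = block_size)),
                      mean, numeric(1))
  list(blocks = unname(blocks), mean_rate = unname(mean_rate), key = key,
       discarded = df$family_id[-idx])
}

#' Tie-corrected Spearman rank correlation with two-tailed p-value
#'
#' The coefficient is the Pearson correlation of midranks. For `n >= 10`
#' the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df; below that an
#' exact permutation distribution is enumerated.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return List with `rho` and `p` (`rho = NA` flagged `undefined` when
#'   either input is constant).
#' @examples
#' spearman(c(1, 2, 3), c(3, 1, 2))   # rho = -0.5
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = structure(NA_real_, undefined = TRUE), p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n >= 10L) {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    perms <- .all_permutations(n)
    rhos <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as an (n!) x n matrix, built by insertion
.all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(p) * k, k)
    row <- 1L
    for (i in seq_len(nrow(p))) for (pos in seq_len(k)) {
      out[row, ] <- append(p[i, ], k, after = pos - 1L)
      row <- row + 1L
    }
    p <- out
  }
  p
}

#' Block-ranked rooting power analysis
#'
#' The procedure behind the duplication-informativeness result: rank
#' families by a freely fitted rate, AU-test each consecutive block of
#' `block_size` families, count the retained roots per block, and
#' correlate (Spearman) the block's mean rate with its retained-root
#' count. Per-block AU tests subset the columns of one globally computed
#' free-policy log-likelihood matrix rather than re-scanning.
#'
#' @param scan A free-policy `root_scan` covering all families.
#' @param fits Free-mode fits used for the ranking (defaults to the
#'   scan's reference fits).
#' @param key Rate to rank by (`"duplication"`, `"transfer"`, `"loss"`).
#' @param block_size Families per block.
#' @param alpha AU rejection threshold.
#' @param B,scales AU settings (see [au_test()]).
#' @param seed Base seed; block `b` uses `seed + b`.
#' @return An object of class `power_curve`: data.frame `table`
#'   (`block`, `mean_rate`, `n_roots_retained`), `rho`, `p`, `key`.
#' @export
power_analysis <- function(scan, fits = NULL,
                           key = c("duplication", "transfer", "loss"),
                           block_size = 100L, alpha = 0.05,
                           B = 10000L, scales = seq(0.5, 1.4, by = 0.1),
                           seed = 1L) {
  key <- match.arg(key)
  stopifnot(inherits(scan, "root_scan"))
  if (is.null(fits)) fits <- scan$ref_fits
  if (is.null(fits)) stop("free-mode fits required for ranking")
  rb <- rank_and_block(fits, key, block_size)
  nb <- length(rb$blocks)
  nroots <- integer(nb)
  for (b in seq_len(nb)) {
    sub <- scan$ll[, rb$blocks[[b]], drop = FALSE]
    a <- au_test(sub, B = B, scales = scales, seed = seed + b)
    nroots[b] <- length(root_set(a, alpha)$retained)
  }
  sp <- if (nb >= 3L) spearman(rb$mean_rate, as.numeric(nroots))
        else list(rho = structure(NA_real_, undefined = TRUE), p = NA_real_)
  structure(list(table = data.frame(block = seq_len(nb),
                                    mean_rate = rb$mean_rate,
                                    n_roots_retained = nroots),
                 rho = sp$rho, p = sp$p, key = key,
                 block_size = block_size, alpha = alpha),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat("power_curve (", x$key, ", blocks of ", x$block_size, "): rho = ",
      signif(x$rho, 3), ", p = ", signif(x$p, 3), "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a power curve to TSV
#' @param pc A `power_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_power_tsv <- function(pc, path) {
  df <- pc$table
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# key=%s rho=%.6g p=%.6g\n", pc$key, pc$rho, pc$p),
      file = path, append = TRUE)
  invisible(path)
}
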