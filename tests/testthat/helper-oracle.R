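# Independent oracle for the reconciliation likelihood: exhaustive
# enumeration of event histories with at most `jmax` duplication, transfer
# or loss events, organised as a convolution over the exact event count.
# No fixed-point closures, no geometric-series tricks: histories terminate
# because every D/T/L event decrements the remaining budget and speciations
# walk down the finite species tree. For small rates (<= 0.05) histories
# with >= 4 events contribute < 1e-8, so jmax = 3 pins the likelihood to
# ~1e-6 relative accuracy.

oracle_family_lik <- function(gf, st, rates, jmax = 3L, orig_stem = TRUE) {
  r <- dtlroot:::as_rates(rates)
  W <- sum(r) + 1
  pD <- r[["delta"]] / W; pT <- r[["tau"]] / W
  pL <- r[["lambda"]] / W; pS <- 1 / W
  M <- st$M; J <- jmax + 1L
  po <- seq_len(M)   # branch ids are postorder by construction
  c1 <- st$child1; c2 <- st$child2; m <- st$m

  conv <- function(a, b, j) {       # sum_{j1+j2=j} a[j1+1] b[j2+1]
    if (j < 0) return(0)
    s <- 0
    for (j1 in 0:j) s <- s + a[j1 + 1] * b[j - j1 + 1]
    s
  }

  # extinction with exactly j events: ex[e, j+1]
  ex <- matrix(0, M, J)
  for (j in 0:jmax) {
    for (e in po) {
      v <- 0
      if (j == 1) v <- v + pL
      v <- v + pD * conv(ex[e, ], ex[e, ], j - 1)
      if (M > 1) {
        tsum <- 0
        for (h in seq_len(M)) if (h != e)
          tsum <- tsum + conv(ex[e, ], ex[h, ], j - 1)
        v <- v + pT * tsum / (M - 1)
      }
      if (c1[e] == 0L) {
        if (j == 0) v <- v + pS * m[e]
      } else {
        v <- v + pS * conv(ex[c1[e], ], ex[c2[e], ], j)
      }
      ex[e, j + 1] <- v
    }
  }

  enc <- dtlroot:::gene_encoding(gf, st)
  D <- length(enc$kind)
  P <- vector("list", D)          # each M x J

  node_val <- function(e, j, self, leaf_sp, Pv, Pw) {
    # `self` is the partially filled M x J matrix for this gene node
    v <- 0
    if (!is.null(leaf_sp) && e == leaf_sp && j == 0) v <- v + pS * (1 - m[e])
    if (!is.null(Pv)) {
      v <- v + pD * conv(Pv[e, ], Pw[e, ], j - 1)
      if (M > 1) {
        ts <- 0
        for (h in seq_len(M)) if (h != e)
          ts <- ts + conv(Pv[e, ], Pw[h, ], j - 1) + conv(Pw[e, ], Pv[h, ], j - 1)
        v <- v + pT * ts / (M - 1)
      }
      if (c1[e] != 0L)
        v <- v + pS * (conv(Pv[c1[e], ], Pw[c2[e], ], j) +
                       conv(Pv[c2[e], ], Pw[c1[e], ], j))
    }
    # duplication with one daughter extinct (two daughter orderings)
    v <- v + 2 * pD * conv(self[e, ], ex[e, ], j - 1)
    if (M > 1) {
      ts1 <- 0; ts2 <- 0
      for (h in seq_len(M)) if (h != e) {
        ts1 <- ts1 + conv(self[h, ], ex[e, ], j - 1)   # donor extinct
        ts2 <- ts2 + conv(self[e, ], ex[h, ], j - 1)   # recipient extinct
      }
      v <- v + pT * (ts1 + ts2) / (M - 1)
    }
    if (c1[e] != 0L)                                   # speciation-loss
      v <- v + pS * (conv(self[c1[e], ], ex[c2[e], ], j) +
                     conv(self[c2[e], ], ex[c1[e], ], j))
    v
  }

  fill_node <- function(leaf_sp, Pv, Pw) {
    self <- matrix(0, M, J)
    for (j in 0:jmax)
      for (e in po)
        self[e, j + 1] <- node_val(e, j, self, leaf_sp, Pv, Pw)
    self
  }

  for (d in seq_len(D)) {
    if (enc$kind[d] == 0L)
      P[[d]] <- fill_node(enc$g_species[d], NULL, NULL)
    else
      P[[d]] <- fill_node(NULL, P[[enc$childA[d]]], P[[enc$childB[d]]])
  }

  orig <- seq_len(M)
  if (!orig_stem) orig <- setdiff(orig, st$root)
  total <- 0
  for (rr in seq_along(enc$rootA)) {
    Pr <- fill_node(NULL, P[[enc$rootA[rr]]], P[[enc$rootB[rr]]])
    total <- total + sum(Pr[orig, ])
  }
  meanEx <- mean(rowSums(ex)[orig])
  total / length(orig) / (1 - meanEx)
}

# Independent Jacobi solve of the extinction map, written directly from its
# definition (used to cross-check the compiled solver).
oracle_extinction <- function(st, rates, tol = 1e-14, maxit = 1e5) {
  r <- dtlroot:::as_rates(rates)
  W <- sum(r) + 1
  pD <- r[["delta"]] / W; pT <- r[["tau"]] / W
  pL <- r[["lambda"]] / W; pS <- 1 / W
  M <- st$M
  E <- numeric(M)
  for (it in seq_len(maxit)) {
    Ebar <- (sum(E) - E) / max(M - 1, 1)
    tail <- ifelse(st$child1 == 0L, pS * st$m,
                   pS * E[pmax(st$child1, 1L)] * E[pmax(st$child2, 1L)])
    En <- pL + pD * E^2 + pT * Ebar * E + tail
    if (max(abs(En - E)) < tol) return(En)
    E <- En
  }
  stop("oracle extinction did not converge")
}
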