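# Shared fixtures and independent oracles for the test suite.

panel_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_panel()
    cache
  }
})

# Brute-force maximum common connected substructure size (atom unit).
#
# Independent of the package's backtracking search: enumerates atom SUBSETS
# of A from the largest size down, tries every element-compatible injective
# assignment into B, and accepts a subset when the common-edge graph over it
# is connected. Only intended for small molecules (<= ~8 heavy atoms).
oracle_mcs_atoms <- function(A, B, charge_sensitive = FALSE, bond_exact = FALSE) {
  adjA <- brushscreen:::adjacency_matrix_orders(A)
  adjB <- brushscreen:::adjacency_matrix_orders(B)
  keyA <- if (charge_sensitive) paste(A$atoms$element, A$atoms$charge) else A$atoms$element
  keyB <- if (charge_sensitive) paste(B$atoms$element, B$atoms$charge) else B$atoms$element
  nA <- length(keyA); nB <- length(keyB)

  bond_compat <- function(oa, ob) {
    if (oa == 0L || ob == 0L) return(FALSE)
    if (!bond_exact) return(TRUE)
    oa == ob
  }
  connected_common <- function(S, f) {
    s <- length(S)
    if (s == 1L) return(TRUE)
    seen <- logical(s); seen[1L] <- TRUE; queue <- 1L
    while (length(queue) > 0L) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(s)) {
        if (!seen[j] && bond_compat(adjA[S[i], S[j]], adjB[f[i], f[j]])) {
          seen[j] <- TRUE; queue <- c(queue, j)
        }
      }
    }
    all(seen)
  }
  inject <- function(S, pos, f, usedB) {
    if (pos > length(S)) return(connected_common(S, f))
    for (cand in which(keyB == keyA[S[pos]] & !usedB)) {
      f[pos] <- cand; usedB[cand] <- TRUE
      if (inject(S, pos + 1L, f, usedB)) return(TRUE)
      usedB[cand] <- FALSE
    }
    FALSE
  }
  for (s in seq(min(nA, nB), 1L)) {
    subsets <- utils::combn(nA, s)
    for (k in seq_len(ncol(subsets))) {
      S <- subsets[, k]
      if (inject(S, 1L, integer(length(S)), logical(nB))) return(s)
    }
  }
  0L
}

# random symmetric distance matrix with zero diagonal
random_dist_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2, 0.1, 10)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- sprintf("L%02d", seq_len(n))
  m
}
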