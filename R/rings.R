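#' Perceive the smallest set of smallest rings
#'
#' Computes an SSSR-style ring set: for every bond the smallest cycle through
#' it is found by breadth-first search, candidate cycles are sorted by size,
#' and a linearly independent subset (over GF(2) on the bond-incidence
#' vectors) of cardinality `bonds - atoms + 1` is retained. Atom and bond
#' `in_ring` flags are set accordingly.
#'
#' @param mol a molecule
#' @return the molecule with `rings`, `atoms$in_ring` and `bonds$in_ring`
#'   filled in
#' @export
perceive_rings <- function(mol) {
  nA <- n_atoms(mol); nB <- n_bonds(mol)
  n_rings <- nB - nA + 1L
  mol$rings <- list()
  mol$atoms$in_ring <- rep(FALSE, nA)
  mol$bonds$in_ring <- rep(FALSE, nB)
  if (n_rings <= 0L) return(mol)

  adj <- adjacency_list(mol)
  bond_id <- matrix(0L, nA, nA)
  for (k in seq_len(nB)) {
    bond_id[mol$bonds$a1[k], mol$bonds$a2[k]] <- k
    bond_id[mol$bonds$a2[k], mol$bonds$a1[k]] <- k
  }

  # smallest cycle through each bond: BFS from a1 to a2 avoiding the bond
  candidates <- list()
  for (k in seq_len(nB)) {
    s <- mol$bonds$a1[k]; t <- mol$bonds$a2[k]
    parent <- rep(0L, nA); parent[s] <- -1L
    queue <- s; found <- FALSE
    while (length(queue) > 0L && !found) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (v == s && w == t) next
        if (parent[w] == 0L && w != s) {
          parent[w] <- v
          if (w == t) { found <- TRUE; break }
          queue <- c(queue, w)
        }
      }
    }
    if (found) {
      path <- t
      v <- t
      while (parent[v] != -1L) { v <- parent[v]; path <- c(path, v) }
      ring <- path  # cycle atoms in order; bond s-t closes it
      candidates[[length(candidates) + 1L]] <- ring
    }
  }
  if (length(candidates) == 0L) return(mol)

  # canonical form for dedup: sorted atom set
  keys <- vapply(candidates, function(r) paste(sort(r), collapse = "-"), "")
  candidates <- candidates[!duplicated(keys)]
  candidates <- candidates[order(lengths(candidates),
                                 vapply(candidates, function(r) paste(sort(r), collapse = "-"), ""))]

  ring_bond_vec <- function(ring) {
    v <- logical(nB)
    m <- length(ring)
    for (i in seq_len(m)) {
      a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
      v[bond_id[a, b]] <- TRUE
    }
    v
  }

  chosen <- list(); basis <- list()
  for (r in candidates) {
    if (length(chosen) == n_rings) break
    v <- ring_bond_vec(r)
    red <- v
    for (b in basis) {
      pivot <- which(b)[1L]
      if (red[pivot]) red <- xor(red, b)
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      chosen[[length(chosen) + 1L]] <- r
    }
  }

  mol$rings <- chosen
  for (r in chosen) {
    mol$atoms$in_ring[r] <- TRUE
    m <- length(r)
    for (i in seq_len(m)) {
      a <- r[i]; b <- r[if (i == m) 1L else i + 1L]
      mol$bonds$in_ring[bond_id[a, b]] <- TRUE
    }
  }
  mol
}

#' Ring atom sets of a molecule
#'
#' @param mol a molecule
#' @return list of integer vectors, one per perceived ring (empty for acyclic
#'   molecules)
#' @export
ring_perception <- function(mol) {
  perceive_rings(mol)$rings
}

#' Kekulize aromatic rings
#'
#' Assigns alternating single/double orders to aromatic bonds so that the
#' valence model applies uniformly. Atoms that contribute a lone pair to the
#' aromatic sextet (aromatic O/S, pyrrole-type N with an explicit hydrogen or
#' three connections and no positive charge) receive no ring double bond; all
#' other aromatic atoms must be matched by exactly one double bond, found by
#' backtracking over the aromatic bond set. Aromatic flags are retained.
#'
#' @param mol a molecule
#' @return the molecule with integer orders on all bonds
#' @noRd
kekulize <- function(mol) {
  arom_bonds <- which(mol$bonds$aromatic)
  if (length(arom_bonds) == 0L) return(mol)

  deg <- atom_degrees(mol)
  # does an aromatic atom already carry an explicit double bond?
  has_double <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (!mol$bonds$aromatic[k] && mol$bonds$order[k] >= 2L) {
      has_double[mol$bonds$a1[k]] <- TRUE
      has_double[mol$bonds$a2[k]] <- TRUE
    }
  }

  needs <- vapply(seq_len(n_atoms(mol)), function(a) {
    if (!mol$atoms$aromatic[a]) return(FALSE)
    el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
    if (has_double[a]) return(FALSE)
    if (el %in% c("O", "S")) return(FALSE)
    if (el %in% c("N", "P")) {
      if (ch > 0L) return(TRUE)                      # pyridinium-type n+
      if (ch < 0L) return(FALSE)                     # anionic n-
      # pyrrole-type: explicit H or three connections contribute the lone pair
      if (mol$atoms$implicit_h[a] > 0L || deg[a] >= 3L) return(FALSE)
      return(TRUE)                                   # pyridine-type
    }
    TRUE  # aromatic carbon
  }, logical(1L))

  need_idx <- which(needs)
  if (length(need_idx) == 0L) return(mol)

  # backtracking perfect matching on atoms needing a double bond
  matched <- rep(0L, n_atoms(mol))
  bond_between <- function(a, b) {
    for (k in arom_bonds) {
      if ((mol$bonds$a1[k] == a && mol$bonds$a2[k] == b) ||
          (mol$bonds$a1[k] == b && mol$bonds$a2[k] == a)) return(k)
    }
    0L
  }
  adj <- adjacency_list(mol)

  assign_rec <- function(idx) {
    if (idx > length(need_idx)) return(TRUE)
    a <- need_idx[idx]
    if (matched[a] > 0L) return(assign_rec(idx + 1L))
    for (b in sort(adj[[a]])) {
      if (needs[b] && matched[b] == 0L && bond_between(a, b) > 0L) {
        matched[a] <<- b; matched[b] <<- a
        if (assign_rec(idx + 1L)) return(TRUE)
        matched[a] <<- 0L; matched[b] <<- 0L
      }
    }
    FALSE
  }
  if (!assign_rec(1L)) {
    stop(sprintf("cannot kekulize aromatic system of '%s'", mol$id))
  }
  for (k in arom_bonds) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    mol$bonds$order[k] <- if (matched[a] == b) 2L else 1L
  }
  mol
}
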