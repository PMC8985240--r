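#' Specification for the synthetic small-molecule generator
#'
#' The generator emulates the panel's feature space: small organic molecules
#' (acyclic chains or one ring), C/N/O/S/P compositions, occasional double
#' bonds, and optional balanced charge pairs emulating zwitterions
#' (quaternary N+ paired with a terminal O-).
#'
#' @param seed integer random seed
#' @param n_molecules number of molecules to generate
#' @param heavy_atom_range integer 2-vector (min, max) heavy atoms, min >= 1
#' @param element_weights named sampling weights over C, N, O, S, P
#'   (normalized internally)
#' @param ring_probability probability of closing one ring
#' @param charge_pair_probability probability of inserting a +/- charge pair
#' @return a `synthetic_spec` object
#' @export
synthetic_spec <- function(seed = 1L, n_molecules = 100L,
                           heavy_atom_range = c(3L, 12L),
                           element_weights = c(C = 0.62, N = 0.12, O = 0.2,
                                               S = 0.04, P = 0.02),
                           ring_probability = 0.25,
                           charge_pair_probability = 0.2) {
  if (length(heavy_atom_range) != 2L || heavy_atom_range[1L] < 1L ||
      heavy_atom_range[2L] < heavy_atom_range[1L]) {
    stop("heavy_atom_range must be (min, max) with min >= 1")
  }
  if (ring_probability < 0 || ring_probability > 1 ||
      charge_pair_probability < 0 || charge_pair_probability > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (any(element_weights < 0) || sum(element_weights) <= 0) {
    stop("element_weights must be non-negative and sum to > 0")
  }
  w <- element_weights / sum(element_weights)
  structure(
    list(seed = as.integer(seed), n_molecules = as.integer(n_molecules),
         heavy_atom_range = as.integer(heavy_atom_range),
         element_weights = w, ring_probability = ring_probability,
         charge_pair_probability = charge_pair_probability),
    class = "synthetic_spec"
  )
}

# maximum bonding capacity used during construction (conservative single
# valence per element)
GEN_CAPACITY <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)

# sample() without the scalar-x surprise
pick_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# build one random molecule graph honouring the valence model
random_molecule_graph <- function(spec, id) {
  n <- pick_one(seq(spec$heavy_atom_range[1L], spec$heavy_atom_range[2L]))
  want_charges <- stats::runif(1) < spec$charge_pair_probability
  elems <- sample(names(spec$element_weights), n, replace = TRUE,
                  prob = spec$element_weights)
  if (want_charges) {
    # a charge pair needs an N (cation site) and an O (anion site); force
    # their presence, N not terminal-only constraint handled below
    if (!"N" %in% elems) elems[pick_one(seq_len(n))] <- "N"
    if (sum(elems == "O") == 0L && n >= 2L) {
      elems[pick_one(which(elems != "N"))] <- "O"
    }
  }
  charge <- integer(n)
  cap <- GEN_CAPACITY[elems]
  if (want_charges && any(elems == "N") && any(elems == "O")) {
    ni <- which(elems == "N")[1L]
    oi <- which(elems == "O")[1L]
    charge[ni] <- 1L; cap[ni] <- cap[ni] + 1L   # quaternizable N+
    charge[oi] <- -1L; cap[oi] <- cap[oi] - 1L  # oxyanion O-
  }
  used <- integer(n)  # bond-order sum so far
  a1 <- integer(); a2 <- integer(); ord <- integer()
  for (v in seq_len(n)[-1L]) {
    # attach v to a random earlier atom with spare capacity
    host_pool <- which(seq_len(n) < v & used < cap[seq_len(n)])
    host_pool <- host_pool[used[host_pool] < cap[host_pool]]
    if (length(host_pool) == 0L) return(NULL)  # dead end; caller retries
    host <- pick_one(host_pool)
    o <- 1L
    if (used[host] + 2L <= cap[host] && used[v] + 2L <= cap[v] &&
        stats::runif(1) < 0.15) {
      o <- 2L
    }
    a1 <- c(a1, host); a2 <- c(a2, v); ord <- c(ord, o)
    used[host] <- used[host] + o; used[v] <- used[v] + o
  }
  if (n >= 4L && stats::runif(1) < spec$ring_probability) {
    # close one ring between two non-adjacent atoms with spare capacity
    free <- which(used < cap)
    if (length(free) >= 2L) {
      pairs <- expand.grid(i = free, j = free)
      pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
      adjacent <- paste(a1, a2)
      pairs <- pairs[!paste(pairs$i, pairs$j) %in% adjacent, , drop = FALSE]
      if (nrow(pairs) > 0L) {
        pick <- pairs[sample(nrow(pairs), 1L), ]
        a1 <- c(a1, pick$i); a2 <- c(a2, pick$j); ord <- c(ord, 1L)
        used[pick$i] <- used[pick$i] + 1L; used[pick$j] <- used[pick$j] + 1L
      }
    }
  }
  atoms <- data.frame(element = elems, charge = charge,
                      aromatic = FALSE, implicit_h = 0L, in_ring = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = a1, a2 = a2, order = ord,
                      aromatic = logical(length(a1)),
                      in_ring = logical(length(a1)), stringsAsFactors = FALSE)
  mol <- new_molecule(id, atoms, bonds, "")
  bos <- bond_order_sums(mol)
  for (a in seq_len(n)) {
    mol$atoms$implicit_h[a] <- implicit_hydrogen_count(elems[a], bos[a], charge[a])
  }
  # a "charged" molecule must really carry the pair (O- with a bond; an O-
  # that ended up unbonded would be a free hydroxide)
  if (want_charges) {
    neg <- which(mol$atoms$charge < 0L)
    if (length(neg) == 0L || any(bos[neg] == 0L)) return(NULL)
  }
  mol <- perceive_rings(mol)
  mol$smiles <- write_smiles(mol)
  mol
}

#' Generate random synthetic molecules
#'
#' Seeded, reproducible generation of random connected molecular graphs
#' respecting the valence model. Every molecule is emitted with a SMILES
#' spelling and verified to round-trip through [parse_smiles()] to an
#' isomorphic graph.
#'
#' @param spec a [synthetic_spec()]
#' @return list of molecules of length `spec$n_molecules`
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$heavy_atom_range[2L] < 1L) stop("infeasible heavy_atom_range")
  set.seed(spec$seed)
  out <- vector("list", spec$n_molecules)
  i <- 0L
  attempts <- 0L
  while (i < spec$n_molecules) {
    attempts <- attempts + 1L
    if (attempts > 50L * spec$n_molecules + 100L) {
      stop("synthetic generation failed to satisfy the spec (infeasible?)")
    }
    g <- random_molecule_graph(spec, sprintf("syn%04d", i + 1L))
    if (is.null(g)) next
    parsed <- tryCatch(parse_smiles(g$smiles, g$id), error = function(e) NULL)
    if (is.null(parsed) || !molecules_isomorphic(g, parsed)) next
    i <- i + 1L
    out[[i]] <- parsed
  }
  out
}

#' Single-edit perturbation of a molecule
#'
#' `delete_terminal_atom` removes a degree-one heavy atom (the molecule must
#' keep at least one atom); `mutate_element` switches one atom's element to
#' another that accommodates the atom's bond-order sum. Both re-derive
#' implicit hydrogens and return a molecule that reparses from its SMILES.
#'
#' @param mol a molecule
#' @param op `"delete_terminal_atom"` or `"mutate_element"`
#' @param target atom index to edit; defaults to the first applicable atom
#' @param new_element replacement element for `mutate_element`
#' @return the perturbed molecule
#' @export
perturb <- function(mol, op = c("delete_terminal_atom", "mutate_element"),
                    target = NULL, new_element = NULL) {
  op <- match.arg(op)
  deg <- atom_degrees(mol)
  bos <- bond_order_sums(mol)
  if (op == "delete_terminal_atom") {
    if (n_atoms(mol) < 2L) stop("cannot delete from a single-atom molecule")
    cand <- which(deg == 1L & mol$atoms$charge == 0L)
    if (is.null(target)) target <- cand[1L]
    if (is.na(target) || !target %in% cand) {
      stop("no applicable terminal atom to delete")
    }
    keep <- setdiff(seq_len(n_atoms(mol)), target)
    remap <- match(seq_len(n_atoms(mol)), keep)
    atoms <- mol$atoms[keep, , drop = FALSE]
    bonds <- mol$bonds[mol$bonds$a1 != target & mol$bonds$a2 != target, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    rownames(atoms) <- rownames(bonds) <- NULL
    out <- new_molecule(paste0(mol$id, "_del"), atoms, bonds, "")
  } else {
    if (is.null(target)) target <- 1L
    el <- mol$atoms$element[target]
    if (mol$atoms$aromatic[target]) stop("mutate_element on aromatic atoms is not supported")
    if (is.null(new_element)) {
      pool <- setdiff(c("C", "N", "O"), el)
      fits <- pool[vapply(pool, function(e) {
        max(allowed_valences(e, 0L)) >= bos[target]
      }, logical(1L))]
      if (length(fits) == 0L) stop("no element fits this atom's bond-order sum")
      new_element <- fits[1L]
    }
    if (max(allowed_valences(new_element, mol$atoms$charge[target])) < bos[target]) {
      stop(sprintf("element %s cannot accommodate bond-order sum %d",
                   new_element, bos[target]))
    }
    out <- mol
    out$id <- paste0(mol$id, "_mut")
    out$atoms$element[target] <- new_element
    out$smiles <- ""
  }
  bos2 <- bond_order_sums(out)
  for (a in seq_len(n_atoms(out))) {
    out$atoms$implicit_h[a] <- implicit_hydrogen_count(
      out$atoms$element[a], bos2[a], out$atoms$charge[a]
    )
  }
  out <- perceive_rings(out)
  out$smiles <- write_smiles(out)
  parse_smiles(out$smiles, out$id)
}
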