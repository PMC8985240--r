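#' @useDynLib brushscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.dist cutree sd setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

SUPPORTED_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
ORGANIC_SUBSET <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
AROMATIC_ELEMENTS <- c("C", "N", "O", "S", "P")

#' Standard atomic weights (IUPAC 2021, conventional values)
#' @noRd
ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904
)

#' Construct a molecule object
#'
#' Internal constructor. A molecule is a labelled undirected graph of heavy
#' atoms: hydrogens are implicit only, stored as a per-atom count.
#'
#' @param id identifier string
#' @param atoms data.frame with columns element, charge, aromatic, implicit_h,
#'   in_ring
#' @param bonds data.frame with columns a1, a2, order (1/2/3), aromatic,
#'   in_ring
#' @param smiles the source SMILES string
#' @param rings list of integer vectors (atom indices of each perceived ring)
#' @noRd
new_molecule <- function(id, atoms, bonds, smiles, rings = list()) {
  structure(
    list(id = id, atoms = atoms, bonds = bonds, smiles = smiles, rings = rings),
    class = "molecule"
  )
}

#' Number of heavy atoms of a molecule
#' @param mol a molecule
#' @return integer count of non-hydrogen atoms
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Number of bonds of a molecule
#' @param mol a molecule
#' @return integer bond count (between heavy atoms)
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' Net formal charge of a molecule
#' @param mol a molecule
#' @return integer total formal charge (zero for balanced zwitterions)
#' @export
net_charge <- function(mol) sum(mol$atoms$charge)

#' Is the molecule a zwitterion?
#'
#' True when the molecule carries at least one positively and one negatively
#' charged atom (regardless of the net charge).
#' @param mol a molecule
#' @return logical
#' @export
is_zwitterion <- function(mol) {
  any(mol$atoms$charge > 0) && any(mol$atoms$charge < 0)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule> %s: %d heavy atoms, %d bonds, formula %s, net charge %+d\n",
    x$id, n_atoms(x), n_bonds(x), molecular_formula(x), net_charge(x)
  ))
  invisible(x)
}

#' Molecular formula (Hill order) including implicit hydrogens
#' @param mol a molecule
#' @return a string such as "C3H8O3"
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nH <- sum(mol$atoms$implicit_h)
  elems <- names(counts)
  ord <- c("C", "H", sort(setdiff(c(elems, if (nH > 0) "H"), c("C", "H"))))
  full <- setNames(rep(0L, length(ord)), ord)
  full[elems] <- as.integer(counts)
  if (nH > 0) full["H"] <- nH
  full <- full[full > 0]
  paste0(names(full), ifelse(full > 1, full, ""), collapse = "")
}

#' Adjacency list of a molecule
#' @param mol a molecule
#' @return list of integer vectors, neighbours of each atom
#' @export
adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Sum of bond orders incident to each atom
#'
#' Aromatic bonds contribute their kekulized order (1 or 2).
#' @param mol a molecule
#' @return integer vector over atoms
#' @export
bond_order_sums <- function(mol) {
  s <- integer(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + mol$bonds$order[k]
    s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + mol$bonds$order[k]
  }
  s
}

#' Heavy-atom degree of each atom
#' @param mol a molecule
#' @return integer vector over atoms
#' @export
atom_degrees <- function(mol) {
  lengths(adjacency_list(mol))
}

#' Serialize a molecule to JSON (debugging dump)
#'
#' @param mol a molecule
#' @param path optional file path; when `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to a file)
#' @export
molecule_to_json <- function(mol, path = NULL) {
  obj <- list(
    id = mol$id, smiles = mol$smiles, formula = molecular_formula(mol),
    atoms = mol$atoms, bonds = mol$bonds
  )
  txt <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Test whether two molecules are isomorphic as labelled graphs
#'
#' Atoms match on (element, formal charge, aromatic flag, implicit hydrogen
#' count); bonds on order. Used by round-trip invariance checks.
#' @param a,b molecules
#' @return logical
#' @export
molecules_isomorphic <- function(a, b) {
  if (n_atoms(a) != n_atoms(b) || n_bonds(a) != n_bonds(b)) return(FALSE)
  keyA <- paste(a$atoms$element, a$atoms$charge, a$atoms$aromatic, a$atoms$implicit_h)
  keyB <- paste(b$atoms$element, b$atoms$charge, b$atoms$aromatic, b$atoms$implicit_h)
  if (!identical(sort(keyA), sort(keyB))) return(FALSE)
  # exact check by backtracking on the labelled graph
  adjA <- adjacency_matrix_orders(a)
  adjB <- adjacency_matrix_orders(b)
  n <- n_atoms(a)
  cand <- lapply(seq_len(n), function(i) which(keyB == keyA[i]))
  mapping <- integer(n)
  used <- logical(n)
  match_rec <- function(i) {
    if (i > n) return(TRUE)
    for (j in cand[[i]]) {
      if (used[j]) next
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (adjA[i, k] != adjB[j, mapping[k]]) { ok <- FALSE; break }
      }
      if (ok) {
        mapping[i] <<- j; used[j] <<- TRUE
        if (match_rec(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  match_rec(1L)
}

# dense adjacency matrix of bond orders (0 = no bond)
adjacency_matrix_orders <- function(mol) {
  n <- n_atoms(mol)
  m <- matrix(0L, n, n)
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    o <- if (mol$bonds$aromatic[k]) 9L else mol$bonds$order[k]
    m[i, j] <- o; m[j, i] <- o
  }
  m
}
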