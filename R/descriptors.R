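#' Molecular weight
#'
#' Sum of standard atomic weights (IUPAC 2021 conventional values) over heavy
#' atoms plus implicit hydrogens, in g/mol.
#'
#' @param mol a molecule
#' @return numeric molecular weight
#' @examples
#' molecular_weight(parse_smiles("OCC(O)CO", "glycerol"))  # 92.09
#' @export
molecular_weight <- function(mol) {
  sum(ATOMIC_WEIGHTS[mol$atoms$element]) +
    sum(mol$atoms$implicit_h) * ATOMIC_WEIGHTS[["H"]]
}

#' Fraction of sp3-hybridized carbon atoms
#'
#' Carbons that are non-aromatic and carry only single bonds, divided by the
#' total carbon count.
#'
#' @param mol a molecule with at least one carbon
#' @return numeric in \[0, 1\]
#' @export
fraction_csp3 <- function(mol) {
  is_c <- mol$atoms$element == "C"
  if (!any(is_c)) stop(sprintf("fraction_csp3 undefined: '%s' has no carbon", mol$id))
  has_multiple <- logical(n_atoms(mol))
  for (k in seq_len(n_bonds(mol))) {
    if (mol$bonds$order[k] >= 2L || mol$bonds$aromatic[k]) {
      has_multiple[mol$bonds$a1[k]] <- TRUE
      has_multiple[mol$bonds$a2[k]] <- TRUE
    }
  }
  sp3 <- is_c & !mol$atoms$aromatic & !has_multiple
  sum(sp3) / sum(is_c)
}

# is atom `a` an amide-type nitrogen (singly bonded to a carbonyl carbon)?
is_amide_n <- function(mol, a, adj = adjacency_list(mol)) {
  if (mol$atoms$element[a] != "N") return(FALSE)
  om <- adjacency_matrix_orders(mol)
  for (nb in adj[[a]]) {
    if (mol$atoms$element[nb] == "C" && om[a, nb] == 1L) {
      for (nb2 in adj[[nb]]) {
        if (mol$atoms$element[nb2] == "O" && om[nb, nb2] == 2L) return(TRUE)
      }
    }
  }
  FALSE
}

# pyrrole-type aromatic nitrogen donates its lone pair to the ring
is_pyrrole_type_n <- function(mol, a, adj = adjacency_list(mol)) {
  mol$atoms$element[a] == "N" && mol$atoms$aromatic[a] &&
    (mol$atoms$implicit_h[a] > 0L || length(adj[[a]]) >= 3L) &&
    mol$atoms$charge[a] == 0L
}

#' Count hydrogen-bond acceptors
#'
#' N and O atoms, excluding amide and pyrrole-type nitrogens and positively
#' charged nitrogens. This is the pinned package definition (an approximation
#' of the SwissADME acceptor rules).
#'
#' @param mol a molecule
#' @return integer count
#' @export
count_hba <- function(mol) {
  adj <- adjacency_list(mol)
  n <- 0L
  for (a in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[a]
    if (el == "O") n <- n + 1L
    else if (el == "N") {
      if (mol$atoms$charge[a] > 0L) next
      if (is_amide_n(mol, a, adj)) next
      if (is_pyrrole_type_n(mol, a, adj)) next
      n <- n + 1L
    }
  }
  n
}

#' Count hydrogen-bond donors
#'
#' N or O atoms bearing at least one (implicit) hydrogen; each donor atom
#' counts once regardless of its hydrogen count.
#'
#' @param mol a molecule
#' @return integer count
#' @export
count_hbd <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O") & mol$atoms$implicit_h > 0L)
}

#' Count rotatable bonds
#'
#' Acyclic single bonds between two non-terminal heavy atoms, excluding amide
#' C-N bonds.
#'
#' @param mol a molecule
#' @return integer count
#' @export
rotatable_bonds <- function(mol) {
  deg <- atom_degrees(mol)
  adj <- adjacency_list(mol)
  om <- adjacency_matrix_orders(mol)
  n <- 0L
  for (k in seq_len(n_bonds(mol))) {
    b <- mol$bonds[k, ]
    if (b$in_ring || b$aromatic || b$order != 1L) next
    if (deg[b$a1] < 2L || deg[b$a2] < 2L) next
    # amide C-N exclusion (either orientation)
    amide <- FALSE
    for (pr in list(c(b$a1, b$a2), c(b$a2, b$a1))) {
      cc <- pr[1L]; nn <- pr[2L]
      if (mol$atoms$element[cc] == "C" && mol$atoms$element[nn] == "N") {
        for (nb in adj[[cc]]) {
          if (mol$atoms$element[nb] == "O" && om[cc, nb] == 2L) amide <- TRUE
        }
      }
    }
    if (!amide) n <- n + 1L
  }
  n
}

#' ESOL aqueous solubility estimate (log S)
#'
#' Delaney's ESOL linear model on Wildman-Crippen logP, molecular weight,
#' rotatable-bond count and aromatic proportion (aromatic heavy atoms /
#' heavy atoms). Coefficients are packaged in the versioned constants file.
#'
#' @param wlogp Wildman-Crippen logP
#' @param mw molecular weight (g/mol)
#' @param rotatable rotatable-bond count
#' @param aromatic_proportion fraction of heavy atoms that are aromatic
#' @return numeric log of the molar aqueous solubility
#' @export
esol_logs <- function(wlogp, mw, rotatable, aromatic_proportion) {
  co <- bs_constants()$esol
  co$intercept + co$c_logp * wlogp + co$c_mw * mw +
    co$c_rb * rotatable + co$c_ap * aromatic_proportion
}

#' Full descriptor vector of one molecule
#'
#' @param mol a molecule
#' @return a one-row data.frame with columns identifier, molecular_weight,
#'   heavy_atoms, fraction_csp3, hba, hbd, rotatable_bonds, tpsa,
#'   wlogp, molar_refractivity, esol_logs
#' @export
descriptor_vector <- function(mol) {
  wc <- wildman_crippen(mol)
  rb <- rotatable_bonds(mol)
  mw <- molecular_weight(mol)
  ap <- mean(mol$atoms$aromatic)
  data.frame(
    identifier = mol$id,
    molecular_weight = mw,
    heavy_atoms = n_atoms(mol),
    fraction_csp3 = fraction_csp3(mol),
    hba = count_hba(mol),
    hbd = count_hbd(mol),
    rotatable_bonds = rb,
    tpsa = tpsa(mol),
    wlogp = wc$logp,
    molar_refractivity = wc$mr,
    esol_logs = esol_logs(wc$logp, mw, rb, ap),
    stringsAsFactors = FALSE
  )
}

#' Descriptor table for a molecule panel
#'
#' One row per molecule in input order; failures are reported with the
#' offending identifiers.
#'
#' @param panel list of molecules
#' @param path optional CSV output path
#' @return data.frame of descriptors (invisibly returns the same when `path`
#'   is given)
#' @export
descriptor_table <- function(panel, path = NULL) {
  rows <- vector("list", length(panel))
  errs <- character()
  for (i in seq_along(panel)) {
    r <- tryCatch(descriptor_vector(panel[[i]]), error = function(e) e)
    if (inherits(r, "error")) {
      errs <- c(errs, sprintf("%s: %s", panel[[i]]$id, conditionMessage(r)))
    } else rows[[i]] <- r
  }
  if (length(errs) > 0L) {
    stop(sprintf("descriptor computation failed for: %s", paste(errs, collapse = "; ")))
  }
  tab <- if (length(rows) == 0L) {
    empty <- descriptor_vector(parse_smiles("C", "template"))[0, ]
    empty
  } else do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
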