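HETERO_SET <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

# Per-atom context used by the typing rules
atom_context <- function(mol) {
  n <- n_atoms(mol)
  ctx <- vector("list", n)
  adj <- rep(list(integer(0)), n)
  ords <- rep(list(integer(0)), n)
  aroms <- rep(list(logical(0)), n)
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    o <- mol$bonds$order[k]; ab <- mol$bonds$aromatic[k]
    adj[[i]] <- c(adj[[i]], j); ords[[i]] <- c(ords[[i]], o); aroms[[i]] <- c(aroms[[i]], ab)
    adj[[j]] <- c(adj[[j]], i); ords[[j]] <- c(ords[[j]], o); aroms[[j]] <- c(aroms[[j]], ab)
  }
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    ctx[[a]] <- list(
      el = mol$atoms$element[a],
      arom = mol$atoms$aromatic[a],
      chg = mol$atoms$charge[a],
      nH = mol$atoms$implicit_h[a],
      nb = nb,
      nb_el = mol$atoms$element[nb],
      nb_arom = mol$atoms$aromatic[nb],
      ord = ords[[a]],
      bond_arom = aroms[[a]]
    )
  }
  ctx
}

# Wildman-Crippen atom type of each heavy atom, following the published
# pattern table in order (first match wins).
crippen_atom_types <- function(mol) {
  ctx <- atom_context(mol)
  vapply(seq_len(n_atoms(mol)), function(a) {
    x <- ctx[[a]]
    switch(x$el,
      C = type_carbon(x, ctx),
      N = type_nitrogen(x),
      O = type_oxygen(x, ctx),
      S = if (x$arom) "S3" else if (x$chg != 0L ||
            any(x$ord == 2L & !x$bond_arom & x$nb_el %in% c("N", "O", "P", "S"))) "S2" else "S1",
      P = "P",
      F = if (x$chg == 0L) "F" else "Hal",
      Cl = if (x$chg == 0L) "Cl" else "Hal",
      Br = if (x$chg == 0L) "Br" else "Hal",
      I = if (x$chg == 0L) "I" else "Hal",
      stop(sprintf("atom %d of '%s': no Wildman-Crippen type for element %s",
                   a, mol$id, x$el))
    )
  }, character(1L))
}

type_carbon <- function(x, ctx) {
  deg <- length(x$nb)
  aliph <- !x$nb_arom & !x$bond_arom
  single <- x$ord == 1L & !x$bond_arom
  if (x$arom) {
    # aromatic carbon
    exo_single <- which(!x$bond_arom & x$ord == 1L)
    exo_double <- which(!x$bond_arom & x$ord == 2L)
    n_arom_bonds <- sum(x$bond_arom)
    if (length(exo_single) > 0L && any(x$nb_el[exo_single] == "F")) return("C14")
    if (length(exo_single) > 0L && any(x$nb_el[exo_single] == "Cl")) return("C15")
    if (length(exo_single) > 0L && any(x$nb_el[exo_single] == "Br")) return("C16")
    if (length(exo_single) > 0L && any(x$nb_el[exo_single] == "I")) return("C17")
    if (x$nH > 0L) return("C18")
    if (n_arom_bonds >= 3L) return("C19")
    if (length(exo_single) > 0L) {
      w <- exo_single[1L]
      if (x$nb_arom[w]) return("C20")
      if (x$nb_el[w] == "C") return("C21")
      if (x$nb_el[w] == "N") return("C22")
      if (x$nb_el[w] == "O") return("C23")
      if (x$nb_el[w] == "S") return("C24")
      return("C13")
    }
    if (length(exo_double) > 0L && x$nb_el[exo_double[1L]] %in% c("C", "N", "O")) return("C25")
    return("CS")
  }
  dbl <- which(x$ord == 2L & !x$bond_arom)
  trp <- which(x$ord == 3L)
  if (length(dbl) == 0L && length(trp) == 0L) {
    # sp3 carbon
    all_c_aliph <- deg > 0L && all(x$nb_el == "C" & aliph)
    any_het_aliph <- any(x$nb_el %in% HETERO_SET & aliph)
    all_aliph <- all(aliph)
    if (deg == 0L) return("C1")
    if (x$nH == 3L && deg == 1L && all_c_aliph) return("C1")
    if (x$nH == 2L && deg == 2L && all_c_aliph) return("C1")
    if (x$nH == 1L && deg == 3L && all_c_aliph) return("C2")
    if (x$nH == 0L && deg == 4L && all_c_aliph) return("C2")
    if (x$nH == 3L && deg == 1L && x$nb_el[1L] %in% HETERO_SET && aliph[1L]) return("C3")
    if (x$nH == 2L && deg == 2L && any_het_aliph && all_aliph) return("C3")
    if (x$nH == 1L && deg == 3L && any_het_aliph && all_aliph) return("C4")
    if (x$nH == 0L && deg == 4L && any_het_aliph && all_aliph) return("C4")
    if (x$nH == 3L && deg == 1L && x$nb_arom[1L] && x$nb_el[1L] == "C") return("C8")
    if (x$nH == 3L && deg == 1L && x$nb_arom[1L]) return("C9")
    if (x$nH == 2L && any(x$nb_arom)) return("C10")
    if (x$nH == 1L && any(x$nb_arom)) return("C11")
    if (x$nH == 0L && any(x$nb_arom)) return("C12")
    return("CS")
  }
  # sp2 / sp carbon
  if (length(trp) > 0L && deg + x$nH <= 2L) return("C7")
  if (length(dbl) > 0L && any(x$nb_el[dbl] != "C" & !x$nb_arom[dbl])) return("C5")
  dbl_c_aliph <- any(x$nb_el[dbl] == "C" & !x$nb_arom[dbl])
  dbl_c_arom <- any(x$nb_el[dbl] == "C" & x$nb_arom[dbl])
  if (dbl_c_arom) return("C26")          # [C]=c
  if (dbl_c_aliph) {
    others <- setdiff(seq_len(deg), dbl)
    if (x$nH == 2L && deg == 1L) return("C6")               # [CH2]=C
    if (length(dbl) == 2L) return("C6")                     # [C](=C)=C
    if (x$nH == 1L && length(others) == 1L) {
      if (!x$nb_arom[others]) return("C6")                  # [CH1](=C)[A]
      return("C26")                                         # [CH1](=C)a
    }
    if (x$nH == 0L && length(others) == 2L) {
      if (all(!x$nb_arom[others])) return("C6")             # [C](=C)(A)A
      return("C26")                                         # [C](=C)(a)[A]
    }
  }
  "CS"
}

type_nitrogen <- function(x) {
  deg <- length(x$nb)
  if (x$arom) {
    if (x$chg > 0L) return("N12")
    if (x$chg == 0L) return("N11")
    return("N14")
  }
  if (x$chg > 0L) {
    if (x$nH >= 1L) return("N10")
    dbl <- which(x$ord == 2L & !x$bond_arom)
    trp <- which(x$ord == 3L)
    if (length(trp) > 0L) return("N14")
    if (deg == 4L && all(x$ord == 1L) && all(!x$nb_arom)) return("N13")
    if (length(dbl) == 1L && all(!x$nb_arom)) return("N13")
    return("NS")
  }
  if (x$chg < 0L) return("N14")
  dbl <- which(x$ord == 2L & !x$bond_arom)
  trp <- which(x$ord == 3L)
  aliph <- !x$nb_arom
  if (x$nH == 2L && deg == 1L) return(if (aliph[1L]) "N1" else "N3")
  if (x$nH == 1L && deg == 2L && length(dbl) == 0L && length(trp) == 0L) {
    return(if (all(aliph)) "N2" else "N4")
  }
  if (x$nH == 1L && length(dbl) == 1L) return("N5")
  if (x$nH == 0L && length(dbl) == 1L && deg == 2L) return("N6")
  if (x$nH == 0L && deg == 3L && length(dbl) == 0L && length(trp) == 0L) {
    return(if (all(aliph)) "N7" else "N8")
  }
  if (length(trp) > 0L) return("N9")
  "NS"
}

type_oxygen <- function(x, ctx) {
  deg <- length(x$nb)
  if (x$arom) return("O1")
  if (x$chg == 0L) {
    if (x$nH >= 1L) return("O2")
    dbl <- which(x$ord == 2L & !x$bond_arom)
    if (deg == 2L && length(dbl) == 0L) {
      return(if (all(!x$nb_arom)) "O3" else "O4")
    }
    if (length(dbl) == 1L) {
      w <- x$nb[dbl]
      wel <- x$nb_el[dbl]; warom <- x$nb_arom[dbl]
      if (wel %in% c("N", "O")) return("O5")
      if (wel == "S") return("O6")
      if (wel == "C") {
        if (warom) return("O8")                         # [O]=c
        k <- ctx[[w]]
        # neighbours of the carbonyl carbon other than double-bonded oxygens
        keep <- !(k$ord == 2L & k$nb_el == "O" & !k$bond_arom)
        oel <- k$nb_el[keep]; oar <- k$nb_arom[keep]
        if (k$nH >= 1L) {
          if (any(oel == "C" & !oar)) return("O9")      # [O]=[CH]C
          if (any(oel == "C" & oar)) return("O10")      # [O]=[CH]c
          if (any(oel %in% c("N", "O"))) return("O9")   # [O]=[CH][N,O]
          if (length(oel) == 0L) return("O9")           # [O]=[CH2]
          return("OS")
        }
        if (any(k$ord == 2L & k$nb_el == "O") &&
            sum(k$ord == 2L & k$nb_el == "O") >= 2L) return("O9")  # O=C=O
        if (any(oel == "C" & !oar) && all(!oar)) return("O9")      # [O]=C(C)(A)
        if (any(oel == "C") && any(oar)) return("O10")  # [O]=C([C,c])[a]
        if (any(oel == "C" & oar)) return("O10")        # [O]=C(c)[A]
        if (length(oel) >= 2L && all(oel != "C")) return("O11")
        return("OS")
      }
      return("OS")                                      # e.g. O=P
    }
    return("OS")
  }
  if (x$chg < 0L && deg == 1L) {
    wel <- x$nb_el[1L]
    if (wel == "N") return("O5")
    if (wel == "S") return("O6")
    if (wel == "C") {
      k <- ctx[[x$nb[1L]]]
      if (any(k$ord == 2L & k$nb_el == "O" & !k$bond_arom)) return("O12")  # carboxylate
      return("O7")
    }
    return("O7")
  }
  "OS"
}

# Crippen type of the hydrogens attached to heavy atom `a`
hydrogen_type <- function(x, ctx) {
  el <- x$el
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el %in% c("S", "P")) return("H2")   # [#1][!C;!N;!O]
  if (el == "O") {
    if (length(x$nb) == 0L) return("H2")  # water: the sibling hydrogen
                                          # matches [#1]O[!C;!N;!O;!S]
    w <- x$nb[1L]; wel <- x$nb_el[1L]; warom <- x$nb_arom[1L]
    k <- ctx[[w]]
    if (wel == "C") {
      sp3 <- !warom && all(k$ord == 1L & !k$bond_arom)
      if (sp3 || warom) return("H2")      # [#1]O[CX4,c]
      if (any(k$ord == 2L & k$nb_el %in% c("C", "N", "O", "S"))) return("H4")  # acid/enol
      return("HS")
    }
    if (wel == "N") return("H3")          # [#1]O[#7]
    if (wel %in% c("O", "S")) return("H4")
    return("H2")                          # [#1]O[!C;!N;!O;!S], e.g. O-P
  }
  "HS"
}

#' Wildman-Crippen logP and molar refractivity
#'
#' Atom-additive estimates of the octanol/water partition coefficient (WLOGP,
#' the lipophilicity scale used throughout the package) and molar
#' refractivity, using the published atom-type contributions shipped in the
#' packaged table. Implicit hydrogens contribute through their own types.
#'
#' @param mol a molecule
#' @return list with elements `logp`, `mr`, and `types` (heavy-atom types)
#' @export
wildman_crippen <- function(mol) {
  tab <- crippen_table()
  lut_logp <- setNames(tab$logp, tab$type)
  lut_mr <- setNames(tab$mr, tab$type)
  types <- crippen_atom_types(mol)
  ctx <- atom_context(mol)
  htypes <- vapply(seq_len(n_atoms(mol)), function(a) hydrogen_type(ctx[[a]], ctx),
                   character(1L))
  bad <- setdiff(unique(c(types, htypes)), tab$type)
  if (length(bad) > 0L) {
    stop(sprintf("untyped Wildman-Crippen environment(s): %s", paste(bad, collapse = ", ")))
  }
  nH <- mol$atoms$implicit_h
  logp <- sum(lut_logp[types]) + sum(lut_logp[htypes] * nH)
  mr <- sum(lut_mr[types]) + sum(lut_mr[htypes] * nH)
  list(logp = unname(logp), mr = unname(mr), types = types)
}

#' Wildman-Crippen logP of a molecule
#' @param mol a molecule
#' @return numeric logP estimate
#' @export
wlogp <- function(mol) wildman_crippen(mol)$logp

#' Wildman-Crippen molar refractivity of a molecule
#' @param mol a molecule
#' @return numeric molar refractivity
#' @export
molar_refractivity <- function(mol) wildman_crippen(mol)$mr
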