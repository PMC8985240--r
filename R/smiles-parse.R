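#' Allowed valences for an element given its formal charge
#'
#' The valence model used throughout the package. Base valences are C 4, N 3,
#' O 2, S 2/4/6, P 3/5, halogens 1. Cations of N/O/S/P gain one bonding slot
#' per positive charge (quaternary N+ is tetravalent); anions of O/S/N lose
#' one per negative charge (alkoxide/oxyanion O- is monovalent, as in
#' sulfonates and phosphates); charged carbon loses one slot either way.
#'
#' @param element chemical symbol
#' @param charge integer formal charge
#' @return increasing integer vector of allowed valences
#' @export
allowed_valences <- function(element, charge = 0L) {
  base <- switch(element,
    C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
    F = 1L, Cl = 1L, Br = 1L, I = 1L,
    stop(sprintf("unknown element '%s'", element))
  )
  if (charge == 0L) return(base)
  adj <- if (element %in% c("N", "P", "O", "S")) {
    if (charge > 0L) base + charge else base - abs(charge)
  } else {
    base - abs(charge)
  }
  adj <- adj[adj >= 0L]
  if (length(adj) == 0L) {
    stop(sprintf("element %s with charge %+d has no allowed valence", element, charge))
  }
  adj
}

#' Implicit hydrogen count under the standard-valence fill
#'
#' Picks the smallest allowed valence that accommodates the explicit
#' bond-order sum and fills the remainder with hydrogens.
#'
#' @param element chemical symbol (one of C, N, O, S, P, F, Cl, Br, I)
#' @param bond_order_sum sum of explicit bond orders at the atom
#' @param charge formal charge
#' @return non-negative integer hydrogen count
#' @export
implicit_hydrogen_count <- function(element, bond_order_sum, charge = 0L) {
  av <- allowed_valences(element, charge)
  fit <- av[av >= bond_order_sum]
  if (length(fit) == 0L) {
    stop(sprintf(
      "valence overflow: %s%s with bond-order sum %d exceeds allowed valence {%s}",
      element, if (charge != 0) sprintf("%+d", charge) else "",
      bond_order_sum, paste(av, collapse = ",")
    ))
  }
  fit[1L] - bond_order_sum
}

parse_error <- function(pos, msg) {
  stop(sprintf("SMILES parse error at position %d: %s", pos, msg), call. = FALSE)
}

# Parse the contents of a bracket atom "[...]" (without the brackets).
# Returns list(element, aromatic, h, charge). `pos` is the position of '['.
parse_bracket <- function(content, pos) {
  m <- regmatches(
    content,
    regexec("^([A-Za-z][a-z]?)(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?$", content)
  )[[1]]
  if (length(m) == 0L) {
    if (grepl("^[0-9]", content)) parse_error(pos, "isotopes are not supported")
    if (grepl("@", content)) parse_error(pos, "stereochemistry is not supported")
    parse_error(pos, sprintf("cannot parse bracket atom '[%s]'", content))
  }
  sym <- m[2]
  aromatic <- sym == tolower(sym) && nchar(sym) == 1L
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% SUPPORTED_ELEMENTS) {
    parse_error(pos, sprintf("unknown element '%s'", sym))
  }
  if (aromatic && !element %in% AROMATIC_ELEMENTS) {
    parse_error(pos, sprintf("element '%s' cannot be aromatic", sym))
  }
  h <- 0L
  if (m[3] != "") {
    h <- if (m[3] == "H") 1L else as.integer(substring(m[3], 2L))
  }
  charge <- 0L
  if (m[4] != "") {
    sgn <- if (substring(m[4], 1L, 1L) == "+") 1L else -1L
    rest <- substring(m[4], 2L)
    charge <- if (rest == "") sgn else if (grepl("^[0-9]$", rest)) sgn * as.integer(rest) else sgn * (nchar(rest) + 1L)
  }
  list(element = element, aromatic = aromatic, h = h, charge = charge)
}

#' Parse a SMILES string into a molecule
#'
#' Supports the organic subset (C, N, O, S, P, F, Cl, Br, I and their aromatic
#' lowercase forms), bracket atoms with explicit hydrogens and formal charges,
#' branches, ring-closure digits (including `%nn`), and single/double/triple/
#' aromatic bonds. Stereochemistry, isotopes and multi-fragment (dotted)
#' SMILES are rejected. Aromatic rings are kekulized internally so every bond
#' carries an integer order; implicit hydrogens are assigned from the valence
#' model (see [allowed_valences()]).
#'
#' @param smiles SMILES string
#' @param identifier molecule identifier carried through all outputs
#' @return a `molecule` object
#' @examples
#' parse_smiles("C=CC(N)=O", "acrylamide")
#' @export
parse_smiles <- function(smiles, identifier = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || nchar(smiles) == 0L) {
    stop("smiles must be a non-empty string")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element <- character(); charge <- integer(); aromatic <- logical()
  expl_h <- integer(); has_expl_h <- logical()
  b_a1 <- integer(); b_a2 <- integer(); b_sym <- character(); b_pos <- integer()

  prev <- 0L              # index of previous atom (0 = none)
  pending <- ""           # pending bond symbol
  pending_pos <- 0L
  stack <- integer()      # branch stack
  stack_pos <- integer()  # positions of the unclosed '(' characters
  ringmap <- list()       # closure digit -> c(atom, pos), bond sym kept separately
  ringsym <- list()

  add_atom <- function(el, arom, chg, h, hset) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    expl_h[length(expl_h) + 1L] <<- h
    has_expl_h[length(has_expl_h) + 1L] <<- hset
    idx <- length(element)
    if (prev > 0L) {
      b_a1[length(b_a1) + 1L] <<- prev
      b_a2[length(b_a2) + 1L] <<- idx
      b_sym[length(b_sym) + 1L] <<- pending
      b_pos[length(b_pos) + 1L] <<- pending_pos
    }
    prev <<- idx
    pending <<- ""
  }

  close_ring <- function(digit, pos) {
    if (prev == 0L) parse_error(pos, "ring closure before any atom")
    key <- as.character(digit)
    if (is.null(ringmap[[key]])) {
      ringmap[[key]] <<- c(prev, pos)
      ringsym[[key]] <<- pending
    } else {
      other <- ringmap[[key]][1L]
      sym1 <- ringsym[[key]]; sym2 <- pending
      if (other == prev) parse_error(pos, "ring closure to the same atom")
      sym <- if (sym2 != "") sym2 else sym1
      if (sym1 != "" && sym2 != "" && sym1 != sym2) {
        parse_error(pos, "conflicting bond orders on ring closure")
      }
      b_a1[length(b_a1) + 1L] <<- other
      b_a2[length(b_a2) + 1L] <<- prev
      b_sym[length(b_sym) + 1L] <<- sym
      b_pos[length(b_pos) + 1L] <<- pos
      ringmap[[key]] <<- NULL
      ringsym[[key]] <<- NULL
    }
    pending <<- ""
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; pending_pos <- i; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) parse_error(i, "branch before any atom")
      stack <- c(stack, prev); stack_pos <- c(stack_pos, i); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error(i, "unbalanced parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      stack_pos <- stack_pos[-length(stack_pos)]; i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) parse_error(i, "unclosed bracket atom")
      info <- parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""), i)
      add_atom(info$element, info$aromatic, info$charge, info$h, TRUE)
      i <- j + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste(chars[i + 1:2], collapse = ""))) {
        parse_error(i, "'%' must be followed by two digits")
      }
      close_ring(as.integer(paste(chars[i + 1:2], collapse = "")), i)
      i <- i + 3L
    } else if (ch == ".") {
      parse_error(i, "disconnected (dotted) SMILES are not supported")
    } else if (ch %in% c("/", "\\", "@")) {
      parse_error(i, "stereochemistry is not supported")
    } else if (grepl("[A-Z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, 0L, FALSE); i <- i + 2L
      } else if (ch %in% SUPPORTED_ELEMENTS) {
        add_atom(ch, FALSE, 0L, 0L, FALSE); i <- i + 1L
      } else {
        parse_error(i, sprintf("unknown element '%s'", ch))
      }
    } else if (grepl("[a-z]", ch)) {
      up <- toupper(ch)
      if (!up %in% AROMATIC_ELEMENTS) parse_error(i, sprintf("unknown aromatic atom '%s'", ch))
      add_atom(up, TRUE, 0L, 0L, FALSE)
      i <- i + 1L
    } else {
      parse_error(i, sprintf("unexpected character '%s'", ch))
    }
  }

  if (length(stack) > 0L) {
    parse_error(stack_pos[length(stack_pos)], "unbalanced parenthesis (unclosed branch)")
  }
  if (length(ringmap) > 0L) {
    first <- ringmap[[1L]]
    parse_error(first[2L], sprintf("unmatched ring-closure digit %s", names(ringmap)[1L]))
  }
  if (length(element) == 0L) parse_error(1L, "no atoms")
  if (pending != "") parse_error(pending_pos, "dangling bond symbol")

  atoms <- data.frame(
    element = element, charge = charge, aromatic = aromatic,
    implicit_h = 0L, in_ring = FALSE, stringsAsFactors = FALSE
  )
  # duplicate bonds between the same pair are invalid
  if (length(b_a1) > 0L) {
    key <- paste(pmin(b_a1, b_a2), pmax(b_a1, b_a2))
    if (anyDuplicated(key)) {
      parse_error(b_pos[which(duplicated(key))[1L]], "duplicate bond between the same atom pair")
    }
  }
  # resolve bond orders: explicit symbol wins; default aromatic between two
  # aromatic atoms, otherwise single
  ord <- integer(length(b_a1)); arom_b <- logical(length(b_a1))
  for (k in seq_along(b_a1)) {
    sym <- b_sym[k]
    if (sym == "") {
      if (atoms$aromatic[b_a1[k]] && atoms$aromatic[b_a2[k]]) {
        arom_b[k] <- TRUE; ord[k] <- 1L
      } else ord[k] <- 1L
    } else if (sym == "-") ord[k] <- 1L
    else if (sym == "=") ord[k] <- 2L
    else if (sym == "#") ord[k] <- 3L
    else if (sym == ":") { arom_b[k] <- TRUE; ord[k] <- 1L }
  }
  bonds <- data.frame(
    a1 = b_a1, a2 = b_a2, order = ord, aromatic = arom_b,
    in_ring = logical(length(b_a1)), stringsAsFactors = FALSE
  )

  mol <- new_molecule(identifier, atoms, bonds, smiles)

  # connectivity (single covalent species)
  if (n_atoms(mol) > 1L) {
    comp <- connected_component(mol, 1L)
    if (length(comp) != n_atoms(mol)) {
      stop(sprintf("molecule '%s' is not connected", identifier))
    }
  }

  mol <- perceive_rings(mol)
  bad <- which(mol$atoms$aromatic & !mol$atoms$in_ring)
  if (length(bad) > 0L) {
    stop(sprintf("aromatic atom %d of '%s' is not in any ring", bad[1L], identifier))
  }
  # bracket-atom hydrogens are explicit and must be visible to kekulization
  # (pyrrole-type [nH] contributes its lone pair, not a double bond)
  mol$atoms$implicit_h[has_expl_h] <- expl_h[has_expl_h]
  mol <- kekulize(mol)

  # implicit hydrogens from the valence model
  bos <- bond_order_sums(mol)
  for (a in seq_len(n_atoms(mol))) {
    if (has_expl_h[a]) {
      av <- allowed_valences(atoms$element[a], atoms$charge[a])
      if (bos[a] + expl_h[a] > max(av)) {
        stop(sprintf(
          "valence overflow at atom %d of '%s': %s%+d with %d bonds and %d explicit H",
          a, identifier, atoms$element[a], atoms$charge[a], bos[a], expl_h[a]
        ))
      }
      mol$atoms$implicit_h[a] <- expl_h[a]
    } else if (mol$atoms$aromatic[a]) {
      # lowercase organic-subset atom: fill valence after kekulization
      mol$atoms$implicit_h[a] <- implicit_hydrogen_count(
        atoms$element[a], bos[a], atoms$charge[a]
      )
    } else {
      mol$atoms$implicit_h[a] <- implicit_hydrogen_count(
        atoms$element[a], bos[a], atoms$charge[a]
      )
    }
  }
  mol
}

# atoms reachable from `start`
connected_component <- function(mol, start) {
  adj <- adjacency_list(mol)
  seen <- logical(n_atoms(mol))
  queue <- start; seen[start] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}
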