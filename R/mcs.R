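#' Match semantics for the maximum-common-substructure search
#'
#' Pins the three conventions the MCS Tanimoto coefficient depends on:
#' the feature unit used for c/(a+b+c) (heavy atoms, or heavy atoms plus
#' bonds), whether atoms must agree on formal charge in addition to element,
#' and whether bonds must agree on order (single/double/triple/aromatic) or
#' merely exist.
#'
#' @param unit `"atoms"` or `"atoms_bonds"`
#' @param charge_sensitive must mapped atoms carry identical formal charges?
#' @param bond_match `"any"` or `"exact"`
#' @return a `match_semantics` object
#' @export
match_semantics <- function(unit = c("atoms", "atoms_bonds"),
                            charge_sensitive = FALSE,
                            bond_match = c("any", "exact")) {
  unit <- match.arg(unit)
  bond_match <- match.arg(bond_match)
  structure(
    list(unit = unit, charge_sensitive = isTRUE(charge_sensitive),
         bond_match = bond_match),
    class = "match_semantics"
  )
}

#' @export
print.match_semantics <- function(x, ...) {
  cat(sprintf("<match_semantics> unit=%s, charge=%s, bond=%s\n",
              x$unit, if (x$charge_sensitive) "sensitive" else "blind",
              x$bond_match))
  invisible(x)
}

mol_to_cpp <- function(mol) {
  ords <- ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
  list(
    elem = match(mol$atoms$element, SUPPORTED_ELEMENTS),
    chg = mol$atoms$charge,
    bonds = cbind(mol$bonds$a1, mol$bonds$a2, ords)
  )
}

#' Maximum common connected substructure of two molecules
#'
#' Exact backtracking search for the largest connected substructure common to
#' both molecules under the given match semantics, with a deterministic
#' tie-break (the lexicographically smallest atom mapping among the maxima).
#' Feature counts follow the Tanimoto decomposition: `c` features shared,
#' `a` unique to A, `b` unique to B, `tanimoto = c / (a + b + c)`.
#'
#' @param molA,molB molecules
#' @param semantics a [match_semantics()] object
#' @param max_atoms hard size guard for the exact search
#' @return an `mcs_result` list with elements `mapping` (two-column matrix of
#'   atom indices), `c`, `a`, `b`, `tanimoto`
#' @export
mcs <- function(molA, molB, semantics = match_semantics(), max_atoms = 40L) {
  stopifnot(inherits(semantics, "match_semantics"))
  if (n_atoms(molA) > max_atoms || n_atoms(molB) > max_atoms) {
    stop(sprintf("molecule pair (%s, %s) too large for exact MCS (guard: %d atoms)",
                 molA$id, molB$id, max_atoms))
  }
  a_ <- mol_to_cpp(molA); b_ <- mol_to_cpp(molB)
  res <- .mcs_search(
    a_$elem, a_$chg, a_$bonds, b_$elem, b_$chg, b_$bonds,
    semantics$charge_sensitive, semantics$bond_match == "exact",
    semantics$unit == "atoms_bonds"
  )
  if (semantics$unit == "atoms") {
    cc <- res$atoms
    totA <- n_atoms(molA); totB <- n_atoms(molB)
  } else {
    cc <- res$atoms + res$edges
    totA <- n_atoms(molA) + n_bonds(molA)
    totB <- n_atoms(molB) + n_bonds(molB)
  }
  a_feat <- totA - cc; b_feat <- totB - cc
  structure(
    list(
      mapping = res$mapping, c = cc, a = a_feat, b = b_feat,
      atoms_mapped = res$atoms,
      tanimoto = if (a_feat + b_feat + cc == 0) 0 else cc / (a_feat + b_feat + cc),
      semantics = semantics,
      identifiers = c(molA$id, molB$id)
    ),
    class = "mcs_result"
  )
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<mcs_result> %s vs %s: c=%d a=%d b=%d tanimoto=%.3f\n",
              x$identifiers[1], x$identifiers[2], x$c, x$a, x$b, x$tanimoto))
  invisible(x)
}

#' Pairwise MCS-Tanimoto similarity matrix of a panel
#'
#' @param panel list of molecules
#' @param semantics a [match_semantics()] object
#' @param max_atoms size guard passed to [mcs()]
#' @return a `similarity_matrix`: symmetric numeric matrix with unit
#'   diagonal, identifiers as dimnames
#' @export
tanimoto_matrix <- function(panel, semantics = match_semantics(), max_atoms = 40L) {
  ids <- vapply(panel, function(m) m$id, "")
  n <- length(panel)
  mat <- diag(nrow = n)
  dimnames(mat) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        r <- tryCatch(
          mcs(panel[[i]], panel[[j]], semantics, max_atoms),
          error = function(e) {
            stop(sprintf("MCS failed for pair (%s, %s): %s",
                         ids[i], ids[j], conditionMessage(e)))
          }
        )
        mat[i, j] <- mat[j, i] <- r$tanimoto
      }
    }
  }
  class(mat) <- c("similarity_matrix", class(mat))
  mat
}

#' Long-format view of a similarity matrix
#' @param mat a similarity matrix
#' @return data.frame with columns idA, idB, tanimoto (upper triangle)
#' @export
similarity_long <- function(mat) {
  ids <- rownames(mat)
  n <- nrow(mat)
  out <- data.frame(idA = character(), idB = character(), tanimoto = numeric())
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq(i + 1L, n)) {
      out <- rbind(out, data.frame(idA = ids[i], idB = ids[j],
                                   tanimoto = mat[i, j]))
    }
  }
  out
}

#' Calibrate the match semantics against published coefficients
#'
#' Grid-searches the semantics variants (feature unit x charge sensitivity x
#' bond matching) and returns the variant minimizing the maximum absolute
#' deviation from the supplied published coefficients. Ties resolve by a
#' deterministic preference order (atoms before atoms+bonds, charge-blind
#' before charge-sensitive, any-order before exact-order). Residuals are
#' attached as the `"residuals"` attribute.
#'
#' @param panel list of molecules (must contain every identifier referenced)
#' @param printed_pairs data.frame with columns `a`, `b`, `tanimoto`
#' @return the winning [match_semantics()] with residual log attached
#' @export
calibrate_semantics <- function(panel, printed_pairs) {
  if (is.null(printed_pairs) || nrow(printed_pairs) == 0L) {
    stop("calibrate_semantics requires at least one printed reference pair")
  }
  ids <- vapply(panel, function(m) m$id, "")
  missing <- setdiff(unique(c(printed_pairs$a, printed_pairs$b)), ids)
  if (length(missing) > 0L) {
    stop(sprintf("printed pairs reference unknown identifiers: %s",
                 paste(missing, collapse = ", ")))
  }
  grid <- expand.grid(
    bond_match = c("any", "exact"),
    charge_sensitive = c(FALSE, TRUE),
    unit = c("atoms", "atoms_bonds"),
    stringsAsFactors = FALSE
  )
  # preference order for ties: unit first, then charge, then bond match
  grid <- grid[order(match(grid$unit, c("atoms", "atoms_bonds")),
                     grid$charge_sensitive,
                     match(grid$bond_match, c("any", "exact"))), ]
  best <- NULL; best_dev <- Inf; best_res <- NULL
  for (g in seq_len(nrow(grid))) {
    sem <- match_semantics(grid$unit[g], grid$charge_sensitive[g],
                           grid$bond_match[g])
    comp <- vapply(seq_len(nrow(printed_pairs)), function(k) {
      mcs(panel[[match(printed_pairs$a[k], ids)]],
          panel[[match(printed_pairs$b[k], ids)]], sem)$tanimoto
    }, numeric(1L))
    dev <- max(abs(comp - printed_pairs$tanimoto))
    if (dev < best_dev - 1e-12) {
      best <- sem; best_dev <- dev
      best_res <- data.frame(
        a = printed_pairs$a, b = printed_pairs$b,
        printed = printed_pairs$tanimoto, computed = comp,
        deviation = comp - printed_pairs$tanimoto
      )
    }
  }
  attr(best, "residuals") <- best_res
  attr(best, "max_abs_deviation") <- best_dev
  best
}
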