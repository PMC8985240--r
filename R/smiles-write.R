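#' Write a molecule as a SMILES string
#'
#' Emits a (non-canonical) SMILES spelling by depth-first traversal from atom
#' 1, with ring-closure digits for the non-tree bonds. Aromatic atoms are
#' written in kekulized uppercase form, which round-trips through
#' [parse_smiles()] to the same heavy-atom graph, hydrogen counts and charges
#' (the aromatic flags are not preserved; canonical aromatic output is out of
#' scope). Primarily used by the synthetic-molecule generator, whose output is
#' guaranteed to re-parse.
#'
#' @param mol a molecule
#' @return a SMILES string
#' @export
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  ord_mat <- matrix(0L, n, n)
  for (k in seq_len(n_bonds(mol))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    ord_mat[i, j] <- mol$bonds$order[k]; ord_mat[j, i] <- mol$bonds$order[k]
  }

  visited <- logical(n)
  ring_digit <- 0L
  ring_open <- vector("list", n)  # per atom: list of c(digit, order)

  # locate non-tree (ring-closure) bonds by DFS
  parent <- rep(0L, n)
  order_visit <- integer(0)
  stack <- 1L; visited[1L] <- TRUE
  closures <- list()
  dfs_edges <- function(v) {
    for (w in sort(adj[[v]])) {
      if (!visited[w]) {
        visited[w] <<- TRUE; parent[w] <<- v
        dfs_edges(w)
      } else if (parent[v] != w) {
        key <- paste(min(v, w), max(v, w))
        if (is.null(closures[[key]])) closures[[key]] <<- c(v, w)
      }
    }
  }
  dfs_edges(1L)

  for (key in names(closures)) {
    ring_digit <- ring_digit + 1L
    if (ring_digit > 9L) stop("more than 9 ring closures not supported by writer")
    pr <- closures[[key]]
    o <- ord_mat[pr[1L], pr[2L]]
    ring_open[[pr[1L]]] <- c(ring_open[[pr[1L]]], list(c(ring_digit, o)))
    ring_open[[pr[2L]]] <- c(ring_open[[pr[2L]]], list(c(ring_digit, 0L)))
  }
  closure_set <- unlist(lapply(closures, function(pr) paste(min(pr), max(pr))))

  bond_sym <- function(o) switch(o, "", "=", "#")

  atom_token <- function(a) {
    el <- mol$atoms$element[a]; ch <- mol$atoms$charge[a]
    h <- mol$atoms$implicit_h[a]
    if (ch == 0L && el %in% ORGANIC_SUBSET) return(el)
    chs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-" else sprintf("%+d", ch)
    hs <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    paste0("[", el, hs, chs, "]")
  }

  visited2 <- logical(n)
  emit <- function(a, from) {
    out <- atom_token(a)
    for (cl in ring_open[[a]]) {
      out <- paste0(out, bond_sym(cl[2L]), cl[1L])
    }
    visited2[a] <<- TRUE
    kids <- sort(adj[[a]])
    kids <- kids[!visited2[kids] &
                   !paste(pmin(a, kids), pmax(a, kids)) %in% closure_set]
    if (length(kids) > 0L) {
      for (i in seq_along(kids)) {
        w <- kids[i]
        if (visited2[w]) next  # may have been reached through a sibling
        sub <- paste0(bond_sym(ord_mat[a, w]), emit(w, a))
        if (i < length(kids)) sub <- paste0("(", sub, ")")
        out <- paste0(out, sub)
      }
    }
    out
  }
  emit(1L, 0L)
}

#' Read molecules from a .smi file
#'
#' One molecule per line, whitespace-separated `SMILES identifier`; `#` starts
#' a comment; blank lines are skipped. Missing identifiers default to
#' `mol<line>`.
#'
#' @param path path to a .smi file
#' @return list of `molecule` objects
#' @export
read_smi <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read input file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  mols <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    parts <- strsplit(trimws(lines[keep[i]]), "[[:space:]]+")[[1]]
    id <- if (length(parts) >= 2L) parts[2L] else paste0("mol", keep[i])
    mols[[i]] <- parse_smiles(parts[1L], id)
  }
  mols
}

#' Write molecules to a .smi file
#'
#' @param mols list of molecules
#' @param path output path
#' @return `path`, invisibly
#' @export
write_smi <- function(mols, path) {
  lines <- vapply(mols, function(m) paste(m$smiles, m$id, sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
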