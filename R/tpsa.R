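#' Topological polar surface area (Ertl group contributions)
#'
#' Sums the packaged Ertl fragment contributions over every nitrogen, oxygen,
#' sulfur and phosphorus atom, classifying each by element, aromaticity,
#' formal charge, hydrogen count, bond-order pattern and 3-ring membership.
#' The packaged table includes the sulfur/phosphorus extension, which the
#' zwitterionic monomers (sulfobetaines, phosphorylcholine) require.
#'
#' @param mol a molecule
#' @return numeric TPSA in Angstrom^2
#' @export
tpsa <- function(mol) {
  tab <- tpsa_table()
  total <- 0
  polar <- which(mol$atoms$element %in% c("N", "O", "S", "P"))
  if (length(polar) == 0L) return(0)

  in3 <- logical(n_atoms(mol))
  for (r in mol$rings) if (length(r) == 3L) in3[r] <- TRUE

  for (a in polar) {
    ns <- nd <- nt <- na_ <- 0L
    for (k in seq_len(n_bonds(mol))) {
      if (mol$bonds$a1[k] != a && mol$bonds$a2[k] != a) next
      if (mol$bonds$aromatic[k]) na_ <- na_ + 1L
      else if (mol$bonds$order[k] == 1L) ns <- ns + 1L
      else if (mol$bonds$order[k] == 2L) nd <- nd + 1L
      else nt <- nt + 1L
    }
    key <- paste(mol$atoms$element[a], as.integer(mol$atoms$aromatic[a]),
                 mol$atoms$charge[a], mol$atoms$implicit_h[a],
                 ns, nd, nt, na_, as.integer(in3[a]), sep = "|")
    # ring membership only distinguishes 3-rings; retry with the 0 flag
    hit <- tab[key]
    if (is.na(hit)) {
      key0 <- sub("\\|[01]$", "|0", key)
      hit <- tab[key0]
    }
    if (is.na(hit)) {
      el <- mol$atoms$element[a]
      stop(sprintf(
        paste0("no TPSA contribution for atom %d of '%s': environment ",
               "%s (aromatic=%d charge=%+d H=%d single=%d double=%d ",
               "triple=%d aromatic-bonds=%d)"),
        a, mol$id, el, as.integer(mol$atoms$aromatic[a]), mol$atoms$charge[a],
        mol$atoms$implicit_h[a], ns, nd, nt, na_
      ))
    }
    total <- total + hit
  }
  unname(total)
}
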