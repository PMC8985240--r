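# md5 of the packaged panel fixture; guards against silent edits
PANEL_MD5_EXPECTED <- "735d3ffde9ae1dd22609ea204775215a"

#' Load the 14-monomer polymer-brush panel
#'
#' Returns the packaged panel of monomers / polymer repeating units studied
#' as hydrophilic surface grafts (OZ, AA, VP, Gly, AcM, DMA, HPMA, HEMA, SA,
#' CBAA, CBMA, SBMA, MPC, VPPS), parsed into molecules in panel order. The
#' fixture file documents the provenance of every structure; its checksum is
#' verified on load.
#'
#' @param verify_checksum verify the fixture's md5 checksum (default TRUE)
#' @return named list of 14 molecules
#' @export
load_panel <- function(verify_checksum = TRUE) {
  path <- bs_extdata("monomer_panel.smi")
  if (verify_checksum) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, PANEL_MD5_EXPECTED)) {
      stop(sprintf(
        "monomer panel fixture checksum mismatch (got %s, expected %s)",
        got, PANEL_MD5_EXPECTED
      ))
    }
  }
  mols <- read_smi(path)
  names(mols) <- vapply(mols, function(m) m$id, "")
  mols
}
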