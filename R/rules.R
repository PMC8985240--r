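#' Evaluate drug-likeness rule filters on a descriptor vector
#'
#' Applies the Lipinski, Ghose, Veber, Egan, Muegge and lead-likeness
#' threshold filters with the packaged published constants. Lipinski passes
#' with at most one violation; the other rules allow none. The Abbott
#' bioavailability score is attached at report level. The package's single
#' lipophilicity scale (WLOGP) stands in for the per-rule logP flavours of
#' the original publications.
#'
#' @param desc one-row descriptor data.frame from [descriptor_vector()]
#' @param mol optional molecule (for ring/heteroatom counts used by Muegge
#'   and the net charge used by the bioavailability score); when omitted the
#'   Muegge ring/atom-composition conditions are skipped
#' @return data.frame with one row per rule: rule, passes, n_violations,
#'   violations (semicolon-separated labels), bioavailability_score
#' @export
evaluate_rules <- function(desc, mol = NULL) {
  co <- bs_constants()$rules
  v <- list()

  lip <- character()
  if (desc$molecular_weight > co$lipinski$mw_max) lip <- c(lip, "MW>500")
  if (desc$wlogp > co$lipinski$wlogp_max) lip <- c(lip, "WLOGP>5")
  if (desc$hbd > co$lipinski$hbd_max) lip <- c(lip, "HBD>5")
  if (desc$hba > co$lipinski$hba_max) lip <- c(lip, "HBA>10")
  v$Lipinski <- lip

  gh <- character()
  if (desc$molecular_weight < co$ghose$mw_min) gh <- c(gh, "MW<160")
  if (desc$molecular_weight > co$ghose$mw_max) gh <- c(gh, "MW>480")
  if (desc$wlogp < co$ghose$wlogp_min) gh <- c(gh, "WLOGP<-0.4")
  if (desc$wlogp > co$ghose$wlogp_max) gh <- c(gh, "WLOGP>5.6")
  if (desc$molar_refractivity < co$ghose$mr_min) gh <- c(gh, "MR<40")
  if (desc$molar_refractivity > co$ghose$mr_max) gh <- c(gh, "MR>130")
  if (desc$heavy_atoms < co$ghose$atoms_min) gh <- c(gh, "atoms<20")
  if (desc$heavy_atoms > co$ghose$atoms_max) gh <- c(gh, "atoms>70")
  v$Ghose <- gh

  vb <- character()
  if (desc$rotatable_bonds > co$veber$rotatable_max) vb <- c(vb, "rotatable>10")
  if (desc$tpsa > co$veber$tpsa_max) vb <- c(vb, "TPSA>140")
  v$Veber <- vb

  eg <- character()
  if (desc$wlogp > co$egan$wlogp_max) eg <- c(eg, "WLOGP>5.88")
  if (desc$tpsa > co$egan$tpsa_max) eg <- c(eg, "TPSA>131.6")
  v$Egan <- eg

  mg <- character()
  if (desc$molecular_weight < co$muegge$mw_min) mg <- c(mg, "MW<200")
  if (desc$molecular_weight > co$muegge$mw_max) mg <- c(mg, "MW>600")
  if (desc$wlogp < co$muegge$wlogp_min) mg <- c(mg, "WLOGP<-2")
  if (desc$wlogp > co$muegge$wlogp_max) mg <- c(mg, "WLOGP>5")
  if (desc$tpsa > co$muegge$tpsa_max) mg <- c(mg, "TPSA>150")
  if (desc$rotatable_bonds > co$muegge$rotatable_max) mg <- c(mg, "rotatable>15")
  if (desc$hba > co$muegge$hba_max) mg <- c(mg, "HBA>10")
  if (desc$hbd > co$muegge$hbd_max) mg <- c(mg, "HBD>5")
  if (!is.null(mol)) {
    if (length(mol$rings) > co$muegge$rings_max) mg <- c(mg, "rings>7")
    if (sum(mol$atoms$element == "C") < co$muegge$carbons_min) mg <- c(mg, "carbons<5")
    if (sum(mol$atoms$element != "C") < co$muegge$heteroatoms_min) mg <- c(mg, "heteroatoms<2")
  }
  v$Muegge <- mg

  ll <- character()
  if (desc$molecular_weight < co$leadlikeness$mw_min) ll <- c(ll, "MW<250")
  if (desc$molecular_weight > co$leadlikeness$mw_max) ll <- c(ll, "MW>350")
  if (desc$wlogp > co$leadlikeness$wlogp_max) ll <- c(ll, "WLOGP>3.5")
  if (desc$rotatable_bonds > co$leadlikeness$rotatable_max) ll <- c(ll, "rotatable>7")
  v$Leadlikeness <- ll

  allowed <- c(Lipinski = co$lipinski$allowed_violations,
               Ghose = co$ghose$allowed_violations,
               Veber = co$veber$allowed_violations,
               Egan = co$egan$allowed_violations,
               Muegge = co$muegge$allowed_violations,
               Leadlikeness = co$leadlikeness$allowed_violations)
  lipinski_pass <- length(v$Lipinski) <= co$lipinski$allowed_violations
  abs_score <- bioavailability_score(desc, mol, lipinski_pass)
  data.frame(
    rule = names(v),
    passes = vapply(names(v), function(r) length(v[[r]]) <= allowed[[r]], logical(1L)),
    n_violations = lengths(v),
    violations = vapply(v, paste, "", collapse = ";"),
    bioavailability_score = abs_score,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Abbott bioavailability score
#'
#' Probability class for >10% oral bioavailability in rat: net-anionic
#' species are scored on TPSA (>150 gives 0.11, 75-150 gives 0.56, otherwise
#' 0.85); all other species score 0.55 on a rule-of-five pass and 0.17 on a
#' failure.
#'
#' @param desc one-row descriptor data.frame
#' @param mol optional molecule for the net-charge check (assumed neutral
#'   when omitted)
#' @param lipinski_pass logical, rule-of-five outcome
#' @return numeric score in \[0, 1\]
#' @export
bioavailability_score <- function(desc, mol = NULL, lipinski_pass = TRUE) {
  co <- bs_constants()$bioavailability
  anionic <- !is.null(mol) && net_charge(mol) < 0L
  if (anionic) {
    if (desc$tpsa > co$anion_tpsa_high) return(co$score_anion_high_tpsa)
    if (desc$tpsa > co$anion_tpsa_low) return(co$score_anion_mid_tpsa)
    return(co$score_anion_low_tpsa)
  }
  if (lipinski_pass) co$score_ro5_pass else co$score_ro5_fail
}

#' Rule reports for a molecule panel
#'
#' @param panel list of molecules
#' @param path optional CSV output path
#' @return data.frame with one row per molecule x rule
#' @export
rules_table <- function(panel, path = NULL) {
  rows <- lapply(panel, function(m) {
    rep <- evaluate_rules(descriptor_vector(m), m)
    cbind(identifier = m$id, rep)
  })
  tab <- if (length(rows) == 0L) {
    data.frame(identifier = character(), rule = character(),
               passes = logical(), n_violations = integer(),
               violations = character(), bioavailability_score = numeric())
  } else do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(path)) { write.csv(tab, path, row.names = FALSE); return(invisible(tab)) }
  tab
}
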