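point_in_ellipse <- function(x, y, e) {
  th <- e$angle_deg * pi / 180
  dx <- x - e$cx; dy <- y - e$cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / e$rx)^2 + (v / e$ry)^2 <= 1
}

#' BOILED-Egg classification of one (TPSA, WLOGP) point
#'
#' The BOILED-Egg model predicts passive gastrointestinal absorption and
#' blood-brain-barrier permeation from the position of a molecule in the
#' (TPSA, WLOGP) plane: points inside the large "white" ellipse are
#' predicted well absorbed (high GI absorption), points inside the "yolk"
#' ellipse are predicted BBB permeant. The two memberships are evaluated
#' independently. Ellipse geometry is packaged in the versioned constants
#' file.
#'
#' @param tpsa topological polar surface area (Angstrom^2)
#' @param wlogp Wildman-Crippen logP
#' @return data.frame with columns tpsa, wlogp, gi_absorption
#'   ("high"/"low") and bbb_permeant ("yes"/"no")
#' @export
boiled_egg <- function(tpsa, wlogp) {
  stopifnot(is.finite(tpsa), is.finite(wlogp))
  egg <- bs_constants()$boiled_egg
  data.frame(
    tpsa = tpsa, wlogp = wlogp,
    gi_absorption = if (point_in_ellipse(tpsa, wlogp, egg$white)) "high" else "low",
    bbb_permeant = if (point_in_ellipse(tpsa, wlogp, egg$yolk)) "yes" else "no",
    stringsAsFactors = FALSE
  )
}

#' BOILED-Egg screen of a molecule panel
#'
#' One classification row per molecule. Zwitterionic molecules are flagged
#' with a warning, since the published egg was calibrated on neutral
#' species; the geometric classification is still reported.
#'
#' @param panel list of molecules
#' @param descriptors optional precomputed [descriptor_table()] (computed on
#'   the fly when omitted)
#' @param path optional CSV output path
#' @return data.frame with columns identifier, tpsa, wlogp, gi_absorption,
#'   bbb_permeant, warnings
#' @export
screen_panel <- function(panel, descriptors = NULL, path = NULL) {
  if (is.null(descriptors)) descriptors <- descriptor_table(panel)
  out <- data.frame(
    identifier = character(), tpsa = numeric(), wlogp = numeric(),
    gi_absorption = character(), bbb_permeant = character(),
    warnings = character(), stringsAsFactors = FALSE
  )
  for (i in seq_along(panel)) {
    d <- descriptors[i, ]
    cls <- boiled_egg(d$tpsa, d$wlogp)
    warn <- if (is_zwitterion(panel[[i]])) {
      "zwitterion: egg calibrated on neutral species"
    } else ""
    out <- rbind(out, data.frame(
      identifier = panel[[i]]$id, tpsa = d$tpsa, wlogp = d$wlogp,
      gi_absorption = cls$gi_absorption, bbb_permeant = cls$bbb_permeant,
      warnings = warn, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(path)) { write.csv(out, path, row.names = FALSE); return(invisible(out)) }
  out
}
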