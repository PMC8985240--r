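.bs_env <- new.env(parent = emptyenv())

# locate a packaged data file, working both from the installed package and
# from a source checkout
bs_extdata <- function(file) {
  p <- system.file("extdata", file, package = "brushscreen")
  if (nzchar(p)) return(p)
  for (cand in c(file.path("inst", "extdata", file), file.path("extdata", file))) {
    if (file.exists(cand)) return(cand)
  }
  stop(sprintf("packaged data file '%s' not found", file))
}

#' Packaged model constants
#'
#' Returns the versioned constants file shipped with the package: rule-filter
#' thresholds, ESOL coefficients, BOILED-Egg ellipse geometry, bioavailability
#' score classes and the published reference Tanimoto pairs used for
#' semantics calibration.
#'
#' @return a nested list
#' @export
bs_constants <- function() {
  if (is.null(.bs_env$constants)) {
    .bs_env$constants <- jsonlite::fromJSON(bs_extdata("constants.json"),
                                            simplifyDataFrame = TRUE)
  }
  .bs_env$constants
}

tpsa_table <- function() {
  if (is.null(.bs_env$tpsa)) {
    tb <- read.csv(bs_extdata("tpsa_contributions.csv"), comment.char = "#",
                   stringsAsFactors = FALSE)
    .bs_env$tpsa <- setNames(tb$tpsa, tb$key)
  }
  .bs_env$tpsa
}

crippen_table <- function() {
  if (is.null(.bs_env$crippen)) {
    tb <- read.csv(bs_extdata("crippen_contributions.csv"), comment.char = "#",
                   stringsAsFactors = FALSE)
    .bs_env$crippen <- tb
  }
  .bs_env$crippen
}
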