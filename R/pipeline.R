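#' Pipeline configuration
#'
#' @param input_path .smi input file (defaults to the packaged monomer panel)
#' @param output_dir directory for all outputs (created if missing)
#' @param mcs_semantics a [match_semantics()] object, or `"calibrate"` to
#'   pin the semantics against the packaged published coefficients
#' @param standardize z-score the descriptor table before clustering?
#' @param linkage clustering linkage; only `"group_average"` is supported
#' @param distance distance type; only `"euclidean"` is supported
#' @param seed integer seed (echoed into the manifest; the pipeline itself is
#'   deterministic)
#' @return a `pipeline_config` object
#' @export
pipeline_config <- function(input_path = NULL, output_dir = "results",
                            mcs_semantics = "calibrate", standardize = TRUE,
                            linkage = "group_average", distance = "euclidean",
                            seed = 1L) {
  if (!identical(linkage, "group_average")) {
    stop("only group_average linkage is supported")
  }
  if (!identical(distance, "euclidean")) {
    stop("only euclidean distances are supported")
  }
  structure(
    list(input_path = input_path, output_dir = output_dir,
         mcs_semantics = mcs_semantics, standardize = isTRUE(standardize),
         linkage = linkage, distance = distance, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full monomer-screening pipeline
#'
#' Parses the input panel, computes the descriptor table, rule filters and
#' BOILED-Egg screen, the pairwise MCS-Tanimoto similarity matrix (with
#' calibrated or explicitly chosen match semantics), and the group-average
#' dendrogram of the (optionally standardized) descriptors. All outputs are
#' plain CSV/TSV/Newick/JSON. The run is atomic: outputs are assembled in a
#' temporary directory and moved into place only on success.
#'
#' @param config a [pipeline_config()]
#' @return the run manifest (named list), invisibly
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  input <- config$input_path
  if (is.null(input)) input <- bs_extdata("monomer_panel.smi")
  if (!file.exists(input)) {
    stop(sprintf("cannot read input file '%s'", input))
  }
  set.seed(config$seed)
  stage <- "parse"
  manifest <- list(config = list(
    input_path = input, output_dir = config$output_dir,
    standardize = config$standardize, linkage = config$linkage,
    distance = config$distance, seed = config$seed
  ), warnings = character())

  tmp <- tempfile("brushscreen_run_")
  dir.create(tmp, recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  out_files <- character()
  emit <- function(name) {
    out_files <<- c(out_files, name)
    file.path(tmp, name)
  }

  result <- tryCatch({
    panel <- read_smi(input)
    ids <- vapply(panel, function(m) m$id, "")

    stage <- "descriptors"
    desc <- descriptor_table(panel, emit("descriptors.csv"))

    stage <- "rules"
    rules_table(panel, emit("rules.csv"))

    stage <- "adme"
    adme <- screen_panel(panel, desc, emit("adme.csv"))
    if (any(nzchar(adme$warnings))) {
      manifest$warnings <- c(manifest$warnings,
                             sprintf("%s: %s", adme$identifier[nzchar(adme$warnings)],
                                     adme$warnings[nzchar(adme$warnings)]))
    }

    stage <- "similarity"
    sem <- config$mcs_semantics
    if (identical(sem, "calibrate")) {
      printed <- bs_constants()$printed_reference_pairs$pairs
      usable <- all(c(printed$a, printed$b) %in% ids)
      if (usable) {
        sem <- calibrate_semantics(panel, printed)
        manifest$calibration <- list(
          semantics = unclass(sem)[c("unit", "charge_sensitive", "bond_match")],
          residuals = attr(sem, "residuals"),
          max_abs_deviation = attr(sem, "max_abs_deviation")
        )
      } else {
        sem <- match_semantics()
        manifest$warnings <- c(manifest$warnings,
          "calibration pairs absent from input; using default semantics")
      }
    }
    tm <- tanimoto_matrix(panel, sem)
    write.csv(as.data.frame(unclass(tm)), emit("tanimoto.csv"))
    utils::write.table(similarity_long(tm), emit("tanimoto_long.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

    stage <- "clustering"
    mat <- as_descriptor_matrix(desc)
    cl_input <- if (config$standardize) standardize(mat) else mat
    tree <- agglomerate(euclidean_distances(cl_input))
    writeLines(newick_export(tree), emit("dendrogram.nwk"))
    write.csv(tree$merges, emit("merges.csv"), row.names = FALSE)
    write.csv(as.data.frame(cophenetic_matrix(tree)), emit("cophenetic.csv"))
    ord <- heatmap_order(tree)
    write.csv(as.data.frame(unclass(tm))[ord, ord], emit("tanimoto_tree_order.csv"))

    stage <- "manifest"
    manifest$n_molecules <- length(panel)
    manifest$identifiers <- ids
    manifest$semantics <- unclass(sem)[c("unit", "charge_sensitive", "bond_match")]
    manifest$outputs <- out_files
    manifest$checksums <- as.list(tools::md5sum(file.path(tmp, out_files)))
    names(manifest$checksums) <- out_files
    manifest$package_version <- tryCatch(
      as.character(utils::packageVersion("brushscreen")),
      error = function(e) "source"
    )
    manifest$r_version <- as.character(getRversion())
    jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out_files <- c(out_files, "manifest.json")
    manifest
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  # success: move outputs into place atomically
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  for (f in out_files) {
    file.copy(file.path(tmp, f), file.path(config$output_dir, f), overwrite = TRUE)
  }
  invisible(result)
}
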