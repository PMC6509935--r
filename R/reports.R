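# Structured, machine-readable result files.  Every report carries
# provenance: an MD5 content hash of the serialized model, the perturbation
# label, and the package version.

model_hash <- function(net) {
    tf <- tempfile(fileext = ".txt")
    on.exit(unlink(tf))
    writeLines(serializeRules(net, "unicode"), tf)
    unname(tools::md5sum(tf))
}

report_provenance <- function(net, label = "") {
    list(model = if (!is.null(net@metadata$name)) net@metadata$name else "custom",
         modelHash = model_hash(net),
         perturbation = label,
         package = as.character(utils::packageVersion("fachkrec")))
}

#' Write attractor and phenotype reports
#'
#' Writes `attractors.csv` (one row per attractor state, columns = nodes in
#' model order plus attractor id, period, basin size), `phenotypes.csv`
#' (one row per attractor with its category and evidence), and
#' `report.json` bundling both with provenance (model content hash,
#' perturbation label, package version).
#'
#' @param net the [BooleanNetwork] the attractors came from.
#' @param atts an [AttractorSet].
#' @param dir output directory (created if needed).
#' @param label perturbation/protocol label recorded in the provenance.
#' @return invisibly, the paths written.
#' @export
writeAttractorReport <- function(net, atts, dir, label = "") {
    stopifnot(is(atts, "AttractorSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    states <- as.data.frame(atts)
    # phenotype calls only apply to models carrying the signature nodes
    signature <- unique(c(fa_division_nodes, fa_damage_nodes, fa_arrest_nodes))
    classify <- all(signature %in% atts@nodes)
    calls <- if (classify) classifyAttractors(atts) else NULL
    paths <- c(attractors = file.path(dir, "attractors.csv"),
               json = file.path(dir, "report.json"))
    utils::write.csv(states, paths[["attractors"]], row.names = FALSE)
    if (classify) {
        paths[["phenotypes"]] <- file.path(dir, "phenotypes.csv")
        utils::write.csv(calls, paths[["phenotypes"]], row.names = FALSE)
    }
    jsonlite::write_json(
        list(provenance = report_provenance(net, label),
             clamps = as.list(atts@clamps),
             initialSpaceSize = atts@initialSpaceSize,
             attractors = states, phenotypes = calls,
             categoryCounts = if (classify) as.list(attr(calls, "counts"))),
        paths[["json"]], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}

#' Write a double-mutant screen matrix
#'
#' @param net the base [BooleanNetwork].
#' @param screen data.frame from [doubleMutantScreen()].
#' @param dir output directory.
#' @param label background/protocol label for the provenance.
#' @return invisibly, the paths written.
#' @export
writeScreenReport <- function(net, screen, dir, label = "") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(screen = file.path(dir, "screen.csv"),
               json = file.path(dir, "screen.json"))
    utils::write.csv(screen, paths[["screen"]], row.names = FALSE)
    jsonlite::write_json(
        list(provenance = report_provenance(net, label), screen = screen),
        paths[["json"]], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
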