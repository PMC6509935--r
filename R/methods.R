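#' @describeIn nodes node names in encoding order
#' @export
setMethod("nodes", "BooleanNetwork", function(x) x@nodes)

#' @describeIn nodes node order underlying an attractor set
#' @export
setMethod("nodes", "AttractorSet", function(x) x@nodes)

#' @describeIn nodes node order of an attractor's state matrix
#' @export
setMethod("nodes", "Attractor", function(x) colnames(x@states))

#' @describeIn rules named list of update expressions
#' @export
setMethod("rules", "BooleanNetwork", function(x) x@rules)

#' @describeIn period number of states in the cycle
#' @export
setMethod("period", "Attractor", function(x) nrow(x@states))

#' @describeIn basinSize basin size (NA when not computed)
#' @export
setMethod("basinSize", "Attractor", function(x) x@basinSize)

#' @describeIn attractorStates cycle states in canonical rotation
#' @export
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @describeIn attractorStates terminal cycle of a trajectory
#' @export
setMethod("attractorStates", "Trajectory", function(x) x@attractor@states)

#' @describeIn category category string of a call
#' @export
setMethod("category", "PhenotypeCall", function(x) x@category)

#' @describeIn evidence named criterion vector of a call
#' @export
setMethod("evidence", "PhenotypeCall", function(x) x@evidence)

#' @export
setMethod("length", "AttractorSet", function(x) length(x@attractors))

#' @export
setMethod("[[", "AttractorSet", function(x, i) x@attractors[[i]])

setMethod("show", "BooleanNetwork", function(object) {
    cat(sprintf("BooleanNetwork with %d nodes\n", length(object@nodes)))
    preview <- utils::head(object@nodes, 8L)
    cat("  nodes: ", paste(preview, collapse = ", "),
        if (length(object@nodes) > 8L) ", ..." else "", "\n", sep = "")
    if (!is.null(object@metadata$name))
        cat("  name:  ", object@metadata$name, "\n", sep = "")
})

setMethod("show", "Attractor", function(object) {
    cat(sprintf("Attractor: period %d%s\n", nrow(object@states),
                if (nrow(object@states) == 1L) " (fixed point)" else ""))
    if (!is.na(object@basinSize))
        cat(sprintf("  basin size: %.0f\n", object@basinSize))
    on_nodes <- colnames(object@states)[colSums(object@states) > 0L]
    cat("  nodes ever ON: ",
        if (length(on_nodes)) paste(on_nodes, collapse = ", ") else "(none)",
        "\n", sep = "")
})

setMethod("show", "AttractorSet", function(object) {
    cat(sprintf("AttractorSet: %d attractor(s) over %d nodes\n",
                length(object@attractors), length(object@nodes)))
    if (length(object@clamps))
        cat("  clamps: ",
            paste(names(object@clamps), object@clamps, sep = "=", collapse = ", "),
            "\n", sep = "")
    if (!is.na(object@initialSpaceSize))
        cat(sprintf("  initial space: %.0f states\n", object@initialSpaceSize))
    for (i in seq_along(object@attractors)) {
        a <- object@attractors[[i]]
        cat(sprintf("  [%d] period %d, basin %s\n", i, nrow(a@states),
                    format(a@basinSize, big.mark = ",")))
    }
})

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: transient length %d into a period-%d attractor\n",
                nrow(object@transient), nrow(object@attractor@states)))
})

setMethod("show", "Perturbation", function(object) {
    cat("Perturbation:", if (nzchar(object@label)) object@label else "(unlabelled)", "\n")
    if (length(object@clamps))
        cat("  clamps: ",
            paste(names(object@clamps), object@clamps, sep = "=", collapse = ", "),
            "\n", sep = "")
    if (nrow(object@removedEdges))
        cat("  removed edges: ",
            paste(object@removedEdges[, 1L], object@removedEdges[, 2L],
                  sep = "->", collapse = ", "), "\n", sep = "")
})

setMethod("show", "PhenotypeCall", function(object) {
    cat("PhenotypeCall:", object@category, "\n")
    ev <- object@evidence
    cat("  evidence: ",
        paste(names(ev), ifelse(ev, "yes", "no"), sep = "=", collapse = ", "),
        "\n", sep = "")
})

#' Flatten an AttractorSet to a per-state data frame
#'
#' One row per attractor state; columns `attractor` (1-based id in set
#' order), `period`, `basinSize`, `stateIndex` (position in the cycle) and
#' one 0/1 column per node.  This is the tabular layout used by the CSV
#' report writers.
#'
#' @param x an [AttractorSet].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame.
#' @export
as.data.frame.AttractorSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    if (!length(x@attractors))
        return(cbind(data.frame(attractor = integer(0), period = integer(0),
                                basinSize = numeric(0), stateIndex = integer(0)),
                     as.data.frame(matrix(integer(0), 0, length(x@nodes),
                                          dimnames = list(NULL, x@nodes)))))
    parts <- lapply(seq_along(x@attractors), function(i) {
        a <- x@attractors[[i]]
        cbind(data.frame(attractor = i, period = nrow(a@states),
                         basinSize = a@basinSize,
                         stateIndex = seq_len(nrow(a@states))),
              as.data.frame(a@states))
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}

setMethod("as.data.frame", "AttractorSet", as.data.frame.AttractorSet)
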