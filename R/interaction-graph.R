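# Signed regulatory graph derived from the logic.  Edges are defined
# semantically, not syntactically: u -> v exists with positive sign iff some
# context of v's other regulators exists in which switching u from 0 to 1
# raises v's rule output (negative: lowers it; dual: both).  Literals with
# no witness in either direction are inert and excluded from the edge list
# (reported separately), so typographic occurrences never inflate counts.

#' Derive the signed interaction graph from the update rules
#'
#' For each pair (u, v) with u occurring in v's rule, enumerates all
#' assignments of v's regulators and looks for witness contexts in which
#' flipping u changes the rule output.  The sign is `positive`, `negative`
#' or `dual` according to which witnesses exist.
#'
#' @param net a [BooleanNetwork].
#' @param maxInputs refuse rules with more regulators than this (context
#'   enumeration is `2^(k-1)` per pair).
#' @return data.frame with columns `source`, `target`, `sign`, and two
#'   witness columns `witnessPos`/`witnessNeg` giving, when the sign
#'   direction exists, one verifying context of the *other* regulators as a
#'   compact `name=value` string (`""` when none, `"(empty)"` for a
#'   single-regulator rule).  Inert pairs are attached as the `"inert"`
#'   attribute (data.frame with `source`, `target`).
#' @examples
#' e <- deriveSignedEdges(faChkrecNetwork())
#' subset(e, source == "p53" & target == "p21")$sign  # "positive"
#' @export
deriveSignedEdges <- function(net, maxInputs = 16L) {
    stopifnot(is(net, "BooleanNetwork"))
    rows <- list()
    inert <- list()
    for (v in net@nodes) {
        expr <- net@rules[[v]]
        vars <- all.vars(expr)
        if (!length(vars)) next
        if (length(vars) > maxInputs)
            stop("rule for '", v, "' has ", length(vars),
                 " regulators; context enumeration refused (maxInputs = ",
                 maxInputs, ")", call. = FALSE)
        tt <- truthTable(expr, vars)
        ctx <- attr(tt, "contexts")
        for (u in vars) {
            ui <- match(u, vars)
            u0 <- ctx[, ui] == 0L
            # rows come in (u=0, u=1) pairs: row r with u=0 pairs with r + 2^(ui-1)
            partner <- which(u0) + 2^(ui - 1L)
            f0 <- tt[u0]
            f1 <- tt[partner]
            pos <- which(f0 == 0L & f1 == 1L)
            neg <- which(f0 == 1L & f1 == 0L)
            fmt <- function(idx) {
                if (!length(idx)) return("")
                w <- ctx[which(u0)[idx[1L]], setdiff(vars, u), drop = TRUE]
                if (!length(w)) return("(empty)")
                paste(names(w), w, sep = "=", collapse = ",")
            }
            if (!length(pos) && !length(neg)) {
                inert[[length(inert) + 1L]] <- data.frame(source = u, target = v)
                next
            }
            sign <- if (length(pos) && length(neg)) "dual"
                    else if (length(pos)) "positive" else "negative"
            rows[[length(rows) + 1L]] <-
                data.frame(source = u, target = v, sign = sign,
                           witnessPos = fmt(pos), witnessNeg = fmt(neg),
                           stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(source = character(0), target = character(0),
                           sign = character(0), witnessPos = character(0),
                           witnessNeg = character(0))
    rownames(out) <- NULL
    attr(out, "inert") <- if (length(inert)) do.call(rbind, inert)
                          else data.frame(source = character(0),
                                          target = character(0))
    out
}

#' Summarise a signed edge list
#'
#' Dual-sign edges count once in the total and get their own column rather
#' than being split into a positive and a negative edge.
#'
#' @param edges data.frame from [deriveSignedEdges()].
#' @return list with `counts` (named vector: total, positive, negative,
#'   dual) and `degrees` (data.frame: node, outDegree, inDegree).
#' @export
edgeSummary <- function(edges) {
    counts <- c(total = nrow(edges),
                positive = sum(edges$sign == "positive"),
                negative = sum(edges$sign == "negative"),
                dual = sum(edges$sign == "dual"))
    nodes <- sort(unique(c(edges$source, edges$target)))
    degrees <- data.frame(
        node = nodes,
        outDegree = vapply(nodes, function(x) sum(edges$source == x), integer(1)),
        inDegree = vapply(nodes, function(x) sum(edges$target == x), integer(1)))
    rownames(degrees) <- NULL
    list(counts = counts, degrees = degrees)
}

#' Export a signed edge list in simple interaction format (SIF)
#'
#' One line per edge: `source sign target`.
#'
#' @param edges data.frame from [deriveSignedEdges()].
#' @param file optional path.
#' @return character vector of lines (invisibly when `file` is given).
#' @export
writeSIF <- function(edges, file = NULL) {
    lines <- sprintf("%s\t%s\t%s", edges$source, edges$sign, edges$target)
    if (!is.null(file)) {
        writeLines(lines, file)
        return(invisible(lines))
    }
    lines
}
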