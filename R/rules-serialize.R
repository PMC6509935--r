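# Precedence levels for parenthesis-minimal serialization.
op_prec <- function(e) {
    if (!is.call(e)) return(4L)
    switch(as.character(e[[1L]]), "(" = op_prec(e[[2L]]),
           "!" = 3L, "&" = 2L, "|" = 1L, 4L)
}

deparse_expr <- function(e, dialect, nameMap) {
    sym <- if (dialect == "unicode")
        c("&" = "∧", "|" = "∨", "!" = "¬")
    else c("&" = "&", "|" = "|", "!" = "!")
    rec <- function(e, ctx) {
        if (is.symbol(e)) {
            nm <- as.character(e)
            if (dialect == "boolnet") nm <- to_safe_name(nm, nameMap)
            return(nm)
        }
        if (is.numeric(e)) return(as.character(as.integer(e)))
        op <- as.character(e[[1L]])
        if (op == "(") return(rec(e[[2L]], ctx))
        p <- op_prec(e)
        out <- if (op == "!") {
            paste0(sym[["!"]], rec(e[[2L]], p))
        } else {
            paste(rec(e[[2L]], p), sym[[op]], rec(e[[3L]], p + 1L))
        }
        if (p < ctx) paste0("(", out, ")") else out
    }
    rec(e, 0L)
}

#' Serialize a BooleanNetwork to rule-file text
#'
#' The output parses back (with [parseRules()], same dialect) to a network
#' whose per-node truth tables equal the input's.  The boolnet dialect emits
#' the `targets, factors` header and identifier-safe node names via
#' [nodeNameMap()].
#'
#' @param net a [BooleanNetwork].
#' @param dialect `"unicode"` or `"boolnet"`.
#' @param file optional path; when given, lines are written there.
#' @param nameMap canonical-to-safe name map used by the boolnet dialect.
#' @return character vector of lines (invisibly when `file` is given).
#' @examples
#' cat(serializeRules(parseRules("p21 <- p53"), "boolnet"), sep = "\n")
#' @export
serializeRules <- function(net, dialect = c("unicode", "boolnet"), file = NULL,
                           nameMap = nodeNameMap()) {
    dialect <- match.arg(dialect)
    stopifnot(is(net, "BooleanNetwork"))
    lines <- vapply(net@nodes, function(nd) {
        rhs <- deparse_expr(net@rules[[nd]], dialect, nameMap)
        if (dialect == "unicode") paste(nd, "<-", rhs)
        else paste0(to_safe_name(nd, nameMap), ", ", rhs)
    }, character(1), USE.NAMES = FALSE)
    if (dialect == "boolnet") lines <- c("targets, factors", lines)
    if (!is.null(file)) {
        writeLines(lines, file)
        return(invisible(lines))
    }
    lines
}
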