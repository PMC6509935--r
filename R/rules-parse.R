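# Plain-text rule-file dialects
# -----------------------------
# unicode:  one rule per line, "target <- expression", operators
#           ∧ (AND), ∨ (OR), ¬ (NOT); "←" is accepted in
#           place of "<-", and the ASCII operators & | ! are accepted too.
# boolnet:  BoolNet-compatible "targets, factors" format: optional header
#           line "targets, factors", then "target, expression" with & | !.
#           Node names are identifier-safe; the documented name map converts
#           them to and from the canonical (hyphenated) forms.
# Precedence in both dialects: NOT > AND > OR; parentheses override.

#' Bidirectional map between canonical and identifier-safe node names
#'
#' Canonical names follow the field's nomenclature and may contain hyphens
#' (`PARP-1`, `R-DSB`, `KU-53BP1`, `CDK1-AurA`, `CycB-CDK1`, `PP2A-B55`);
#' the BoolNet text format requires identifier-safe names, so serialization
#' applies this map and parsing inverts it.
#'
#' @return named character vector: names are canonical node names, values the
#'   identifier-safe forms used in BoolNet files.
#' @examples
#' nodeNameMap()[["PARP-1"]]  # "PARP1"
#' @export
nodeNameMap <- function() {
    c("PARP-1"    = "PARP1",
      "R-DSB"     = "RDSB",
      "KU-53BP1"  = "KU_53BP1",
      "CDK1-AurA" = "CDK1_AurA",
      "CycB-CDK1" = "CycB_CDK1",
      "PP2A-B55"  = "PP2A_B55")
}

to_safe_name <- function(x, map = nodeNameMap()) {
    hit <- match(x, names(map))
    out <- ifelse(is.na(hit), x, map[hit])
    bad <- grepl("[^A-Za-z0-9_]", out)
    if (any(bad)) out[bad] <- gsub("[^A-Za-z0-9_]", "_", out[bad])
    unname(out)
}

from_safe_name <- function(x, map = nodeNameMap()) {
    hit <- match(x, map)
    unname(ifelse(is.na(hit), x, names(map)[hit]))
}

# Tokenizer shared by both dialects (input already normalized to ASCII ops).
# Node names: start with a letter, may contain letters, digits, "_" and "-".
tokenize_expr <- function(s, line = NA_integer_) {
    tokens <- character(0)
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
        ch <- substr(s, i, i)
        if (grepl("^\\s$", ch)) { i <- i + 1L; next }
        if (ch %in% c("&", "|", "!", "(", ")")) {
            tokens <- c(tokens, ch); i <- i + 1L; next
        }
        if (ch %in% c("0", "1")) {
            nxt <- substr(s, i + 1L, i + 1L)
            if (nzchar(nxt) && grepl("[A-Za-z0-9_-]", nxt))
                stop_parse(line, "malformed token starting at '",
                           substr(s, i, i + 5L), "'")
            tokens <- c(tokens, ch); i <- i + 1L; next
        }
        if (grepl("[A-Za-z]", ch)) {
            m <- regmatches(substr(s, i, n),
                            regexpr("^[A-Za-z][A-Za-z0-9_-]*", substr(s, i, n)))
            tokens <- c(tokens, m)
            i <- i + nchar(m)
            next
        }
        stop_parse(line, "unexpected character '", ch, "'")
    }
    tokens
}

stop_parse <- function(line, ...) {
    prefix <- if (is.na(line)) "parse error: "
              else sprintf("parse error on line %d: ", line)
    stop(prefix, ..., call. = FALSE)
}

# Recursive-descent parser over the token stream.
#   or   := and ("|" and)*
#   and  := not ("&" not)*
#   not  := "!" not | atom
#   atom := name | 0 | 1 | "(" or ")"
parse_expr_tokens <- function(tokens, line = NA_integer_) {
    pos <- 1L
    peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
    advance <- function() { pos <<- pos + 1L }

    parse_or <- function() {
        e <- parse_and()
        while (!is.na(peek()) && peek() == "|") {
            advance()
            e <- call("|", e, parse_and())
        }
        e
    }
    parse_and <- function() {
        e <- parse_not()
        while (!is.na(peek()) && peek() == "&") {
            advance()
            e <- call("&", e, parse_not())
        }
        e
    }
    parse_not <- function() {
        if (!is.na(peek()) && peek() == "!") {
            advance()
            return(call("!", parse_not()))
        }
        parse_atom()
    }
    parse_atom <- function() {
        t <- peek()
        if (is.na(t)) stop_parse(line, "unexpected end of expression")
        if (t == "(") {
            advance()
            e <- parse_or()
            if (is.na(peek()) || peek() != ")")
                stop_parse(line, "missing closing parenthesis")
            advance()
            return(e)
        }
        if (t %in% c("0", "1")) { advance(); return(as.integer(t)) }
        if (grepl("^[A-Za-z]", t)) { advance(); return(as.name(t)) }
        stop_parse(line, "unexpected token '", t, "'")
    }

    e <- parse_or()
    if (!is.na(peek()))
        stop_parse(line, "trailing input starting at '", peek(), "'")
    e
}

normalize_ops <- function(s) {
    s <- gsub("∧", " & ", s)
    s <- gsub("∨", " | ", s)
    s <- gsub("¬", " ! ", s)
    s <- gsub("←", " <- ", s)
    s
}

#' Parse a plain-text Boolean rule file into a BooleanNetwork
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines, or a file path (when `file = TRUE`).
#' @param dialect `"unicode"` (`target <- expr`, logical-symbol or ASCII
#'   operators) or `"boolnet"` (`target, expr`, ASCII operators, optional
#'   `targets, factors` header).
#' @param file logical; treat `text` as a path and read it.
#' @param nameMap applied in reverse when parsing the boolnet dialect so the
#'   canonical hyphenated node names round-trip; set to `character(0)` to
#'   keep file names verbatim.
#' @param implicitInputs when `TRUE` (default), variables referenced by some
#'   rule but never declared as a target become input nodes with identity
#'   rules (`x <- x`), appended after the targets; when `FALSE` they raise
#'   an error listing every offender.
#' @return a [BooleanNetwork].  Node order is the order of rule lines
#'   (implicit inputs last, in order of first appearance).
#' @details Errors report the offending line: syntax errors, duplicate
#'   targets, and — with `implicitInputs = FALSE` — undeclared variables
#'   (listed exhaustively).
#' @examples
#' parseRules("p21 <- p53")
#' parseRules(c("targets, factors", "A, !B", "B, A"), dialect = "boolnet")
#' @export
parseRules <- function(text, dialect = c("unicode", "boolnet"), file = FALSE,
                       nameMap = nodeNameMap(), implicitInputs = TRUE) {
    dialect <- match.arg(dialect)
    if (file) text <- readLines(text, warn = FALSE)
    if (length(text) == 1L && grepl("\n", text))
        text <- strsplit(text, "\n", fixed = TRUE)[[1L]]

    targets <- character(0)
    exprs <- list()
    for (ln in seq_along(text)) {
        raw <- text[[ln]]
        s <- normalize_ops(raw)
        s <- sub("#.*$", "", s)
        if (!nzchar(trimws(s))) next
        if (dialect == "boolnet" &&
            grepl("^\\s*targets\\s*,\\s*factors\\s*$", s, ignore.case = TRUE))
            next
        if (dialect == "unicode") {
            if (!grepl("<-", s, fixed = TRUE))
                stop_parse(ln, "expected 'target <- expression'")
            parts <- strsplit(s, "<-", fixed = TRUE)[[1L]]
            if (length(parts) != 2L)
                stop_parse(ln, "expected a single '<-'")
        } else {
            ci <- regexpr(",", s, fixed = TRUE)
            if (ci < 0L)
                stop_parse(ln, "expected 'target, expression'")
            parts <- c(substr(s, 1L, ci - 1L), substr(s, ci + 1L, nchar(s)))
        }
        tgt <- trimws(parts[[1L]])
        if (!grepl("^[A-Za-z][A-Za-z0-9_-]*$", tgt))
            stop_parse(ln, "invalid target name '", tgt, "'")
        tokens <- tokenize_expr(parts[[2L]], line = ln)
        if (dialect == "boolnet" && length(nameMap)) {
            tgt <- from_safe_name(tgt, nameMap)
            isvar <- grepl("^[A-Za-z]", tokens) & !tokens %in% c("0", "1")
            tokens[isvar] <- from_safe_name(tokens[isvar], nameMap)
        }
        if (tgt %in% targets)
            stop_parse(ln, "duplicate target '", tgt, "'")
        e <- parse_expr_tokens(tokens, line = ln)
        targets <- c(targets, tgt)
        exprs <- c(exprs, list(e))
    }
    if (!length(targets)) stop("no rules found in input", call. = FALSE)
    names(exprs) <- targets
    used <- unique(unlist(lapply(exprs, all.vars)))
    undecl <- setdiff(used, targets)
    if (length(undecl)) {
        if (!implicitInputs)
            stop("rules reference undeclared node(s): ",
                 paste(sort(undecl), collapse = ", "), call. = FALSE)
        inputs <- lapply(undecl, as.name)
        names(inputs) <- undecl
        targets <- c(targets, undecl)
        exprs <- c(exprs, inputs)
    }
    new("BooleanNetwork", nodes = targets, rules = exprs, metadata = list())
}
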