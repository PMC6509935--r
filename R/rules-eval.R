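# Boolean expression trees are plain R language objects: a symbol (node
# reference), the constants 0/1, or a call to one of `!`, `&`, `|` (calls to
# `(` are tolerated and skipped).  Keeping them as language objects means
# substitution, variable extraction (all.vars) and vectorized evaluation all
# come for free.

is_bool_expr <- function(e) {
    if (is.symbol(e)) return(nzchar(as.character(e)))
    if (is.numeric(e) && length(e) == 1L) return(e %in% c(0, 1))
    if (is.call(e)) {
        op <- as.character(e[[1L]])
        if (op == "(") return(is_bool_expr(e[[2L]]))
        if (op == "!") return(length(e) == 2L && is_bool_expr(e[[2L]]))
        if (op %in% c("&", "|"))
            return(length(e) == 3L && is_bool_expr(e[[2L]]) && is_bool_expr(e[[3L]]))
        return(FALSE)
    }
    FALSE
}

#' Evaluate a Boolean expression under an assignment
#'
#' Standard Boolean semantics with precedence NOT > AND > OR already baked
#' into the expression tree.  Evaluation is vectorized: every variable may be
#' bound to an equal-length 0/1 vector, in which case the result is the
#' pointwise evaluation (this is how truth tables and whole-state-space
#' sweeps are computed).
#'
#' @param expr a Boolean expression (R language object over `!`, `&`, `|`,
#'   node symbols and the constants 0/1), e.g. a rule from [rules()].
#' @param state named 0/1 vector or list binding every variable referenced by
#'   `expr`; extra names are ignored.
#' @return integer 0/1 vector (length 1 for a scalar assignment).
#' @examples
#' net <- faChkrecNetwork()
#' evaluateRule(rules(net)[["p21"]], c(p53 = 1))
#' @export
evaluateRule <- function(expr, state) {
    env <- as.list(state)
    eval_expr(expr, env)
}

eval_expr <- function(e, env) {
    if (is.symbol(e)) {
        nm <- as.character(e)
        v <- env[[nm]]
        if (is.null(v))
            stop("variable '", nm, "' is not assigned in the state", call. = FALSE)
        return(as.integer(v))
    }
    if (is.numeric(e)) return(as.integer(e))
    op <- as.character(e[[1L]])
    switch(op,
           "(" = eval_expr(e[[2L]], env),
           "!" = 1L - eval_expr(e[[2L]], env),
           "&" = as.integer(eval_expr(e[[2L]], env) & eval_expr(e[[3L]], env)),
           "|" = as.integer(eval_expr(e[[2L]], env) | eval_expr(e[[3L]], env)),
           stop("unsupported operator '", op, "' in Boolean expression",
                call. = FALSE))
}

#' Truth table of a Boolean expression
#'
#' Enumerates all `2^k` assignments of the given input variables (first input
#' toggling fastest, i.e. input `i` is bit `i - 1` of the row index) and
#' evaluates the expression on each.
#'
#' @param expr Boolean expression.
#' @param inputs character vector of variable names; defaults to
#'   `all.vars(expr)`.  Must cover every variable referenced.
#' @param maxInputs guard against context explosion; enumeration refuses when
#'   `length(inputs)` exceeds it.
#' @return integer 0/1 vector of length `2^length(inputs)`, with the input
#'   assignments attached as the `"contexts"` attribute (0/1 matrix).
#' @examples
#' truthTable(quote(!(A & B) | C))
#' @export
truthTable <- function(expr, inputs = all.vars(expr), maxInputs = 16L) {
    k <- length(inputs)
    if (k > maxInputs)
        stop("truth-table enumeration over ", k,
             " inputs exceeds maxInputs = ", maxInputs, call. = FALSE)
    if (k == 0L) {
        out <- eval_expr(expr, list())
        attr(out, "contexts") <- matrix(integer(0), 1L, 0L)
        return(out)
    }
    ctx <- vapply(seq_len(k) - 1L,
                  function(b) rep(rep(0:1, each = 2^b), length.out = 2^k),
                  integer(2^k))
    colnames(ctx) <- inputs
    out <- eval_expr(expr, as.list(as.data.frame(ctx)))
    if (length(out) == 1L) out <- rep(out, 2^k)
    attr(out, "contexts") <- ctx
    out
}

#' Semantic equality of two Boolean expressions
#'
#' Two expressions are equal iff their truth tables over the union of their
#' referenced variables agree.
#'
#' @param a,b Boolean expressions.
#' @param maxInputs passed to [truthTable()].
#' @return logical scalar.
#' @export
sameRule <- function(a, b, maxInputs = 16L) {
    vars <- sort(unique(c(all.vars(a), all.vars(b))))
    if (length(vars) == 0L)
        return(eval_expr(a, list()) == eval_expr(b, list()))
    ta <- truthTable(a, vars, maxInputs = maxInputs)
    tb <- truthTable(b, vars, maxInputs = maxInputs)
    all(ta == tb)
}

# Substitute a variable by a constant (or another expression) inside a rule.
substitute_var <- function(e, var, value) {
    if (is.symbol(e)) {
        if (identical(as.character(e), var)) return(value)
        return(e)
    }
    if (is.numeric(e)) return(e)
    for (i in seq.int(2L, length(e)))
        e[[i]] <- substitute_var(e[[i]], var, value)
    e
}
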