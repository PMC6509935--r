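#' Generate a reproducible random Boolean network
#'
#' Each node receives `k` distinct regulators drawn uniformly and a uniform
#' random truth table over them, rebuilt as an explicit expression
#' (disjunctive normal form; constant rules become the constants 0/1).
#' Identical `n`, `k` and `seed` give identical networks, and the generator
#' refuses to run without a seed so sampled fixtures are always
#' reproducible.
#'
#' @param n number of nodes (`X1` ... `Xn`).
#' @param k in-degree of every node (`1 <= k <= n`).
#' @param seed integer RNG seed.
#' @return a [BooleanNetwork].
#' @examples
#' net <- randomNetwork(5, 2, seed = 1)
#' identical(serializeRules(net), serializeRules(randomNetwork(5, 2, seed = 1)))
#' @export
randomNetwork <- function(n, k, seed) {
    if (missing(seed) || is.null(seed))
        stop("randomNetwork requires an explicit seed", call. = FALSE)
    stopifnot(n >= 1, k >= 1, k <= n)
    nodes <- paste0("X", seq_len(n))
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    rules <- lapply(seq_len(n), function(i) {
        regs <- sample(nodes, k)
        tt <- sample(0:1, 2^k, replace = TRUE)
        tt_to_expr(tt, regs)
    })
    names(rules) <- nodes
    net <- new("BooleanNetwork", nodes = nodes, rules = rules,
               metadata = list(name = sprintf("random(n=%d,k=%d,seed=%d)",
                                              n, k, as.integer(seed))))
    validObject(net)
    net
}

# Truth table (input i = bit i-1 of the row index) -> DNF expression.
tt_to_expr <- function(tt, inputs) {
    ones <- which(tt == 1L) - 1L
    if (!length(ones)) return(0L)
    if (length(ones) == 2^length(inputs)) return(1L)
    terms <- lapply(ones, function(row) {
        lits <- lapply(seq_along(inputs), function(i) {
            if (bitwAnd(row, bitwShiftL(1L, i - 1L)) > 0L) as.name(inputs[i])
            else call("!", as.name(inputs[i]))
        })
        Reduce(function(a, b) call("&", a, b), lits)
    })
    Reduce(function(a, b) call("|", a, b), terms)
}

.Random.seed_get <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed_set <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
}
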