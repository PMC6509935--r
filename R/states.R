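# State encoding: bit i-1 of the integer code is node i in network order.
# Codes are exact doubles (n <= 25 << 53 bits), so the full 2^25 space fits
# ordinary numeric vectors.

#' Encode a network state as an integer code
#'
#' Bit `i - 1` of the code carries node `i` in the network's node order;
#' encoding and decoding round-trip exactly.
#'
#' @param state named 0/1 vector covering every node, or an unnamed 0/1
#'   vector already in node order.
#' @param nodes node order (e.g. `nodes(net)`).
#' @return numeric scalar code in `[0, 2^n)`.
#' @export
encodeState <- function(state, nodes) {
    v <- as_state_vector(state, nodes)
    sum(v * 2^(seq_along(nodes) - 1))
}

#' Decode an integer code into a named network state
#'
#' @param code numeric scalar in `[0, 2^n)`.
#' @param nodes node order.
#' @return named integer 0/1 vector.
#' @export
decodeState <- function(code, nodes) {
    n <- length(nodes)
    v <- integer(n)
    for (i in seq_len(n)) {
        v[i] <- as.integer(code %% 2)
        code <- code %/% 2
    }
    names(v) <- nodes
    v
}

as_state_vector <- function(state, nodes) {
    n <- length(nodes)
    if (is.null(names(state))) {
        if (length(state) != n)
            stop("unnamed state must have one value per node", call. = FALSE)
        v <- as.integer(state)
    } else {
        miss <- setdiff(nodes, names(state))
        if (length(miss))
            stop("state is missing node(s): ", paste(miss, collapse = ", "),
                 call. = FALSE)
        unknown <- setdiff(names(state), nodes)
        if (length(unknown))
            stop("state assigns unknown node(s): ",
                 paste(unknown, collapse = ", "), call. = FALSE)
        v <- as.integer(state[nodes])
    }
    if (!all(v %in% c(0L, 1L)))
        stop("state values must be 0 or 1", call. = FALSE)
    names(v) <- nodes
    v
}

#' Build a named state vector: all nodes 0 except the given ones
#'
#' @param nodes node order (e.g. `nodes(net)`).
#' @param on character vector of nodes set to 1.
#' @return named integer 0/1 vector.
#' @export
makeState <- function(nodes, on = character(0)) {
    v <- integer(length(nodes))
    names(v) <- nodes
    bad <- setdiff(on, nodes)
    if (length(bad))
        stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
    v[on] <- 1L
    v
}

check_clamps <- function(clamps, nodes) {
    if (is.null(clamps) || length(clamps) == 0L)
        return(integer(0))
    if (is.null(names(clamps)) || any(!nzchar(names(clamps))))
        stop("clamps must be a named vector", call. = FALSE)
    unknown <- setdiff(names(clamps), nodes)
    if (length(unknown))
        stop("unknown clamp node(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    if (anyDuplicated(names(clamps)))
        stop("a node appears more than once in clamps", call. = FALSE)
    cl <- as.integer(clamps)
    if (!all(cl %in% c(0L, 1L)))
        stop("clamp values must be 0 or 1", call. = FALSE)
    names(cl) <- names(clamps)
    cl
}
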