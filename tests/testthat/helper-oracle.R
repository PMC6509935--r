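# Independent brute-force oracle for synchronous Boolean dynamics.
# Deliberately naive and separate from the package's compiled engine and
# recursive evaluator: rules are evaluated with base R's eval(), states are
# tracked as plain strings, and attractors are found by per-state trajectory
# simulation with a visited list.

oracle_eval <- function(expr, state) {
    as.integer(eval(expr, as.list(state)) != 0)
}

oracle_step <- function(net, state, clamps = NULL) {
    out <- vapply(nodes(net),
                  function(nd) oracle_eval(rules(net)[[nd]], state),
                  integer(1))
    if (!is.null(clamps)) out[names(clamps)] <- as.integer(clamps)
    out
}

oracle_key <- function(state) paste(state, collapse = "")

# Canonical key of a cycle: lexicographically smallest rotation of the
# per-state keys.
oracle_cycle_key <- function(states) {
    keys <- vapply(states, oracle_key, character(1))
    rots <- vapply(seq_along(keys), function(i)
        paste(keys[c(i:length(keys), seq_len(i - 1))], collapse = "|"),
        character(1))
    min(rots)
}

# All attractors and basin sizes from the given initial states (defaults to
# the whole space), by naive simulation.
oracle_attractors <- function(net, clamps = NULL, inits = NULL) {
    n <- length(nodes(net))
    if (is.null(inits)) inits <- 0:(2^n - 1)
    basins <- list()
    for (code in inits) {
        state <- as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
        names(state) <- nodes(net)
        if (!is.null(clamps)) state[names(clamps)] <- as.integer(clamps)
        seen <- character(0)
        path <- list()
        repeat {
            k <- oracle_key(state)
            hit <- match(k, seen)
            if (!is.na(hit)) {
                cyc <- path[hit:length(path)]
                ck <- oracle_cycle_key(cyc)
                basins[[ck]] <- c(if (is.null(basins[[ck]])) 0 else basins[[ck]][1],
                                  length(cyc))
                basins[[ck]][1] <- basins[[ck]][1] + 1
                break
            }
            seen <- c(seen, k)
            path <- c(path, list(state))
            state <- oracle_step(net, state, clamps)
        }
    }
    basins  # named list: canonical cycle key -> c(basin, period)
}

# Canonical keys of an AttractorSet, for comparison with the oracle.
set_cycle_keys <- function(atts) {
    vapply(seq_len(length(atts)), function(i) {
        s <- attractorStates(atts[[i]])
        oracle_cycle_key(lapply(seq_len(nrow(s)), function(r) s[r, ]))
    }, character(1))
}
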