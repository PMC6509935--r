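# Synchronous dynamics.  The single-step and small-scale operations run in
# plain R; trajectory following and exhaustive enumeration compile each rule
# to a truth table over its regulators and hand the bit-packed problem to
# the C++ functional-graph engine.

#' One synchronous update step
#'
#' Every unclamped node takes the value of its rule evaluated on the input
#' state; every clamped node takes its clamp value regardless of its rule.
#' Deterministic.
#'
#' @param net a [BooleanNetwork].
#' @param state named 0/1 vector (or unnamed, in node order).
#' @param clamps optional named 0/1 vector of clamped nodes.
#' @return named integer 0/1 state vector.
#' @examples
#' net <- faChkrecNetwork()
#' s1 <- stepState(net, rep(0L, 25))
#' names(which(s1 == 1L))  # "CDK1-AurA"
#' @export
stepState <- function(net, state, clamps = NULL) {
    stopifnot(is(net, "BooleanNetwork"))
    v <- as_state_vector(state, net@nodes)
    cl <- check_clamps(clamps, net@nodes)
    env <- as.list(v)
    out <- vapply(net@nodes, function(nd) eval_expr(net@rules[[nd]], env),
                  integer(1))
    if (length(cl)) out[names(cl)] <- cl
    out
}

# Compile rules to truth tables over their regulators; returns the engine's
# argument list.  Clamped nodes keep a dummy constant table (the engine
# overrides them anyway).
compile_network <- function(net, clamps = integer(0)) {
    nodes <- net@nodes
    n <- length(nodes)
    clampVec <- rep(-1L, n)
    if (length(clamps)) clampVec[match(names(clamps), nodes)] <- clamps
    inputIdx <- vector("list", n)
    tts <- vector("list", n)
    for (i in seq_len(n)) {
        if (clampVec[i] >= 0L) {
            inputIdx[[i]] <- integer(0)
            tts[[i]] <- clampVec[i]
            next
        }
        vars <- all.vars(net@rules[[i]])
        tt <- truthTable(net@rules[[i]], vars, maxInputs = 25L)
        inputIdx[[i]] <- match(vars, nodes) - 1L
        tts[[i]] <- as.integer(tt)
    }
    list(n = n, inputIdx = inputIdx, tts = tts, clampVec = clampVec)
}

new_attractor <- function(codes, nodes, basin = NA_real_) {
    i0 <- which.min(codes)
    codes <- c(codes[i0:length(codes)], codes[seq_len(i0 - 1L)])
    states <- t(vapply(codes, decodeState, integer(length(nodes)),
                       nodes = nodes))
    colnames(states) <- nodes
    new("Attractor", states = states, basinSize = basin)
}

#' Deterministic trajectory into an attractor
#'
#' Iterates the synchronous update map from `state` with visited-state cycle
#' detection and splits the run into a transient and its terminal cycle.
#'
#' @param net a [BooleanNetwork].
#' @param state start state (named or in node order).
#' @param clamps optional named 0/1 clamp vector; the start state is
#'   projected onto the clamps before the first step.
#' @param maxSteps step budget; the default `2^n` can never be exceeded by a
#'   deterministic finite system, so lower values are only useful to bound
#'   runaway inputs.  Exceeding the budget is an explicit error.
#' @return a [Trajectory].
#' @examples
#' net <- faChkrecNetwork()
#' tr <- simulateTrajectory(net, makeState(nodes(net), "ICL"))
#' period(tr@attractor)
#' @export
simulateTrajectory <- function(net, state, clamps = NULL,
                               maxSteps = 2^length(nodes(net))) {
    stopifnot(is(net, "BooleanNetwork"))
    if (maxSteps < 1) stop("maxSteps must be >= 1", call. = FALSE)
    v <- as_state_vector(state, net@nodes)
    cl <- check_clamps(clamps, net@nodes)
    comp <- compile_network(net, cl)
    res <- .bn_trajectory(comp$n, comp$inputIdx, comp$tts, comp$clampVec,
                          encodeState(v, net@nodes), maxSteps)
    att <- new_attractor(res$cycle, net@nodes)
    transient <- if (length(res$transient)) {
        m <- t(vapply(res$transient, decodeState, integer(length(net@nodes)),
                      nodes = net@nodes))
        colnames(m) <- net@nodes
        m
    } else {
        matrix(integer(0), 0, length(net@nodes),
               dimnames = list(NULL, net@nodes))
    }
    new("Trajectory", transient = transient, attractor = att)
}

#' Exhaustive attractor enumeration with basin sizes
#'
#' Builds the synchronous successor map over the whole (free-node) state
#' space and extracts all cycles of the resulting functional graph, so every
#' attractor reachable from the requested initial space is found and basin
#' sizes partition that space exactly.  With clamps, initial states
#' conflicting with a clamp are projected onto it, i.e. "all initial states"
#' means all assignments of the free nodes.
#'
#' @param net a [BooleanNetwork] with at most 25 free (unclamped) nodes:
#'   above that the engine refuses rather than silently subsampling.
#' @param clamps optional named 0/1 vector fixing nodes throughout the run.
#' @param initialStates `"all"` (default) or an explicit list/matrix of start
#'   states (rows or list elements, named or in node order).
#' @param forceOn character vector of nodes forced to 1 at `t = 0` only
#'   (pulse-style start ensembles); ignored when `initialStates` is
#'   explicit.
#' @return an [AttractorSet]; attractors are canonically rotated and sorted
#'   by their smallest state code, so repeated runs are identical.
#' @examples
#' toy <- parseRules(c("A <- B", "B <- A"))
#' length(enumerateAttractors(toy))  # 3: two fixed points and a 2-cycle
#' @export
enumerateAttractors <- function(net, clamps = NULL, initialStates = "all",
                                forceOn = character(0)) {
    stopifnot(is(net, "BooleanNetwork"))
    nodes <- net@nodes
    cl <- check_clamps(clamps, nodes)
    nFree <- length(nodes) - length(cl)
    if (nFree > 25L)
        stop("state space too large for exhaustive enumeration (2^", nFree,
             " free states); clamp nodes or supply explicit initialStates",
             call. = FALSE)
    bad <- setdiff(forceOn, nodes)
    if (length(bad))
        stop("unknown node(s) in forceOn: ", paste(bad, collapse = ", "),
             call. = FALSE)
    if (length(forceOn) && any(cl[intersect(forceOn, names(cl))] == 0L))
        stop("forceOn node is clamped to 0", call. = FALSE)

    comp <- compile_network(net, cl)
    explicit <- NULL
    if (!identical(initialStates, "all")) {
        if (is.matrix(initialStates)) {
            explicit <- apply(initialStates, 1L, encodeState, nodes = nodes)
        } else if (is.list(initialStates)) {
            explicit <- vapply(initialStates, encodeState, numeric(1),
                               nodes = nodes)
        } else if (is.numeric(initialStates)) {
            explicit <- as.numeric(initialStates)  # pre-encoded codes
        } else {
            stop("initialStates must be \"all\", a matrix, a list, or codes",
                 call. = FALSE)
        }
    }
    fixedOn <- match(forceOn, nodes) - 1L
    res <- .bn_attractors(comp$n, comp$inputIdx, comp$tts, comp$clampVec,
                          as.numeric(fixedOn), explicit)
    atts <- mapply(function(cyc, b) new_attractor(cyc, nodes, basin = b),
                   res$cycles, res$basin, SIMPLIFY = FALSE)
    ord <- order(vapply(atts, function(a)
        encodeState(a@states[1L, ], nodes), numeric(1)))
    new("AttractorSet", attractors = atts[ord], nodes = nodes,
        clamps = cl, initialSpaceSize = res$nStarts)
}
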