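# Mutant and damage-exposure experiments.  Null and constitutive-activation
# mutants are clamps (node fixed at 0 / 1 at every step); interaction
# removal substitutes the source node by the constant 0 inside the target's
# rule; DNA-damage exposure is either a pulse (damage node set to 1 at t = 0
# only) or persistent (damage node clamped to 1), matching how the chemical
# inhibitors used against CHKREC components map onto node knockouts.

#' Construct a perturbation
#'
#' @param clamps named 0/1 vector of nodes fixed for the whole simulation.
#' @param removedEdges two-column character matrix (or data.frame with
#'   columns `source`, `target`) of interactions to remove.
#' @param label text label used in reports.
#' @return a [Perturbation].
#' @export
perturbation <- function(clamps = integer(0), removedEdges = NULL, label = "") {
    cl <- if (length(clamps)) {
        v <- as.integer(clamps)
        names(v) <- names(clamps)
        v
    } else integer(0)
    re <- if (is.null(removedEdges)) {
        matrix(character(0), 0, 2, dimnames = list(NULL, c("source", "target")))
    } else {
        m <- as.matrix(removedEdges[, c("source", "target"), drop = FALSE])
        colnames(m) <- c("source", "target")
        m
    }
    new("Perturbation", clamps = cl, removedEdges = re, label = label)
}

#' Null and constitutive-activation mutants
#'
#' `knockout(node)` clamps the node at 0 (null mutant); `constitutive(node)`
#' clamps it at 1 (constitutive activation).  Clamping a damage node at 1 is
#' identical to the persistent-exposure protocol on that node.
#'
#' @param node node name.
#' @return a [Perturbation] with a single clamp.
#' @examples
#' knockout("FAcore")
#' @export
knockout <- function(node) {
    stopifnot(is.character(node), length(node) == 1L)
    perturbation(clamps = stats::setNames(0L, node),
                 label = paste0(node, "-KO"))
}

#' @rdname knockout
#' @export
constitutive <- function(node) {
    stopifnot(is.character(node), length(node) == 1L)
    perturbation(clamps = stats::setNames(1L, node),
                 label = paste0(node, "-ON"))
}

#' Combine perturbations (e.g. double mutants)
#'
#' @param ... [Perturbation] objects.
#' @return a single [Perturbation]; clamping the same node twice is an
#'   error.
#' @export
combinePerturbations <- function(...) {
    ps <- list(...)
    stopifnot(all(vapply(ps, is, logical(1), class2 = "Perturbation")))
    cl <- unlist(lapply(ps, function(p) p@clamps))
    if (anyDuplicated(names(cl)))
        stop("perturbations clamp the same node(s): ",
             paste(unique(names(cl)[duplicated(names(cl))]), collapse = ", "),
             call. = FALSE)
    re <- do.call(rbind, lapply(ps, function(p) p@removedEdges))
    labs <- vapply(ps, function(p) p@label, character(1))
    perturbation(clamps = cl, removedEdges = re,
                 label = paste(labs[nzchar(labs)], collapse = " x "))
}

#' Remove a regulatory interaction from a network
#'
#' Excises every literal occurrence of `source` from `target`'s rule, so the
#' rule loses that regulator: activating occurrences become inert (the rest
#' of their conjunction survives) and negated occurrences become permissive
#' (the inhibition term vanishes).  A rule consisting solely of the removed
#' regulator becomes the constant 0.  No other rule changes.
#'
#' @param net a [BooleanNetwork].
#' @param source,target node names; `source` must occur in `target`'s rule.
#' @return a new [BooleanNetwork].
#' @examples
#' net <- removeInteraction(faChkrecNetwork(), "NUC1", "ICL")
#' rules(net)[["ICL"]]  # ICL & !NUC2
#' @export
removeInteraction <- function(net, source, target) {
    stopifnot(is(net, "BooleanNetwork"))
    if (!target %in% net@nodes)
        stop("unknown target node '", target, "'", call. = FALSE)
    if (!source %in% all.vars(net@rules[[target]]))
        stop("no interaction ", source, " -> ", target,
             " in the model (source absent from the target's rule)",
             call. = FALSE)
    res <- excise_var(net@rules[[target]], source)
    net@rules[[target]] <- if (is.null(res)) 0L else res
    net
}

# Literal excision: returns NULL when the whole (sub)expression reduces to
# the removed regulator; binary operators drop a vanished argument.
excise_var <- function(e, var) {
    if (is.symbol(e)) {
        if (identical(as.character(e), var)) return(NULL)
        return(e)
    }
    if (is.numeric(e)) return(e)
    op <- as.character(e[[1L]])
    if (op == "(") {
        inner <- excise_var(e[[2L]], var)
        return(inner)
    }
    if (op == "!") {
        a <- excise_var(e[[2L]], var)
        if (is.null(a)) return(NULL)
        return(call("!", a))
    }
    a <- excise_var(e[[2L]], var)
    b <- excise_var(e[[3L]], var)
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    call(op, a, b)
}

#' Remove a set of interactions (e.g. the inferred-interaction list)
#'
#' @param net a [BooleanNetwork].
#' @param edges data.frame or matrix with columns `source`, `target`;
#'   defaults to the full inferred-interaction table of the built-in model.
#' @return a new [BooleanNetwork] with all listed edges removed.
#' @export
removeInteractions <- function(net, edges = novelInteractions()) {
    edges <- as.data.frame(edges)
    for (i in seq_len(nrow(edges)))
        net <- removeInteraction(net, edges$source[i], edges$target[i])
    net
}

apply_perturbation_rules <- function(net, pert) {
    if (nrow(pert@removedEdges)) {
        for (i in seq_len(nrow(pert@removedEdges)))
            net <- removeInteraction(net, pert@removedEdges[i, "source"],
                                     pert@removedEdges[i, "target"])
    }
    net
}

#' Specify a DNA-damage exposure protocol
#'
#' @param exposure `"pulse"` (damage node(s) set to 1 at the initial state
#'   only), `"persistent"` (damage node(s) clamped to 1), or `"none"`.
#' @param damageNodes nodes carrying the exposure; default `"ICL"`.
#' @param start `"canonical"` (single start: all nodes 0 except the exposed
#'   damage nodes, i.e. damage hitting an unstressed cell) or `"all"`
#'   (ensemble over all initial states; for a pulse the pulsed nodes are
#'   forced to 1 at `t = 0`, for persistent exposure the starts are
#'   projected onto the damage clamp).  Defaults to `"canonical"` for pulse
#'   and persistent exposure — the single trajectory from damage onset —
#'   and `"all"` for `"none"`.
#' @return protocol spec (list) accepted by [runProtocol()].
#' @export
protocolSpec <- function(exposure = c("pulse", "persistent", "none"),
                         damageNodes = "ICL", start = NULL) {
    exposure <- match.arg(exposure)
    if (is.null(start)) start <- if (exposure == "none") "all" else "canonical"
    start <- match.arg(start, c("canonical", "all"))
    structure(list(exposure = exposure, damageNodes = damageNodes,
                   start = start), class = "bn_protocol")
}

#' Run a mutant under a damage-exposure protocol
#'
#' Applies the perturbation's edge removals to the rules and its clamps to
#' the dynamics, adds the protocol's damage clamps (persistent exposure),
#' and either follows the single canonical trajectory (pulse from the
#' all-zero state with the pulsed nodes on) or exhaustively enumerates
#' attractors over the requested initial space.  Every attractor is
#' classified into a cell-fate category.
#'
#' @param net a [BooleanNetwork].
#' @param pert a [Perturbation] (default: none).
#' @param protocol a spec from [protocolSpec()].
#' @return list with components `attractors` (an [AttractorSet]),
#'   `phenotypes` (data.frame from [classifyAttractors()]), and — for a
#'   canonical pulse — `trajectory` (the [Trajectory]).
#' @examples
#' wt <- runProtocol(faChkrecNetwork(), protocol = protocolSpec("pulse"))
#' wt$phenotypes$category  # "CCP"
#' @export
runProtocol <- function(net, pert = perturbation(),
                        protocol = protocolSpec("pulse")) {
    stopifnot(is(net, "BooleanNetwork"), is(pert, "Perturbation"),
              inherits(protocol, "bn_protocol"))
    net2 <- apply_perturbation_rules(net, pert)
    clamps <- pert@clamps
    # a damage node knocked out by the perturbation cannot carry the lesion:
    # the exposure on it is vacuous, so the screen over *all* null mutants
    # (including the damage node itself) stays complete
    dmg <- setdiff(protocol$damageNodes,
                   names(clamps)[clamps == 0L])
    if (protocol$exposure == "persistent") {
        add <- setdiff(dmg, names(clamps))
        clamps <- c(clamps, stats::setNames(rep(1L, length(add)), add))
    }
    traj <- NULL
    if (protocol$start == "canonical") {
        s0 <- makeState(net2@nodes,
                        on = if (protocol$exposure == "none") character(0)
                             else dmg)
        if (length(clamps)) {
            s0[names(clamps)] <- clamps
        }
        traj <- simulateTrajectory(net2, s0, clamps = clamps)
        atts <- new("AttractorSet", attractors = list(traj@attractor),
                    nodes = net2@nodes,
                    clamps = if (length(clamps)) clamps else integer(0),
                    initialSpaceSize = 1)
    } else {
        forceOn <- if (protocol$exposure == "pulse") dmg else character(0)
        atts <- enumerateAttractors(net2, clamps = clamps, forceOn = forceOn)
    }
    signature <- unique(c(fa_division_nodes, fa_damage_nodes, fa_arrest_nodes))
    out <- list(attractors = atts,
                phenotypes = if (all(signature %in% net2@nodes))
                    classifyAttractors(atts))
    if (!is.null(traj)) out$trajectory <- traj
    out
}

#' Double-mutant screen over a candidate node list
#'
#' Runs `background + knockout(candidate)` under the given protocol for each
#' candidate; no candidate is skipped, and the result is invariant to
#' candidate order (rows are reported in the given order, one block per
#' candidate and attractor).
#'
#' @param net a [BooleanNetwork].
#' @param background a [Perturbation] (e.g. `knockout("FAcore")`).
#' @param candidates character vector of nodes to knock out on top of the
#'   background; must not overlap the background's clamped nodes.
#' @param protocol a [protocolSpec()].
#' @return data.frame with one row per (candidate, attractor): columns
#'   `candidate`, `attractor`, `period`, `basinSize`, `category`,
#'   `cycbEverOn`, `damageEverOn`.
#' @examples
#' doubleMutantScreen(faChkrecNetwork(), knockout("FAcore"),
#'                    c("WIP1", "PLK1"),
#'                    protocolSpec("persistent"))
#' @export
doubleMutantScreen <- function(net, background, candidates,
                               protocol = protocolSpec("persistent")) {
    stopifnot(is(net, "BooleanNetwork"), is(background, "Perturbation"))
    overlap <- intersect(candidates, names(background@clamps))
    if (length(overlap))
        stop("candidate(s) overlap the background clamps: ",
             paste(overlap, collapse = ", "), call. = FALSE)
    bad <- setdiff(candidates, net@nodes)
    if (length(bad))
        stop("unknown candidate node(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    rows <- lapply(candidates, function(cand) {
        res <- runProtocol(net, combinePerturbations(background, knockout(cand)),
                           protocol)
        ph <- res$phenotypes
        if (!nrow(ph)) return(NULL)
        data.frame(candidate = cand, attractor = ph$attractor,
                   period = ph$period, basinSize = ph$basinSize,
                   category = ph$category, cycbEverOn = ph$cycbEverOn,
                   damageEverOn = ph$damageEverOn)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
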