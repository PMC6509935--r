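#' @import methods
NULL

#' BooleanNetwork: a set of synchronous Boolean update rules
#'
#' A `BooleanNetwork` holds one Boolean update rule per node.  Rules are
#' stored as R language objects over the operators `!`, `&`, `|`, node-name
#' symbols, and the constants `0`/`1`.  The node order is part of the object:
#' state encodings (bit `i` of the integer code is node `i`) depend on it and
#' it never changes silently.
#'
#' @slot nodes character vector of node names; defines bit positions of the
#'   integer state encoding (node 1 is the least significant bit).
#' @slot rules named list of update expressions, exactly one per node and in
#'   node order.  Every variable referenced by any rule must be a declared
#'   node (closure).
#' @slot metadata free-form list; the built-in model stores node annotations
#'   (`category`, `description`) and the inferred-interaction table here.
#'
#' @seealso [parseRules()], [faChkrecNetwork()], [enumerateAttractors()]
#' @export
setClass("BooleanNetwork",
         slots = c(nodes = "character",
                   rules = "list",
                   metadata = "list"),
         prototype = prototype(nodes = character(0),
                               rules = list(),
                               metadata = list()))

setValidity("BooleanNetwork", function(object) {
    msgs <- character(0)
    n <- object@nodes
    if (anyDuplicated(n))
        msgs <- c(msgs, sprintf("duplicate node names: %s",
                                paste(unique(n[duplicated(n)]), collapse = ", ")))
    if (any(!nzchar(n)))
        msgs <- c(msgs, "empty node name")
    if (!identical(names(object@rules), n))
        msgs <- c(msgs, "names(rules) must equal nodes (one rule per node, in order)")
    bad <- !vapply(object@rules, is_bool_expr, logical(1))
    if (any(bad))
        msgs <- c(msgs, sprintf("rules for %s are not Boolean expressions",
                                paste(n[bad], collapse = ", ")))
    if (!any(bad) && length(object@rules)) {
        used <- unique(unlist(lapply(object@rules, all.vars)))
        undecl <- setdiff(used, n)
        if (length(undecl))
            msgs <- c(msgs, sprintf("rules reference undeclared node(s): %s",
                                    paste(undecl, collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' Attractor: a cycle of states closed under the synchronous update map
#'
#' States are stored as a 0/1 integer matrix with one row per cycle state
#' (period = number of rows) and one column per node, rotated so that the
#' smallest integer-encoded state comes first (canonical rotation: attractor
#' identity is this tuple).  A fixed point has period 1.
#'
#' @slot states integer 0/1 matrix, `period x n`, columns named by node.
#' @slot basinSize number of initial states whose trajectory reaches this
#'   attractor (`NA_real_` when basins were not computed).
#' @export
setClass("Attractor",
         slots = c(states = "matrix", basinSize = "numeric"),
         prototype = prototype(states = matrix(integer(0), 0, 0),
                               basinSize = NA_real_))

setValidity("Attractor", function(object) {
    s <- object@states
    if (nrow(s) < 1L) return("an attractor has period >= 1")
    if (is.null(colnames(s))) return("state columns must be named by node")
    if (!all(s %in% c(0L, 1L))) return("states must be 0/1")
    codes <- apply(s, 1L, function(r) sum(r * 2^(seq_along(r) - 1)))
    if (anyDuplicated(codes)) return("cycle states must be pairwise distinct")
    if (length(codes) > 1L && which.min(codes) != 1L)
        return("states must be rotated so the smallest encoded state is first")
    if (length(object@basinSize) != 1L) return("basinSize must be length 1")
    TRUE
})

#' AttractorSet: all attractors reached from an initial-state space
#'
#' @slot attractors list of [Attractor] objects, sorted by the integer code
#'   of their canonical first state (stable, deterministic order).
#' @slot nodes node order of the underlying network.
#' @slot clamps named integer vector of clamped nodes (values 0/1); empty for
#'   the free network.  Initial states conflicting with the clamps were
#'   projected onto them, so basin sizes partition the projected space.
#' @slot initialSpaceSize number of initial states simulated; basin sizes sum
#'   to this value.
#' @export
setClass("AttractorSet",
         slots = c(attractors = "list",
                   nodes = "character",
                   clamps = "integer",
                   initialSpaceSize = "numeric"),
         prototype = prototype(attractors = list(), nodes = character(0),
                               clamps = integer(0), initialSpaceSize = NA_real_))

setValidity("AttractorSet", function(object) {
    ok <- vapply(object@attractors, is, logical(1), class2 = "Attractor")
    if (!all(ok)) return("attractors must be a list of Attractor objects")
    bad <- vapply(object@attractors,
                  function(a) !identical(colnames(a@states), object@nodes),
                  logical(1))
    if (any(bad)) return("attractor state columns must match the node order")
    TRUE
})

#' Trajectory: a deterministic run into an attractor
#'
#' @slot transient integer 0/1 matrix of the pre-cycle states in visit order
#'   (the start state first; zero rows when the start already lies on the
#'   cycle).  Transient states are pairwise distinct and none belongs to the
#'   attractor.
#' @slot attractor the terminal [Attractor].
#' @export
setClass("Trajectory",
         slots = c(transient = "matrix", attractor = "Attractor"))

#' Perturbation: a mutant condition
#'
#' Clamps model null (0) and constitutive-activation (1) mutants: a clamped
#' node keeps its value at every update step regardless of its rule.
#' Removed interactions substitute the source node by the constant 0 inside
#' the target's rule.
#'
#' @slot clamps named integer vector (values 0/1); a node appears at most
#'   once.
#' @slot removedEdges character matrix with columns `source`, `target`.
#' @slot label free-text label used in reports.
#' @export
setClass("Perturbation",
         slots = c(clamps = "integer", removedEdges = "matrix",
                   label = "character"),
         prototype = prototype(clamps = integer(0),
                               removedEdges = matrix(character(0), 0, 2,
                                   dimnames = list(NULL, c("source", "target"))),
                               label = ""))

setValidity("Perturbation", function(object) {
    cl <- object@clamps
    if (length(cl) && (is.null(names(cl)) || any(!nzchar(names(cl)))))
        return("clamps must be a named vector")
    if (anyDuplicated(names(cl)))
        return("a node appears more than once in clamps")
    if (length(cl) && !all(cl %in% c(0L, 1L)))
        return("clamp values must be 0 or 1")
    if (ncol(object@removedEdges) != 2L)
        return("removedEdges must have two columns (source, target)")
    TRUE
})

#' PhenotypeCall: classification of an attractor into a cell-fate category
#'
#' Categories follow the activity signatures of the FA-CHKREC model: `CCP`
#' (cell-cycle progression: the four division-promoter nodes ON and every
#' other node OFF in every cycle state), `CCP_DDA` (progression with DNA
#' damage adaptation: CycB-CDK1 active together with a damage node),
#' `CCA` (cell-cycle arrest: CycB-CDK1 never active while damage and arrest
#' nodes are), and `OTHER`.
#'
#' @slot category one of `"CCP"`, `"CCP_DDA"`, `"CCA"`, `"OTHER"`.
#' @slot evidence named logical vector of the individual criteria backing the
#'   call (`divisionAllOn`, `othersAllOff`, `cycbEverOn`, `damageEverOn`,
#'   `arrestEverOn`).
#' @export
setClass("PhenotypeCall",
         slots = c(category = "character", evidence = "logical"))

setValidity("PhenotypeCall", function(object) {
    if (length(object@category) != 1L ||
        !object@category %in% c("CCP", "CCP_DDA", "CCA", "OTHER"))
        return("category must be one of CCP, CCP_DDA, CCA, OTHER")
    TRUE
})
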