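# Cell-fate classification of attractors.  "Active in a cyclic attractor"
# means ON in at least one cycle state: the cyclic arrest attractors show
# recurrent, not constant, activation of the FA pathway and the checkpoint.
# The decision rule is ordered -- strict CCP is tested before its
# damage-carrying variant (CCP_DDA), which is tested before CCA -- so every
# attractor receives exactly one category.

fa_division_nodes <- c("CDK1-AurA", "PLK1", "CDC25", "CycB-CDK1")
fa_damage_nodes <- c("ICL", "DSB", "R-DSB")
fa_arrest_nodes <- c("ATM", "ATR", "p53", "p21", "WEE1", "MYT1")

#' Classify an attractor into a cell-fate category
#'
#' Ordered decision rule over the activity signature of the cycle:
#' \enumerate{
#'   \item `CCP` — in every cycle state the four cell-division promoter
#'     nodes (CDK1-AurA, PLK1, CDC25, CycB-CDK1) are ON and every other node
#'     is OFF;
#'   \item `CCP_DDA` — CycB-CDK1 is ON in at least one cycle state and at
#'     least one DNA-damage node (ICL, DSB, R-DSB) is ON in at least one
#'     cycle state: division despite unrepaired damage (DNA damage
#'     adaptation);
#'   \item `CCA` — CycB-CDK1 is OFF in every cycle state while at least one
#'     damage node and at least one arrest node (ATM, ATR, p53, p21, WEE1,
#'     MYT1) are ON somewhere in the cycle: checkpoint-enforced arrest;
#'   \item `OTHER` — anything else.
#' }
#'
#' @param att an [Attractor] over a model containing the signature nodes.
#' @param divisionNodes,damageNodes,arrestNodes signature node sets; the
#'   defaults are the FA-CHKREC sets above.
#' @param mitoticNode the single node whose activation commits the cell to
#'   division (default `"CycB-CDK1"`, the mitosis-promoting factor).
#' @return a [PhenotypeCall] carrying the category and the per-criterion
#'   evidence booleans.
#' @examples
#' net <- faChkrecNetwork()
#' ccp <- makeState(nodes(net), c("CDK1-AurA", "PLK1", "CDC25", "CycB-CDK1"))
#' att <- simulateTrajectory(net, ccp)@attractor
#' category(classifyAttractor(att))  # "CCP"
#' @export
classifyAttractor <- function(att,
                              divisionNodes = fa_division_nodes,
                              damageNodes = fa_damage_nodes,
                              arrestNodes = fa_arrest_nodes,
                              mitoticNode = "CycB-CDK1") {
    stopifnot(is(att, "Attractor"))
    s <- att@states
    need <- unique(c(divisionNodes, damageNodes, arrestNodes, mitoticNode))
    miss <- setdiff(need, colnames(s))
    if (length(miss))
        stop("signature node(s) absent from the model: ",
             paste(miss, collapse = ", "), call. = FALSE)
    others <- setdiff(colnames(s), divisionNodes)
    divisionAllOn <- all(s[, divisionNodes] == 1L)
    othersAllOff <- all(s[, others] == 0L)
    cycbEverOn <- any(s[, mitoticNode] == 1L)
    damageEverOn <- any(s[, damageNodes] == 1L)
    arrestEverOn <- any(s[, arrestNodes] == 1L)
    category <-
        if (divisionAllOn && othersAllOff) "CCP"
        else if (cycbEverOn && damageEverOn) "CCP_DDA"
        else if (!cycbEverOn && damageEverOn && arrestEverOn) "CCA"
        else "OTHER"
    new("PhenotypeCall", category = category,
        evidence = c(divisionAllOn = divisionAllOn,
                     othersAllOff = othersAllOff,
                     cycbEverOn = cycbEverOn,
                     damageEverOn = damageEverOn,
                     arrestEverOn = arrestEverOn))
}

#' Classify every attractor of a set
#'
#' @param atts an [AttractorSet] (or plain list of [Attractor]s).
#' @param ... signature node sets passed to [classifyAttractor()].
#' @return data.frame with one row per attractor (`attractor`, `period`,
#'   `basinSize`, `category`, and the evidence booleans), with the per-
#'   category counts attached as the `"counts"` attribute (named integer
#'   vector over CCP, CCP_DDA, CCA, OTHER).
#' @export
classifyAttractors <- function(atts, ...) {
    lst <- if (is(atts, "AttractorSet")) atts@attractors else atts
    cats <- c("CCP", "CCP_DDA", "CCA", "OTHER")
    if (!length(lst)) {
        out <- data.frame(attractor = integer(0), period = integer(0),
                          basinSize = numeric(0), category = character(0),
                          divisionAllOn = logical(0), othersAllOff = logical(0),
                          cycbEverOn = logical(0), damageEverOn = logical(0),
                          arrestEverOn = logical(0))
        attr(out, "counts") <- stats::setNames(integer(4), cats)
        return(out)
    }
    rows <- lapply(seq_along(lst), function(i) {
        call <- classifyAttractor(lst[[i]], ...)
        ev <- as.list(call@evidence)
        data.frame(attractor = i, period = nrow(lst[[i]]@states),
                   basinSize = lst[[i]]@basinSize, category = call@category,
                   ev, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "counts") <- stats::setNames(
        vapply(cats, function(k) sum(out$category == k), integer(1)), cats)
    out
}
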