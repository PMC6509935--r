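#' Node names of a Boolean network
#'
#' @param x a [BooleanNetwork], [AttractorSet] or [Attractor].
#' @return character vector of node names in encoding order.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Update rules of a Boolean network
#'
#' @param x a [BooleanNetwork].
#' @return named list of update expressions, in node order.
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' Period of an attractor (number of cycle states; 1 for a fixed point)
#'
#' @param x an [Attractor].
#' @return integer period.
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' Basin size of an attractor
#'
#' @param x an [Attractor].
#' @return number of initial states reaching `x`, or `NA` if not computed.
#' @export
setGeneric("basinSize", function(x) standardGeneric("basinSize"))

#' Cycle states of an attractor
#'
#' @param x an [Attractor] or [Trajectory].
#' @return 0/1 integer matrix, one row per state.
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' Phenotype category of a classification call
#'
#' @param x a [PhenotypeCall].
#' @return single character: `"CCP"`, `"CCP_DDA"`, `"CCA"` or `"OTHER"`.
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' Per-criterion evidence behind a phenotype call
#'
#' @param x a [PhenotypeCall].
#' @return named logical vector.
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
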