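#' Accessors for CloneClub classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param object a CloneClub S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nClones", function(object) standardGeneric("nClones"))
#' @rdname accessors
#' @export
setGeneric("cloneInfo", function(object) standardGeneric("cloneInfo"))
#' @rdname accessors
#' @export
setGeneric("cloneCells", function(object) standardGeneric("cloneCells"))
#' @rdname accessors
#' @export
setGeneric("clubLabels", function(object) standardGeneric("clubLabels"))
#' @rdname accessors
#' @export
setGeneric("aCoefficients", function(object) standardGeneric("aCoefficients"))
#' @rdname accessors
#' @export
setGeneric("dimWeights", function(object) standardGeneric("dimWeights"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("residualMatrix", function(object) standardGeneric("residualMatrix"))
#' @rdname accessors
#' @export
setGeneric("neighborMatrix", function(object) standardGeneric("neighborMatrix"))
#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(object) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setGeneric("runObjectives", function(object) standardGeneric("runObjectives"))
#' @rdname accessors
#' @export
setGeneric("encodingTree", function(object) standardGeneric("encodingTree"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("vertexDegrees", function(object) standardGeneric("vertexDegrees"))

#' @rdname accessors
#' @export
setMethod("nClones", "CloneSet", function(object) nrow(object@clones))
#' @rdname accessors
#' @export
setMethod("cloneInfo", "CloneSet", function(object) object@clones)
#' @rdname accessors
#' @export
setMethod("cloneCells", "CloneSet", function(object) object@cellRows)

#' @rdname accessors
#' @export
setMethod("aCoefficients", "LocalHarmonyFit", function(object) object@A)
#' @rdname accessors
#' @export
setMethod("dimWeights", "LocalHarmonyFit", function(object) object@W)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "LocalHarmonyFit", function(object) object@objectiveTrace)
#' @rdname accessors
#' @export
setMethod("residualMatrix", "LocalHarmonyFit", function(object) object@delta)
#' @rdname accessors
#' @export
setMethod("neighborMatrix", "LocalHarmonyFit", function(object) object@neighbors)

#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "CloneGraph", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("vertexDegrees", "CloneGraph", function(object) object@degrees)

#' @rdname accessors
#' @export
setMethod("clubLabels", "EncodingTree", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("nClones", "ClubResult", function(object) nClones(object@cloneSet))
#' @rdname accessors
#' @export
setMethod("cloneInfo", "ClubResult", function(object) cloneInfo(object@cloneSet))
#' @rdname accessors
#' @export
setMethod("clubLabels", "ClubResult", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ClubResult", function(object) object@consensus)
#' @rdname accessors
#' @export
setMethod("runObjectives", "ClubResult", function(object) object@runObjectives)
#' @rdname accessors
#' @export
setMethod("encodingTree", "ClubResult", function(object) object@tree)
#' @rdname accessors
#' @export
setMethod("aCoefficients", "ClubResult", function(object) object@bestFit@A)
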