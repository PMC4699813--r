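#' @rdname PriorNetwork-accessors
#' @export
setGeneric("speciesInfo", function(object) standardGeneric("speciesInfo"))

#' @rdname PriorNetwork-accessors
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname gates
#' @export
setGeneric("gates", function(object) standardGeneric("gates"))

#' @rdname PriorNetwork-accessors
#' @export
setGeneric("network", function(object) standardGeneric("network"))

#' @rdname ExperimentDesign
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname normalizeFoldChanges
#' @export
setGeneric("scheme", function(object) standardGeneric("scheme"))

#' @rdname fitModelFamily
#' @export
setGeneric("consensus", function(object) standardGeneric("consensus"))

#' @rdname fitModelFamily
#' @export
setGeneric("familyMSE", function(object, reduced = TRUE)
    standardGeneric("familyMSE"))

#' @rdname simulateStates
#' @export
setGeneric("simulateStates", function(model, design, ...)
    standardGeneric("simulateStates"))
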