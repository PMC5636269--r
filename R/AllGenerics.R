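#' @name tilsim-generics
#' @title Generics for tilsim containers
#' @description Accessor and computation generics shared across the
#'   simulation and analysis classes.
#' @param object,x an object.
#' @param ... passed to methods.
NULL

#' @rdname tilsim-generics
#' @export
setGeneric("timeSeries", function(object, ...) standardGeneric("timeSeries"))

#' @rdname tilsim-generics
#' @export
setGeneric("eventLog", function(object, ...) standardGeneric("eventLog"))

#' @rdname tilsim-generics
#' @export
setGeneric("snapshots", function(object, ...) standardGeneric("snapshots"))

#' @rdname tilsim-generics
#' @export
setGeneric("agents", function(object, ...) standardGeneric("agents"))

#' @rdname tilsim-generics
#' @export
setGeneric("occupancy", function(object, ...) standardGeneric("occupancy"))

#' @rdname tilsim-generics
#' @export
setGeneric("cytokine", function(object, ...) standardGeneric("cytokine"))

#' @rdname tilsim-generics
#' @export
setGeneric("entryVoxels", function(object, ...) standardGeneric("entryVoxels"))

#' @rdname tilsim-generics
#' @export
setGeneric("tumorRegion", function(x, ...) standardGeneric("tumorRegion"))

#' @rdname tilsim-generics
#' @export
setGeneric("distanceMap", function(x, ...) standardGeneric("distanceMap"))
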