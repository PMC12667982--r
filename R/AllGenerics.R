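#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequenceId", function(object) standardGeneric("sequenceId"))

#' @rdname accessors
#' @export
setGeneric("repeatAnchors", function(object) standardGeneric("repeatAnchors"))

#' @rdname accessors
#' @export
setGeneric("nRepeats", function(object) standardGeneric("nRepeats"))

#' @rdname accessors
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("runLabels", function(object) standardGeneric("runLabels"))

#' @rdname accessors
#' @export
setGeneric("nRuns", function(object) standardGeneric("nRuns"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("correlationMatrix",
           function(object) standardGeneric("correlationMatrix"))

#' @rdname accessors
#' @export
setGeneric("phases", function(object) standardGeneric("phases"))

#' @rdname accessors
#' @export
setGeneric("wrapSites", function(object) standardGeneric("wrapSites"))
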