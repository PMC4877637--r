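#' Accessors for ScreenBundle slots
#'
#' Accessor generics for the components of a \code{\link{ScreenBundle}} and
#' a \code{\link{ScreenResult}}; user code should use these rather than
#' \code{@} slot access.
#'
#' @param x a \code{ScreenBundle} or \code{ScreenResult}
#' @return the requested component (see the class documentation).
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
setGeneric("tssAnnotation", function(x) standardGeneric("tssAnnotation"))
#' @rdname bundle-accessors
#' @export
setMethod("tssAnnotation", "ScreenBundle", function(x) x@tss)

#' @rdname bundle-accessors
#' @export
setGeneric("cgiIntervals", function(x) standardGeneric("cgiIntervals"))
#' @rdname bundle-accessors
#' @export
setMethod("cgiIntervals", "ScreenBundle", function(x) x@cgi)

#' @rdname bundle-accessors
#' @export
setGeneric("peakSets", function(x) standardGeneric("peakSets"))
#' @rdname bundle-accessors
#' @export
setMethod("peakSets", "ScreenBundle", function(x) x@peaks)

#' @rdname bundle-accessors
#' @export
setGeneric("cpgCalls", function(x) standardGeneric("cpgCalls"))
#' @rdname bundle-accessors
#' @export
setMethod("cpgCalls", "ScreenBundle", function(x) x@cpg)

#' @rdname bundle-accessors
#' @export
setGeneric("expressionTable", function(x) standardGeneric("expressionTable"))
#' @rdname bundle-accessors
#' @export
setMethod("expressionTable", "ScreenBundle", function(x) x@expression)

#' @rdname bundle-accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname bundle-accessors
#' @export
setMethod("clinicalTable", "ScreenBundle", function(x) x@clinical)

#' @rdname bundle-accessors
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))
#' @rdname bundle-accessors
#' @export
setMethod("truthSet", "ScreenBundle", function(x) x@truth)

#' @rdname bundle-accessors
#' @export
setGeneric("bundleConfig", function(x) standardGeneric("bundleConfig"))
#' @rdname bundle-accessors
#' @export
setMethod("bundleConfig", "ScreenBundle", function(x) x@config)

#' @rdname bundle-accessors
#' @export
setGeneric("screenRecords", function(x) standardGeneric("screenRecords"))
#' @rdname bundle-accessors
#' @export
setMethod("screenRecords", "ScreenResult", function(x) x@records)

#' @rdname bundle-accessors
#' @export
setGeneric("funnelTable", function(x) standardGeneric("funnelTable"))
#' @rdname bundle-accessors
#' @export
setMethod("funnelTable", "ScreenResult", function(x) x@funnel)

#' @rdname bundle-accessors
#' @export
setGeneric("k4StatusTable", function(x) standardGeneric("k4StatusTable"))
#' @rdname bundle-accessors
#' @export
setMethod("k4StatusTable", "ScreenResult", function(x) x@k4Status)

#' @rdname bundle-accessors
#' @export
setGeneric("geneHits", function(x) standardGeneric("geneHits"))
#' @rdname bundle-accessors
#' @export
setMethod("geneHits", "ScreenResult", function(x) x@geneHits)

#' Accessors for SurvivalCutoff results
#'
#' @param x a \code{SurvivalCutoff}
#' @return the requested component.
#' @name cutoff-accessors
NULL

#' @rdname cutoff-accessors
#' @export
setGeneric("bestCutoff", function(x) standardGeneric("bestCutoff"))
#' @rdname cutoff-accessors
#' @export
setMethod("bestCutoff", "SurvivalCutoff", function(x) x@bestCutoff)

#' @rdname cutoff-accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
#' @rdname cutoff-accessors
#' @export
setMethod("scanTable", "SurvivalCutoff", function(x) x@scan)

#' @rdname cutoff-accessors
#' @export
setGeneric("kmSupport", function(x) standardGeneric("kmSupport"))
#' @rdname cutoff-accessors
#' @export
setMethod("kmSupport", "SurvivalCutoff", function(x) x@km)
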