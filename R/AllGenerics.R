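#' @rdname PafAlignments-class
#' @param x,object a `PafAlignments` object.
#' @export
setGeneric("pafRecords", function(x) standardGeneric("pafRecords"))

#' @rdname PbdResult-class
#' @param x,object a `PbdResult`.
#' @export
setGeneric("coverageWindows", function(x) standardGeneric("coverageWindows"))

#' @rdname PbdResult-class
#' @export
setGeneric("flaggedRegions", function(x) standardGeneric("flaggedRegions"))

#' @rdname PbdResult-class
#' @export
setGeneric("meanDepth", function(x) standardGeneric("meanDepth"))

#' @rdname TelomereCensus-class
#' @param x,object a `TelomereCensus`.
#' @export
setGeneric("telomereCalls", function(x) standardGeneric("telomereCalls"))

#' @rdname SimGenome-class
#' @param x,object a `SimGenome` or `CorruptedAssembly`.
#' @export
setGeneric("assemblySeq", function(x) standardGeneric("assemblySeq"))

#' @rdname SimGenome-class
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))

#' @rdname CorruptedAssembly-class
#' @param x a `CorruptedAssembly`.
#' @export
setGeneric("truthRegions", function(x) standardGeneric("truthRegions"))

#' @rdname CorruptedAssembly-class
#' @export
setGeneric("liftoverChunks", function(x) standardGeneric("liftoverChunks"))
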