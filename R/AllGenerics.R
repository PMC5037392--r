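#' @import methods
NULL

#' @rdname poolCallSet
#' @export
setGeneric("refReads", function(x) standardGeneric("refReads"))

#' @rdname poolCallSet
#' @export
setGeneric("altReads", function(x) standardGeneric("altReads"))

#' @rdname poolCallSet
#' @export
setGeneric("qualScores", function(x) standardGeneric("qualScores"))

#' @rdname poolCallSet
#' @export
setGeneric("inDb", function(x) standardGeneric("inDb"))

#' @rdname poolCallSet
#' @export
setGeneric("poolSize", function(x) standardGeneric("poolSize"))

#' @rdname poolCallSet
#' @export
setGeneric("numPools", function(x) standardGeneric("numPools"))

#' @rdname poolCallSet
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname alleleFrequencies
#' @export
setGeneric("perPoolAF", function(x, ...) standardGeneric("perPoolAF"))

#' @rdname alleleFrequencies
#' @export
setGeneric("cohortAF", function(x, ...) standardGeneric("cohortAF"))

#' @rdname FilterOutcome-accessors
#' @export
setGeneric("surviving", function(x) standardGeneric("surviving"))

#' @rdname FilterOutcome-accessors
#' @export
setGeneric("removedKeys", function(x) standardGeneric("removedKeys"))

#' @rdname FilterOutcome-accessors
#' @export
setGeneric("poolResets", function(x) standardGeneric("poolResets"))

#' @rdname ScanResult-accessors
#' @export
setGeneric("bestThreshold", function(x) standardGeneric("bestThreshold"))

#' @rdname ScanResult-accessors
#' @export
setGeneric("bestDstat", function(x) standardGeneric("bestDstat"))
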