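#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @export
setGeneric("populations<-", function(x, value) standardGeneric("populations<-"))

#' @export
setGeneric("lociInfo", function(x, ...) standardGeneric("lociInfo"))

#' @export
setGeneric("accessionIds", function(x, ...) standardGeneric("accessionIds"))

#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @export
setGeneric("nAccessions", function(x) standardGeneric("nAccessions"))

#' @export
setGeneric("selectedIds", function(object) standardGeneric("selectedIds"))

#' @export
setGeneric("coreSize", function(object) standardGeneric("coreSize"))

#' @export
setGeneric("alleleCoverage", function(x, subset, ...) standardGeneric("alleleCoverage"))
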