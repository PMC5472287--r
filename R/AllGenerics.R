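#' @rdname GrsCohort-class
#' @param x,object a \code{GrsCohort}, \code{GrsPanel} or \code{ScoreSet}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GrsCohort-class
#' @export
setGeneric("snpMeta", function(x) standardGeneric("snpMeta"))

#' @rdname GrsCohort-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname GrsCohort-class
#' @param per for \code{missingRate}, report the missing fraction per
#'   \code{"snp"}, per \code{"sample"} or \code{"overall"}.
#' @export
setGeneric("missingRate",
           function(x, per = c("snp", "sample", "overall"))
               standardGeneric("missingRate"))

#' @rdname ScoreSet-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ScoreSet-class
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' @rdname ScoreSet-class
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname GrsPanel-class
#' @param x,object a \code{GrsPanel}.
#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))

#' @rdname GrsPanel-class
#' @export
setGeneric("panelSnps", function(x) standardGeneric("panelSnps"))

#' @rdname GrsPanel-class
#' @export
setGeneric("panelWeights", function(x) standardGeneric("panelWeights"))
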