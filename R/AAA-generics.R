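#' @importFrom BiocGenerics counts
NULL

#' Modality of a quantified object
#'
#' @param object a [FeatureMatrix-class] or other modality-carrying object.
#' @return `"RNA"` or `"DNA"`.
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' Community membership of a partition
#'
#' @param object a [Partition-class].
#' @return named integer vector, cell to community label.
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' Multiplex modularity of a partition
#'
#' @param object a [Partition-class].
#' @param ... passed to methods (`perLayer = TRUE` returns the per-layer
#'   vector).
#' @export
setGeneric("modularity", function(object, ...) standardGeneric("modularity"))
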