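#' @rdname StrainReference-class
#' @param x,object a \code{StrainReference}, \code{FragmentCounts},
#'   \code{AbundanceReport} or \code{CommunityDesign} object.
#' @export
setGeneric("subcontigTable", function(x) standardGeneric("subcontigTable"))

#' @rdname StrainReference-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname StrainReference-class
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname StrainReference-class
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname FragmentCounts-class
#' @param x object.
#' @export
setGeneric("fragmentCounts", function(x) standardGeneric("fragmentCounts"))

#' @rdname FragmentCounts-class
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname FragmentCounts-class
#' @export
setGeneric("totalInput", function(x) standardGeneric("totalInput"))

#' @rdname AbundanceReport-class
#' @param x object.
#' @export
setGeneric("abundanceTable", function(x) standardGeneric("abundanceTable"))

#' @rdname AbundanceReport-class
#' @export
setGeneric("subcontigMetrics", function(x) standardGeneric("subcontigMetrics"))

#' @rdname CommunityDesign-class
#' @param x object.
#' @export
setGeneric("trueAbundances", function(x) standardGeneric("trueAbundances"))

#' @rdname CommunityDesign-class
#' @export
setGeneric("memberGenomes", function(x) standardGeneric("memberGenomes"))

#' Fraction of community-unique k-mers per strain
#'
#' For every strain, the fraction of its k-mer positions whose canonical
#' k-mer occurs exactly once in the whole community reference. Mirrors the
#' genome-selection screen used when assembling large communities (members
#' are expected to retain at least a few percent unique k-mers).
#'
#' @param x a [StrainReference].
#' @return named numeric vector, one fraction per strain.
#' @export
setGeneric("uniqueKmerFraction",
           function(x) standardGeneric("uniqueKmerFraction"))
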