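#' @rdname StrainReference-class
#' @export
setMethod("subcontigTable", "StrainReference", function(x) x@subcontigs)

#' @rdname StrainReference-class
#' @export
setMethod("refSequences", "StrainReference", function(x) x@sequences)

#' @rdname StrainReference-class
#' @export
setMethod("strainNames", "StrainReference", function(x) x@strainIds)

#' @rdname StrainReference-class
#' @export
setMethod("kmerSize", "StrainReference", function(x) x@k)

#' @rdname CommunityDesign-class
#' @export
setMethod("strainNames", "CommunityDesign", function(x) names(x@genomes))

#' @rdname FragmentCounts-class
#' @export
setMethod("fragmentCounts", "FragmentCounts", function(x) x@counts)

#' @rdname FragmentCounts-class
#' @export
setMethod("totalMapped", "FragmentCounts", function(x) x@totalMapped)

#' @rdname FragmentCounts-class
#' @export
setMethod("totalInput", "FragmentCounts", function(x) x@totalInput)

#' @rdname AbundanceReport-class
#' @export
setMethod("abundanceTable", "AbundanceReport", function(x) x@strains)

#' @rdname AbundanceReport-class
#' @export
setMethod("subcontigMetrics", "AbundanceReport", function(x) x@subcontigMetrics)

#' @rdname AbundanceReport-class
#' @export
setMethod("totalMapped", "AbundanceReport", function(x) x@totalMapped)

#' @rdname CommunityDesign-class
#' @export
setMethod("trueAbundances", "CommunityDesign", function(x) x@abundances)

#' @rdname CommunityDesign-class
#' @export
setMethod("memberGenomes", "CommunityDesign", function(x) x@genomes)

#' @rdname uniqueKmerFraction
#' @export
setMethod("uniqueKmerFraction", "StrainReference", function(x) {
  tab <- x@subcontigs
  kpos <- pmax(0L, tab$seq_length - x@k + 1L)
  u <- tapply(tab$unique_kmers, tab$strain_id, sum)
  tot <- tapply(kpos, tab$strain_id, sum)
  frac <- as.numeric(u) / pmax(1, as.numeric(tot))
  names(frac) <- names(u)
  frac[x@strainIds]
})

setMethod("show", "StrainReference", function(object) {
  tab <- object@subcontigs
  cat("StrainReference with", length(object@strainIds), "strains,",
      nrow(tab), "subcontigs (", sum(tab$excluded), "excluded )\n")
  cat("  k =", object@k, "| max subcontig =", object@maxSubcontigSize,
      "| min contig =", object@minContigSize,
      "| overlap =", object@overlap, "\n")
  cat("  unique k-mers:", sum(as.numeric(tab$unique_kmers)),
      "across", sum(as.numeric(pmax(0L, tab$seq_length - object@k + 1L))),
      "k-mer positions\n")
})

setMethod("show", "FragmentCounts", function(object) {
  cat("FragmentCounts:", object@totalMapped, "of", object@totalInput,
      "fragments mapped perfectly and uniquely across",
      length(object@counts), "subcontigs\n")
})

setMethod("show", "AbundanceReport", function(object) {
  cat("AbundanceReport (weighted percentile p =", object@percentile, ")\n")
  cat("  total mapped fragments:", object@totalMapped, "of",
      object@totalInput, "\n")
  show(object@strains)
})

setMethod("show", "CommunityDesign", function(object) {
  cat("CommunityDesign:", length(object@genomes), "strains,",
      object@distribution, "abundances,", object@nFragments,
      "fragments (seed", object@seed, ")\n")
})
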