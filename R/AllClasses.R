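#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Uniqueness-normalized strain reference database
#'
#' Holds the subcontig sequences and per-subcontig unique canonical k-mer
#' counts for a defined community, together with the parameters used to build
#' them. Subcontigs are N50-bounded slices of the input contigs, extended by
#' \code{overlap} bases on each side; contigs below \code{minContigSize} are
#' kept as single excluded subcontigs (their k-mers still poison uniqueness,
#' but they contribute no FUKM estimate).
#'
#' @slot sequences \link[Biostrings]{DNAStringSet} of subcontig sequences
#'   (cores plus overlap flanks), named by subcontig id.
#' @slot subcontigs \link[S4Vectors]{DataFrame} with one row per subcontig:
#'   \code{subcontig_id}, \code{strain_id}, \code{contig_id},
#'   \code{core_start}, \code{core_end} (0-based half-open on the parent
#'   contig), \code{seq_start}, \code{seq_end}, \code{seq_length},
#'   \code{excluded}, \code{unique_kmers}.
#' @slot k odd integer, canonical k-mer size (default \code{2*readSize + 1}).
#' @slot readSize integer, nominal mate length in bases.
#' @slot maxSubcontigSize integer, upper bound on subcontig core size
#'   (default: smallest N50 across input genomes).
#' @slot minContigSize integer, contigs shorter than this are excluded.
#' @slot overlap integer, flank length shared with neighbouring subcontigs.
#' @slot hashName character, identifier of the 64-bit k-mer hash.
#' @slot strainIds character vector of community member ids.
#'
#' @seealso [buildReferenceDatabase()], [strainAbundance()]
#' @export
setClass("StrainReference",
  representation(
    sequences = "DNAStringSet",
    subcontigs = "DataFrame",
    k = "integer",
    readSize = "integer",
    maxSubcontigSize = "integer",
    minContigSize = "integer",
    overlap = "integer",
    hashName = "character",
    strainIds = "character"
  )
)

setValidity("StrainReference", function(object) {
  tab <- object@subcontigs
  msg <- character()
  need <- c("subcontig_id", "strain_id", "contig_id", "core_start",
            "core_end", "seq_start", "seq_end", "seq_length", "excluded",
            "unique_kmers")
  if (!all(need %in% colnames(tab)))
    return(paste("subcontigs table must have columns:",
                 paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(tab))
    msg <- c(msg, "one sequence per subcontig row required")
  if (!identical(names(object@sequences), as.character(tab$subcontig_id)))
    msg <- c(msg, "sequence names must equal subcontig_id, in order")
  if (!all(tab$strain_id %in% object@strainIds))
    msg <- c(msg, "all subcontig strain_ids must appear in strainIds")
  if (length(object@k) != 1L || object@k < 3L || object@k %% 2L == 0L)
    msg <- c(msg, "k must be a single odd integer >= 3")
  if (!all(Biostrings::width(object@sequences) == tab$seq_length))
    msg <- c(msg, "seq_length must match sequence widths")
  kpos <- pmax(0L, tab$seq_length - object@k + 1L)
  if (!all(tab$unique_kmers >= 0L & tab$unique_kmers <= kpos))
    msg <- c(msg, "unique_kmers must lie in [0, number of k-mer positions]")
  # cores of each contig must tile it exactly
  key <- paste(tab$strain_id, tab$contig_id, sep = "\r")
  for (g in split(seq_len(nrow(tab)), key)) {
    o <- g[order(tab$core_start[g])]
    if (tab$core_start[o[1L]] != 0L ||
        !all(tab$core_start[o][-1L] == tab$core_end[o][-length(o)]))
      msg <- c(msg, "subcontig cores must tile their contig exactly")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample perfect-unique fragment counts
#'
#' Result of mapping one sample's read pairs against a [StrainReference]:
#' the number of fragments (read pairs) that map perfectly and unambiguously
#' to each subcontig, plus sample-wide totals. \code{totalMapped} is the FUKM
#' denominator ("total mapped fragments") and includes fragments assigned to
#' excluded subcontigs.
#'
#' @slot counts named integer vector, fragments per subcontig id.
#' @slot totalMapped integer, sum of \code{counts}.
#' @slot totalInput integer, read pairs supplied before filtering.
#' @export
setClass("FragmentCounts",
  representation(
    counts = "integer",
    totalMapped = "integer",
    totalInput = "integer"
  )
)

setValidity("FragmentCounts", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) && length(object@counts) > 0L)
    msg <- c(msg, "counts must be named by subcontig id")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (object@totalMapped != sum(object@counts))
    msg <- c(msg, "totalMapped must equal sum(counts)")
  if (object@totalMapped > object@totalInput)
    msg <- c(msg, "totalMapped cannot exceed totalInput")
  if (length(msg)) msg else TRUE
})

#' Per-strain abundance report
#'
#' Per-strain abundance estimates for one sample: the median subcontig FUKM
#' (mFUKM), the unique-k-mer-weighted percentile FUKM (wpFUKM, the
#' recommended point estimate), the FPKM baseline computed from the same
#' perfect-unique fragment counts, the wpFUKM share as relative abundance,
#' and a presence call (\code{wpfukm > 0}).
#'
#' @slot strains \link[S4Vectors]{DataFrame}: \code{strain_id},
#'   \code{n_subcontigs_used}, \code{mfukm}, \code{wpfukm}, \code{fpkm},
#'   \code{relative_abundance}, \code{present}.
#' @slot subcontigMetrics \link[S4Vectors]{DataFrame}: per-subcontig
#'   \code{subcontig_id}, \code{strain_id}, \code{unique_kmers},
#'   \code{mapped_fragments}, \code{fukm} (non-excluded subcontigs with
#'   unique k-mers only).
#' @slot totalMapped integer, total mapped fragments in the sample.
#' @slot totalInput integer, input read pairs.
#' @slot percentile numeric, weighted percentile used for wpFUKM.
#' @export
setClass("AbundanceReport",
  representation(
    strains = "DataFrame",
    subcontigMetrics = "DataFrame",
    totalMapped = "integer",
    totalInput = "integer",
    percentile = "numeric"
  )
)

setValidity("AbundanceReport", function(object) {
  tab <- object@strains
  msg <- character()
  need <- c("strain_id", "n_subcontigs_used", "mfukm", "wpfukm", "fpkm",
            "relative_abundance", "present")
  if (!all(need %in% colnames(tab)))
    return(paste("strains table must have columns:",
                 paste(need, collapse = ", ")))
  ra <- sum(tab$relative_abundance)
  if (!(abs(ra - 1) < 1e-8 || ra == 0))
    msg <- c(msg, "relative abundances must sum to 1 (or all be 0)")
  if (!all(tab$present == (tab$wpfukm > 0)))
    msg <- c(msg, "present must equal wpfukm > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic community design
#'
#' Ground truth for a simulated defined community: member genomes (with their
#' phylogenetic provenance and assembly fragmentation), a true relative
#' abundance vector, and the read-generation parameters. Abundances are
#' relative genome (cell) abundances, so expected coverage is proportional to
#' abundance.
#'
#' @slot genomes \link[Biostrings]{DNAStringSet}, one full genome per strain,
#'   named by strain id.
#' @slot contigLengths list of integer vectors; per strain, the contig
#'   lengths of its (possibly fragmented) assembly. Sums must equal genome
#'   lengths.
#' @slot strainInfo \link[S4Vectors]{DataFrame}: \code{strain_id},
#'   \code{parent_id} (NA for de novo ancestors), \code{divergence}
#'   (substitutions per base from parent).
#' @slot abundances named numeric, true relative abundances (sum 1; absent
#'   strains 0).
#' @slot distribution character, name of the abundance distribution.
#' @slot readLength,insertMean,insertSd,errorRate,nFragments,seed read
#'   simulation parameters.
#' @export
setClass("CommunityDesign",
  representation(
    genomes = "DNAStringSet",
    contigLengths = "list",
    strainInfo = "DataFrame",
    abundances = "numeric",
    distribution = "character",
    readLength = "integer",
    insertMean = "numeric",
    insertSd = "numeric",
    errorRate = "numeric",
    nFragments = "integer",
    seed = "integer"
  )
)

setValidity("CommunityDesign", function(object) {
  msg <- character()
  n <- length(object@genomes)
  if (length(object@contigLengths) != n)
    msg <- c(msg, "one contigLengths entry per genome required")
  else if (!all(vapply(seq_len(n), function(i)
      sum(object@contigLengths[[i]]) == Biostrings::width(object@genomes)[i],
      logical(1))))
    msg <- c(msg, "contig lengths must sum to genome lengths")
  if (length(object@abundances) != n)
    msg <- c(msg, "one abundance per genome required")
  if (any(object@abundances < 0))
    msg <- c(msg, "abundances must be non-negative")
  if (abs(sum(object@abundances) - 1) > 1e-8)
    msg <- c(msg, "abundances must sum to 1")
  if (!identical(names(object@abundances), names(object@genomes)))
    msg <- c(msg, "abundances must be named like genomes")
  if (length(msg)) msg else TRUE
})
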