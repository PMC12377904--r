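#' FUKM: fragments per thousand unique k-mers per million mapped fragments
#'
#' The uniqueness-normalized analog of FPKM:
#' \deqn{FUKM = \frac{F}{(U/10^3)\,(M/10^6)}}
#' where F is the subcontig's perfect-unique fragment count, U its unique
#' canonical k-mer count, and M the sample's total mapped fragments.
#' Subcontigs with U = 0 have no FUKM (callers must exclude them); M = 0
#' yields 0.
#'
#' @param mappedFragments fragments mapped to the subcontig (vectorized).
#' @param uniqueKmers the subcontig's unique k-mer count.
#' @param totalMapped total mapped fragments in the sample.
#' @return numeric FUKM value(s).
#' @examples
#' computeFUKM(200, 5000, 1e6)  # 40
#' @export
computeFUKM <- function(mappedFragments, uniqueKmers, totalMapped) {
  if (any(uniqueKmers <= 0))
    stop("FUKM is undefined for subcontigs with no unique k-mers")
  if (totalMapped == 0) return(rep(0, length(mappedFragments)))
  mappedFragments / ((uniqueKmers / 1e3) * (totalMapped / 1e6))
}

#' Median subcontig FUKM (mFUKM)
#'
#' @param fukm FUKM values of one strain's usable subcontigs.
#' @return the median (mean of central pair for even counts); 0 for an
#'   empty vector (no usable subcontigs).
#' @export
computeMFUKM <- function(fukm) {
  if (length(fukm) == 0L) return(0)
  stats::median(fukm)
}

#' Weighted-percentile subcontig FUKM (wpFUKM)
#'
#' Subcontigs are sorted ascending by FUKM (ties broken by id for
#' determinism) and the cumulative proportion of unique k-mers is
#' accumulated along the sorted list; the wpFUKM is the FUKM of the first
#' subcontig at which that proportion reaches p percent. Weighting by unique
#' k-mers lets subcontigs rich in uniquely mappable sites dominate the point
#' estimate.
#'
#' @param fukm FUKM values of one strain's usable subcontigs.
#' @param uniqueKmers matching unique k-mer counts (the weights).
#' @param p percentile in (0, 100] (default 60).
#' @param ids optional subcontig ids for deterministic tie-breaking.
#' @return the weighted-percentile FUKM; 0 for an empty list.
#' @examples
#' computeWPFUKM(c(1, 2, 3), c(100, 300, 600), p = 60)  # 3
#' @export
computeWPFUKM <- function(fukm, uniqueKmers, p = 60, ids = NULL) {
  stopifnot(p > 0, p <= 100)
  if (length(fukm) == 0L) return(0)
  if (length(uniqueKmers) != length(fukm))
    stop("fukm and uniqueKmers must have equal length")
  o <- if (is.null(ids)) order(fukm) else order(fukm, ids)
  cum <- cumsum(as.numeric(uniqueKmers[o]))
  idx <- which(cum >= (p / 100) * cum[length(cum)])[1L]
  fukm[o][idx]
}

#' FPKM baseline from the same mapping data
#'
#' Fragments per kilobase of genome per million mapped fragments, computed
#' from the same perfect-unique fragment counts the FUKM normalizes; the
#' un-normalized comparator biased against strains with near-clonal
#' partners.
#'
#' @param strainFragments summed perfect-unique fragments of the strain.
#' @param genomeLength total genome length in bases.
#' @param totalMapped total mapped fragments in the sample.
#' @return numeric FPKM.
#' @export
computeFPKM <- function(strainFragments, genomeLength, totalMapped) {
  stopifnot(all(genomeLength > 0))
  if (totalMapped == 0) return(rep(0, length(strainFragments)))
  strainFragments / ((genomeLength / 1e3) * (totalMapped / 1e6))
}

#' Per-strain abundance report from a mapped sample
#'
#' Computes per-subcontig FUKM (dropping excluded subcontigs and subcontigs
#' with no unique k-mers, whose fragments nevertheless stay in the total
#' mapped denominator), then per strain the mFUKM, wpFUKM, FPKM baseline,
#' relative abundance (wpFUKM share) and presence call.
#'
#' @param db a [StrainReference].
#' @param counts a [FragmentCounts] for one sample, aligned to \code{db}.
#' @param percentile weighted percentile p for wpFUKM (default 60).
#' @return an [AbundanceReport].
#' @export
strainAbundance <- function(db, counts, percentile = 60) {
  tab <- db@subcontigs
  cnt <- counts@counts
  unknown <- setdiff(names(cnt), tab$subcontig_id)
  if (length(unknown))
    stop("counts reference unknown subcontig(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  frag <- integer(nrow(tab))
  names(frag) <- tab$subcontig_id
  frag[names(cnt)] <- cnt
  M <- counts@totalMapped

  usable <- !tab$excluded & tab$unique_kmers > 0L
  met <- S4Vectors::DataFrame(
    subcontig_id = tab$subcontig_id[usable],
    strain_id = tab$strain_id[usable],
    unique_kmers = tab$unique_kmers[usable],
    mapped_fragments = frag[usable])
  met$fukm <- if (M > 0)
    computeFUKM(met$mapped_fragments, met$unique_kmers, M)
  else rep(0, nrow(met))

  strains <- db@strainIds
  coreLen <- tapply(as.numeric(tab$core_end - tab$core_start),
                    tab$strain_id, sum)[strains]
  strainFrag <- tapply(as.numeric(frag), tab$strain_id, sum)[strains]
  mf <- wp <- numeric(length(strains))
  nUsed <- integer(length(strains))
  for (i in seq_along(strains)) {
    rows <- met$strain_id == strains[i]
    nUsed[i] <- sum(rows)
    mf[i] <- computeMFUKM(met$fukm[rows])
    wp[i] <- computeWPFUKM(met$fukm[rows], met$unique_kmers[rows],
                           p = percentile, ids = met$subcontig_id[rows])
  }
  fpkm <- computeFPKM(strainFrag, coreLen, M)
  rel <- if (sum(wp) > 0) wp / sum(wp) else rep(0, length(wp))

  new("AbundanceReport",
      strains = S4Vectors::DataFrame(
        strain_id = strains,
        n_subcontigs_used = nUsed,
        mfukm = mf,
        wpfukm = wp,
        fpkm = as.numeric(fpkm),
        relative_abundance = rel,
        present = wp > 0),
      subcontigMetrics = met,
      totalMapped = as.integer(M),
      totalInput = counts@totalInput,
      percentile = percentile)
}

#' Write abundance report files
#'
#' Writes \code{abundances.tsv} (per strain) and \code{subcontig_fukm.tsv}
#' (per subcontig detail) into \code{dir}.
#'
#' @param report an [AbundanceReport].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeAbundanceReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report@strains),
                     file.path(dir, "abundances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report@subcontigMetrics),
                     file.path(dir, "subcontig_fukm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
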