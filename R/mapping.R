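#' Filter and trim read pairs
#'
#' Read-quality gate applied before exact mapping: trailing poly-G runs of at
#' least \code{polyGMinRun} bases are trimmed from the 3' end of each mate
#' (an Illumina two-color artifact); pairs where either mate then carries
#' more than \code{maxN} ambiguous bases or is shorter than \code{minLength}
#' are dropped.
#'
#' @param r1,r2 character vectors (or \link[Biostrings]{DNAStringSet}) of
#'   mate sequences, element i of r1 paired with element i of r2.
#' @param minLength minimum mate length after trimming (default 50).
#' @param maxN maximum ambiguous bases per mate (default 0).
#' @param polyGMinRun minimum trailing G-run length to trim (default 10).
#' @return list with \code{r1}, \code{r2} (trimmed, kept pairs only) and
#'   \code{kept} (logical over the input pairs).
#' @export
filterReadPairs <- function(r1, r2, minLength = 50L, maxN = 0L,
                            polyGMinRun = 10L) {
  r1 <- toupper(as.character(r1))
  r2 <- toupper(as.character(r2))
  if (length(r1) != length(r2)) stop("r1 and r2 must have equal length")
  pat <- sprintf("G{%d,}$", as.integer(polyGMinRun))
  r1 <- sub(pat, "", r1)
  r2 <- sub(pat, "", r2)
  nN <- function(x) nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))
  kept <- nchar(r1) >= minLength & nchar(r2) >= minLength &
          nN(r1) <= maxN & nN(r2) <= maxN
  list(r1 = r1[kept], r2 = r2[kept], kept = kept)
}

#' Map read pairs exactly against a reference database
#'
#' A pair hits a subcontig when both mates match its sequence exactly and
#' full-length, on opposite strands in convergent orientation with
#' non-negative inner gap. Pairs hitting exactly one subcontig are unique
#' (multiple positions on the same subcontig still count as unique to it);
#' pairs hitting two or more subcontigs are ambiguous and discarded; the
#' rest are unmapped. Mates must be ACGT-only and at least 31 b long (the
#' read filter guarantees 50 b); anything else is reported unmapped.
#'
#' @param r1,r2 mate sequences (character or
#'   \link[Biostrings]{DNAStringSet}), already filtered.
#' @param db a [StrainReference].
#' @return character vector, one element per pair: the subcontig id for
#'   unique pairs, \code{"ambiguous"}, or \code{"unmapped"}.
#' @export
mapFragments <- function(r1, r2, db) {
  r1 <- toupper(as.character(r1))
  r2 <- toupper(as.character(r2))
  v <- cpp_map_fragments(as.character(db@sequences), r1, r2)
  ids <- db@subcontigs$subcontig_id
  out <- rep("unmapped", length(v))
  out[v == -1L] <- "ambiguous"
  out[v > 0L] <- ids[v[v > 0L]]
  out
}

#' Count perfect-unique fragments per subcontig
#'
#' Applies [filterReadPairs()] then [mapFragments()]; each uniquely mapped
#' fragment increments exactly one subcontig. Counts are independent of read
#' order. Fragments assigned to excluded subcontigs are counted too (they
#' are real mapped data and enter the FUKM denominator).
#'
#' @inheritParams filterReadPairs
#' @param db a [StrainReference].
#' @param filter apply the read filter first (default TRUE).
#' @return a [FragmentCounts].
#' @export
countFragments <- function(r1, r2, db, filter = TRUE, minLength = 50L,
                           maxN = 0L, polyGMinRun = 10L) {
  nInput <- length(r1)
  if (filter) {
    f <- filterReadPairs(r1, r2, minLength = minLength, maxN = maxN,
                         polyGMinRun = polyGMinRun)
    r1 <- f$r1; r2 <- f$r2
  }
  ids <- db@subcontigs$subcontig_id
  counts <- integer(length(ids))
  names(counts) <- ids
  if (length(r1) > 0L) {
    hit <- mapFragments(r1, r2, db)
    t <- table(hit[!(hit %in% c("ambiguous", "unmapped"))])
    counts[names(t)] <- as.integer(t)
  }
  new("FragmentCounts", counts = counts,
      totalMapped = as.integer(sum(counts)), totalInput = as.integer(nInput))
}

#' Count fragments from paired FASTQ files
#'
#' @param r1Path,r2Path paired FASTQ files (plain or gzip), mates matched by
#'   record order.
#' @inheritParams countFragments
#' @return a [FragmentCounts].
#' @export
countFragmentsFastq <- function(r1Path, r2Path, db, ...) {
  for (p in c(r1Path, r2Path))
    if (!file.exists(p)) stop("missing read file: ", p)
  r1 <- Biostrings::readDNAStringSet(r1Path, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(r2Path, format = "fastq")
  if (length(r1) != length(r2))
    stop("mate files have different record counts")
  countFragments(r1, r2, db, ...)
}

#' Import fragment counts from an external SAM/BAM alignment
#'
#' Alternate input path for alignments produced externally under the
#' perfect-and-unambiguous mapping contract (end-to-end, no mismatches,
#' ambiguous reads discarded, proper pairs only). One fragment is counted
#' per template whose two primary records are properly paired on the same
#' subcontig with edit distance 0 (NM tag) and a CIGAR that is a single
#' full-length match; all other records are ignored.
#'
#' @param samPath SAM or BAM file; reference names must be subcontig ids of
#'   \code{db}.
#' @param db a [StrainReference].
#' @return a [FragmentCounts].
#' @export
importSamCounts <- function(samPath, db) {
  if (!file.exists(samPath)) stop("missing alignment file: ", samPath)
  bam <- samPath
  if (grepl("\\.sam$", samPath, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(samPath, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar", "qwidth"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- x$flag
  qname <- x$qname
  rname <- as.character(x$rname)
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  nInput <- length(unique(qname[primary]))
  aligned <- primary & bitwAnd(flag, 0x4L) == 0L
  ids <- db@subcontigs$subcontig_id
  unknown <- setdiff(unique(rname[aligned]), ids)
  if (length(unknown))
    stop("alignment references unknown subcontig(s): ",
         paste(unknown, collapse = ", "))
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(flag))
  if (anyNA(nm[aligned]))
    stop("NM (edit distance) tag missing; re-align with NM tags enabled")
  fullM <- !is.na(x$cigar) & x$cigar == paste0(x$qwidth, "M")
  ok <- aligned & bitwAnd(flag, 0x1L) != 0L & bitwAnd(flag, 0x2L) != 0L &
        nm == 0L & fullM
  counts <- integer(length(ids))
  names(counts) <- ids
  if (any(ok)) {
    # both mates of a template must qualify, on the same subcontig
    byq <- split(rname[ok], qname[ok])
    good <- vapply(byq, function(r) length(r) == 2L && r[1] == r[2],
                   logical(1))
    t <- table(vapply(byq[good], `[`, character(1), 1L))
    if (length(t)) counts[names(t)] <- as.integer(t)
  }
  new("FragmentCounts", counts = counts,
      totalMapped = as.integer(sum(counts)), totalInput = as.integer(nInput))
}
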