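#' Assembly N50
#'
#' The largest contig length L such that contigs of length >= L contain at
#' least half the total assembly length.
#'
#' @param contigLengths positive integer vector of contig lengths.
#' @return a single length (bases).
#' @examples
#' computeN50(c(5, 4, 3, 2, 1))  # 4
#' @export
computeN50 <- function(contigLengths) {
  if (length(contigLengths) == 0L) stop("no contigs")
  if (any(contigLengths <= 0)) stop("contig lengths must be positive")
  s <- sort(as.numeric(contigLengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Maximum subcontig size for a community
#'
#' By default the smallest per-genome N50 across the community, so every
#' genome is split to the build quality of the worst assembly; an override
#' wins when given.
#'
#' @param genomeContigLengths list of integer vectors, one per genome.
#' @param override optional size in bases.
#' @param minContigSize used only to warn when the result falls below it.
#' @param k k-mer size; the result must exceed it.
#' @return size in bases.
#' @export
determineMaxSubcontigSize <- function(genomeContigLengths, override = NULL,
                                      minContigSize = 10000L, k = 301L) {
  if (length(genomeContigLengths) == 0L) stop("no genomes")
  size <- if (!is.null(override)) as.numeric(override)
          else min(vapply(genomeContigLengths, computeN50, numeric(1)))
  if (size <= k)
    stop("max subcontig size (", size, ") must exceed the k-mer size (", k, ")")
  if (size < minContigSize)
    warning("max subcontig size (", size, ") is below the minimum contig size (",
            minContigSize, "); the database may exclude everything")
  size
}

#' Split one contig into N50-bounded subcontigs
#'
#' The contig is cut into \code{ceiling(L / maxSize)} pieces of (near-)equal
#' core size \code{ceiling(L / pieces)}; the last core absorbs the remainder.
#' Each subcontig's sequence extends its core by \code{overlap} bases on both
#' sides (truncated at the contig ends) so fragments straddling a core
#' boundary can still map. Contigs shorter than \code{minContigSize} are
#' returned whole as a single subcontig with \code{excluded = TRUE}.
#'
#' @param sequence contig sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param contigId,strainId identifiers used to build subcontig ids.
#' @param maxSize maximum core size in bases.
#' @param overlap flank size in bases (default 500).
#' @param minContigSize exclusion threshold in bases (default 10000).
#' @return list with \code{table} (\link[S4Vectors]{DataFrame} of subcontig
#'   coordinates, 0-based half-open cores) and \code{sequences}
#'   (\link[Biostrings]{DNAStringSet}).
#' @export
splitContig <- function(sequence, contigId, strainId, maxSize,
                        overlap = 500L, minContigSize = 10000L) {
  if (maxSize <= 0) stop("maxSize must be positive")
  seqchar <- toupper(as.character(sequence))
  L <- nchar(seqchar)
  if (L == 0L) stop("empty contig ", contigId)
  if (L < minContigSize) {
    starts <- 0L
    ends <- L
    excluded <- TRUE
  } else {
    pieces <- ceiling(L / maxSize)
    core <- ceiling(L / pieces)
    starts <- as.integer((seq_len(pieces) - 1L) * core)
    ends <- as.integer(pmin(starts + core, L))
    excluded <- rep(FALSE, pieces)
  }
  seqStart <- pmax(0L, starts - as.integer(overlap))
  seqEnd <- pmin(L, ends + as.integer(overlap))
  ids <- paste(strainId, contigId, starts, ends, sep = "|")
  tab <- S4Vectors::DataFrame(
    subcontig_id = ids,
    strain_id = strainId,
    contig_id = contigId,
    core_start = starts,
    core_end = ends,
    seq_start = as.integer(seqStart),
    seq_end = as.integer(seqEnd),
    seq_length = as.integer(seqEnd - seqStart),
    excluded = excluded
  )
  seqs <- Biostrings::DNAStringSet(substring(seqchar, seqStart + 1L, seqEnd))
  names(seqs) <- ids
  list(table = tab, sequences = seqs)
}

#' Canonical k-mers of a sequence
#'
#' Every k-length window over \{A,C,G,T\} is reported as the
#' lexicographically smaller of the window and its reverse complement;
#' windows containing any other character are skipped. Odd k guarantees no
#' palindromes, so the canonical form is always well-defined.
#'
#' @param sequence character or \link[Biostrings]{DNAString}.
#' @param k odd k-mer size.
#' @return character vector of canonical k-mers, one per retained position.
#' @export
canonicalKmers <- function(sequence, k) {
  stopifnot(k >= 3, k %% 2 == 1)
  cpp_canonical_kmers(toupper(as.character(sequence)), as.integer(k))
}

#' Canonical k-mer hashes of a sequence
#'
#' As [canonicalKmers()], but each canonical k-mer is reduced to its FNV-1a
#' 64-bit hash (reported as a 16-character hex string). This is the hash the
#' uniqueness index is built on.
#'
#' @inheritParams canonicalKmers
#' @return character vector of 64-bit hashes in hex.
#' @export
canonicalKmerHashes <- function(sequence, k) {
  stopifnot(k >= 3, k %% 2 == 1)
  cpp_canonical_kmer_hashes(toupper(as.character(sequence)), as.integer(k))
}

#' Community-wide unique k-mer counts
#'
#' For each sequence, the number of k-mer positions whose canonical k-mer
#' hash occurs exactly once across all sequences taken together. A k-mer
#' occurring twice within one sequence is non-unique, as are k-mers
#' duplicated by the overlap flanks of adjacent subcontigs; excluded
#' subcontigs participate fully (their k-mers mark shared content
#' non-unique) and receive a count of their own.
#'
#' @param sequences \link[Biostrings]{DNAStringSet} or character vector.
#' @param k odd k-mer size.
#' @return integer vector of per-sequence unique k-mer counts.
#' @export
buildUniquenessIndex <- function(sequences, k) {
  stopifnot(k >= 3, k %% 2 == 1)
  cpp_unique_kmer_counts(toupper(as.character(sequences)), as.integer(k))
}

#' Build the uniqueness-normalized reference database
#'
#' Reads one genome per community member, determines the maximum subcontig
#' size (smallest N50 by default), splits every contig into overlapping
#' subcontigs, and counts each subcontig's community-unique canonical
#' k-mers. Deterministic for fixed inputs and parameters.
#'
#' @param genomes either a character vector of FASTA paths (one file per
#'   strain, strain id = file stem; plain or gzip) or a named list of
#'   \link[Biostrings]{DNAStringSet} objects (strain id = list name, one
#'   entry per contig).
#' @param maxSubcontigSize optional override of the smallest-N50 default.
#' @param minContigSize contigs below this are excluded from FUKM (default
#'   10000).
#' @param readSize nominal mate length; k = 2*readSize + 1 (default 150, so
#'   k = 301).
#' @param overlap subcontig flank size (default 500).
#' @return a [StrainReference].
#' @examples
#' g <- list(sA = Biostrings::DNAStringSet(c(c1 = paste(
#'   sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""))))
#' db <- buildReferenceDatabase(g, minContigSize = 100, readSize = 50)
#' @export
buildReferenceDatabase <- function(genomes, maxSubcontigSize = NULL,
                                   minContigSize = 10000L, readSize = 150L,
                                   overlap = 500L) {
  if (is.character(genomes)) {
    paths <- genomes
    ids <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(paths),
               ignore.case = TRUE)
    genomes <- lapply(seq_along(paths), function(i) {
      if (!file.exists(paths[i])) stop("cannot read FASTA: ", paths[i])
      x <- Biostrings::readDNAStringSet(paths[i])
      if (length(x) == 0L) stop("empty FASTA: ", paths[i])
      # FASTA headers may carry descriptions; keep the first token
      names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
      x
    })
    names(genomes) <- ids
  }
  if (length(genomes) == 0L) stop("no genomes found")
  if (is.null(names(genomes)) || anyNA(names(genomes)) ||
      any(names(genomes) == ""))
    stop("genomes must be named by strain id")
  if (anyDuplicated(names(genomes)))
    stop("duplicate strain IDs: ",
         paste(unique(names(genomes)[duplicated(names(genomes))]),
               collapse = ", "))

  k <- 2L * as.integer(readSize) + 1L
  if (k %% 2L == 0L) k <- k + 1L

  lens <- lapply(genomes, Biostrings::width)
  maxSize <- determineMaxSubcontigSize(lens, maxSubcontigSize,
                                       minContigSize = minContigSize, k = k)

  tabs <- list()
  seqs <- list()
  for (strain in names(genomes)) {
    contigs <- genomes[[strain]]
    cids <- names(contigs)
    if (is.null(cids)) cids <- paste0("contig", seq_along(contigs))
    for (j in seq_along(contigs)) {
      sp <- splitContig(contigs[[j]], cids[j], strain, maxSize,
                        overlap = overlap, minContigSize = minContigSize)
      tabs[[length(tabs) + 1L]] <- sp$table
      seqs[[length(seqs) + 1L]] <- sp$sequences
    }
  }
  tab <- do.call(rbind, tabs)
  allseq <- do.call(c, seqs)

  tab$unique_kmers <- buildUniquenessIndex(allseq, k)

  exc <- tapply(tab$excluded, tab$strain_id, all)
  if (any(exc))
    warning("all subcontigs excluded for strain(s): ",
            paste(names(exc)[exc], collapse = ", "))

  new("StrainReference",
      sequences = allseq,
      subcontigs = tab,
      k = k,
      readSize = as.integer(readSize),
      maxSubcontigSize = as.integer(maxSize),
      minContigSize = as.integer(minContigSize),
      overlap = as.integer(overlap),
      hashName = "fnv1a64-canonical",
      strainIds = names(genomes))
}

#' Write a reference database directory
#'
#' Writes \code{subcontigs.fasta} (headers = subcontig ids),
#' \code{kmer_counts.tsv} and \code{db_meta.json}. Output is byte-identical
#' across repeated runs on the same inputs.
#'
#' @param db a [StrainReference].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReferenceDatabase <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(db@sequences, file.path(dir, "subcontigs.fasta"))
  tab <- as.data.frame(db@subcontigs)
  tab <- tab[, c("subcontig_id", "strain_id", "contig_id", "core_start",
                 "core_end", "seq_start", "seq_end", "seq_length",
                 "unique_kmers", "excluded")]
  utils::write.table(tab, file.path(dir, "kmer_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(k = db@k, read_size = db@readSize,
               max_subcontig_size = db@maxSubcontigSize,
               min_contig_size = db@minContigSize, overlap = db@overlap,
               hash_name = db@hashName, strain_ids = db@strainIds,
               tool = "StrainQuant",
               version = as.character(utils::packageVersion("StrainQuant")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "db_meta.json"))
  invisible(dir)
}

#' Read a reference database directory
#'
#' @param dir directory written by [writeReferenceDatabase()].
#' @return a [StrainReference]; round-trips losslessly.
#' @export
readReferenceDatabase <- function(dir) {
  metaPath <- file.path(dir, "db_meta.json")
  if (!file.exists(metaPath)) stop("not a reference database: ", dir)
  meta <- jsonlite::fromJSON(metaPath)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "subcontigs.fasta"))
  tab <- utils::read.table(file.path(dir, "kmer_counts.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = c(subcontig_id = "character",
                                          strain_id = "character",
                                          contig_id = "character"))
  new("StrainReference",
      sequences = seqs,
      subcontigs = S4Vectors::DataFrame(
        subcontig_id = tab$subcontig_id,
        strain_id = tab$strain_id,
        contig_id = tab$contig_id,
        core_start = as.integer(tab$core_start),
        core_end = as.integer(tab$core_end),
        seq_start = as.integer(tab$seq_start),
        seq_end = as.integer(tab$seq_end),
        seq_length = as.integer(tab$seq_length),
        excluded = as.logical(tab$excluded),
        unique_kmers = as.integer(tab$unique_kmers)),
      k = as.integer(meta$k),
      readSize = as.integer(meta$read_size),
      maxSubcontigSize = as.integer(meta$max_subcontig_size),
      minContigSize = as.integer(meta$min_contig_size),
      overlap = as.integer(meta$overlap),
      hashName = meta$hash_name,
      strainIds = meta$strain_ids)
}
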