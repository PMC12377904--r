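# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's compiled paths: uniqueness is
# re-counted with a plain R dictionary over canonical k-mer strings, and
# mapping is re-derived from Biostrings pattern matching.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# canonical k-mer strings of one sequence, pure R + Biostrings
r_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[ok]
  if (length(kmers) == 0L) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# brute-force multiplicity-1 dictionary: per-sequence count of k-mer
# positions whose canonical form occurs exactly once across all sequences
oracle_unique_counts <- function(seqs, k) {
  per <- lapply(unname(as.character(seqs)), r_canonical_kmers, k = k)
  tab <- table(unlist(per))
  once <- names(tab)[tab == 1L]
  vapply(per, function(x) sum(x %in% once), integer(1))
}

# all-offsets exact mapping oracle for equal-width mates, built on
# Biostrings::matchPDict. Returns "unmapped" / "ambiguous" / subcontig id.
oracle_map_pairs <- function(db, r1, r2) {
  refs <- refSequences(db)
  ids <- subcontigTable(db)$subcontig_id
  n <- length(r1)
  sets <- list(
    f1 = Biostrings::DNAStringSet(r1),
    f2 = Biostrings::DNAStringSet(r2),
    r1 = Biostrings::reverseComplement(Biostrings::DNAStringSet(r1)),
    r2 = Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
  pd <- lapply(sets, Biostrings::PDict)
  l1 <- nchar(r1)
  l2 <- nchar(r2)
  hitrefs <- vector("list", n)
  for (s in seq_along(refs)) {
    pos <- lapply(pd, function(d)
      Biostrings::startIndex(Biostrings::matchPDict(d, refs[[s]])))
    for (i in seq_len(n)) {
      f1 <- pos$f1[[i]]; rc2 <- pos$r2[[i]]
      f2 <- pos$f2[[i]]; rc1 <- pos$r1[[i]]
      proper <-
        (length(f1) && length(rc2) && max(rc2) >= min(f1) + l1[i]) ||
        (length(f2) && length(rc1) && max(rc1) >= min(f2) + l2[i])
      if (proper) hitrefs[[i]] <- c(hitrefs[[i]], s)
    }
  }
  vapply(seq_len(n), function(i) {
    h <- hitrefs[[i]]
    if (is.null(h)) "unmapped"
    else if (length(h) == 1L) ids[h]
    else "ambiguous"
  }, character(1))
}

# fully naive single-pair scan: every offset of every subcontig, both
# orientations, via substring comparison only (no matching library at all)
oracle_map_pair_naive <- function(db, a, b) {
  refs <- as.character(refSequences(db))
  ids <- subcontigTable(db)$subcontig_id
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  all_offsets <- function(ref, mate) {
    lm <- nchar(mate)
    L <- nchar(ref)
    if (L < lm) return(integer(0))
    starts <- seq_len(L - lm + 1L)
    starts[substring(ref, starts, starts + lm - 1L) == mate] - 1L
  }
  hits <- integer(0)
  for (s in seq_along(refs)) {
    f1 <- all_offsets(refs[s], a);  r2p <- all_offsets(refs[s], rc(b))
    f2 <- all_offsets(refs[s], b);  r1p <- all_offsets(refs[s], rc(a))
    proper <-
      (length(f1) && length(r2p) && max(r2p) >= min(f1) + nchar(a)) ||
      (length(f2) && length(r1p) && max(r1p) >= min(f2) + nchar(b))
    if (proper) hits <- c(hits, s)
  }
  if (length(hits) == 0L) "unmapped"
  else if (length(hits) == 1L) ids[hits]
  else "ambiguous"
}

# small random community reference for oracle comparisons
toy_reference <- function(nStrains, genomeLength, k = 31L, seed = 1L,
                          maxSubcontigSize = NULL, minContigSize = 0L) {
  set.seed(seed)
  genomes <- lapply(seq_len(nStrains), function(i) {
    g <- Biostrings::DNAStringSet(random_dna(genomeLength))
    names(g) <- "c1"
    g
  })
  names(genomes) <- sprintf("s%02d", seq_len(nStrains))
  readSize <- (k - 1L) %/% 2L
  buildReferenceDatabase(genomes, maxSubcontigSize = maxSubcontigSize,
                         minContigSize = minContigSize,
                         readSize = readSize, overlap = 50L)
}

# substitute one base at a fixed position (test-local, deterministic)
substitute_base <- function(seq, pos) {
  b <- substring(seq, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), b)[1]
  paste0(substring(seq, 1, pos - 1L), repl, substring(seq, pos + 1L))
}
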