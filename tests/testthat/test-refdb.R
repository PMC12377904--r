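test_that("N50 follows the standard definition", {
  expect_equal(computeN50(10), 10)
  expect_equal(computeN50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(computeN50(c(3, 3, 3)), 3)
  expect_error(computeN50(integer(0)), "no contigs")
  # brute-force check on random length sets
  set.seed(42)
  for (i in 1:25) {
    lens <- sample(1:5000, sample(1:30, 1), replace = TRUE)
    s <- sort(lens, decreasing = TRUE)
    brute <- s[min(which(cumsum(s) >= sum(s) / 2))]
    expect_equal(computeN50(lens), brute)
  }
})

test_that("max subcontig size defaults to the smallest N50", {
  g <- list(a = c(12000), b = c(9000), c = c(20000))
  expect_equal(determineMaxSubcontigSize(g, minContigSize = 5000), 9000)
  expect_equal(determineMaxSubcontigSize(g, override = 5000,
                                         minContigSize = 1000), 5000)
  expect_equal(determineMaxSubcontigSize(list(x = 8000),
                                         minContigSize = 5000), 8000)
  expect_error(determineMaxSubcontigSize(list(x = 200), k = 301),
               "must exceed the k-mer size")
  expect_warning(determineMaxSubcontigSize(list(x = 5000),
                                           minContigSize = 10000, k = 301),
                 "below the minimum contig size")
})

test_that("contig splitting tiles cores and extends flanks", {
  g <- random_dna(25000, seed = 1)
  sp <- splitContig(g, "c1", "sA", maxSize = 10000, overlap = 500,
                    minContigSize = 10000)
  tab <- sp$table
  expect_equal(tab$core_start, c(0L, 8334L, 16668L))
  expect_equal(tab$core_end, c(8334L, 16668L, 25000L))
  expect_equal(tab$seq_start, c(0L, 7834L, 16168L))
  expect_equal(tab$seq_end, c(8834L, 17168L, 25000L))
  expect_equal(unname(as.character(sp$sequences)),
               substring(g, tab$seq_start + 1L, tab$seq_end))

  # short contig kept whole
  sp2 <- splitContig(random_dna(8000, seed = 2), "c1", "sA",
                     maxSize = 10000, minContigSize = 0)
  expect_equal(nrow(sp2$table), 1L)
  expect_false(sp2$table$excluded)
  expect_equal(sp2$table$core_end, 8000L)

  # below minimum size: single excluded subcontig
  sp3 <- splitContig(random_dna(9500, seed = 3), "c1", "sA",
                     maxSize = 10000, minContigSize = 10000)
  expect_true(sp3$table$excluded)
  expect_equal(nrow(sp3$table), 1L)
})

test_that("core tiling reconstructs the contig byte-for-byte", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(500:30000, 1)
    maxSize <- sample(300:12000, 1)
    g <- random_dna(L)
    sp <- splitContig(g, "c", "s", maxSize = maxSize, overlap = 500,
                      minContigSize = 0)
    tab <- sp$table
    o <- order(tab$core_start)
    expect_equal(tab$core_start[o][1], 0L)
    expect_equal(tab$core_end[o][nrow(tab)], L)
    if (nrow(tab) > 1)
      expect_equal(tab$core_start[o][-1], tab$core_end[o][-nrow(tab)])
    expect_true(all(tab$core_end - tab$core_start <=
                    ceiling(L / ceiling(L / maxSize))))
    cores <- substring(g, tab$core_start[o] + 1L, tab$core_end[o])
    expect_equal(paste(cores, collapse = ""), g)
  }
})

test_that("canonical k-mers use the lexicographically smaller strand", {
  expect_equal(canonicalKmers("ACGTA", 3), c("ACG", "ACG", "GTA"))
  expect_equal(canonicalKmers("ACNGT", 3), character(0))
  expect_equal(canonicalKmers("AC", 3), character(0))
  # hashes are stable and one per retained position
  h <- canonicalKmerHashes("ACGTA", 3)
  expect_length(h, 3)
  expect_equal(h[1], h[2])  # ACG twice
  expect_match(h, "^[0-9a-f]{16}$")
  # random agreement with the R re-derivation
  set.seed(11)
  for (k in c(5L, 7L, 31L)) {
    s <- random_dna(500)
    expect_equal(canonicalKmers(s, k), r_canonical_kmers(s, k))
  }
})

test_that("uniqueness counting matches the dictionary oracle", {
  # duplicated strain: every k-mer multiplicity >= 2
  s <- random_dna(400, seed = 5)
  expect_equal(buildUniquenessIndex(c(s, s), 31), c(0L, 0L))
  # within-sequence repeat is non-unique
  expect_equal(buildUniquenessIndex("AAAA", 3), 0L)
  # toy pair against the oracle
  toy <- c(S1 = "ACGTACCTG", S2 = "ACGTAGGTG")
  expect_equal(buildUniquenessIndex(toy, 5), oracle_unique_counts(toy, 5))
  # random communities, all three k values
  set.seed(19)
  for (k in c(5L, 7L, 31L)) {
    for (rep in 1:5) {
      seqs <- vapply(seq_len(sample(2:6, 1)),
                     function(i) random_dna(sample(100:800, 1)),
                     character(1))
      expect_equal(buildUniquenessIndex(seqs, k),
                   oracle_unique_counts(seqs, k))
    }
  }
})

test_that("adding a strain never increases unique counts; sum is bounded", {
  set.seed(23)
  base <- vapply(1:4, function(i) random_dna(600), character(1))
  k <- 7L
  before <- buildUniquenessIndex(base, k)
  kpos <- sum(pmax(0L, nchar(base) - k + 1L))
  expect_true(sum(before) <= kpos)
  for (i in 1:5) {
    extra <- if (i <= 2) base[sample(4, 1)] else random_dna(600)
    after <- buildUniquenessIndex(c(base, extra), k)
    expect_true(all(after[1:4] <= before))
  }
})

test_that("reference database round-trips and is deterministic", {
  set.seed(31)
  genomes <- list(
    sA = Biostrings::DNAStringSet(c(c1 = random_dna(4000),
                                    c2 = random_dna(2500))),
    sB = Biostrings::DNAStringSet(c(c1 = random_dna(5000))))
  db <- buildReferenceDatabase(genomes, maxSubcontigSize = 1500,
                               minContigSize = 1000, readSize = 50,
                               overlap = 100)
  expect_true(validObject(db))
  expect_equal(strainNames(db), c("sA", "sB"))
  expect_equal(kmerSize(db), 101L)

  d1 <- tempfile(); d2 <- tempfile()
  writeReferenceDatabase(db, d1)
  back <- readReferenceDatabase(d1)
  expect_equal(as.character(refSequences(back)),
               as.character(refSequences(db)))
  expect_equal(as.data.frame(subcontigTable(back)),
               as.data.frame(subcontigTable(db)))
  expect_equal(kmerSize(back), kmerSize(db))

  # identical inputs -> byte-identical database files
  db2 <- buildReferenceDatabase(genomes, maxSubcontigSize = 1500,
                                minContigSize = 1000, readSize = 50,
                                overlap = 100)
  writeReferenceDatabase(db2, d2)
  for (f in c("subcontigs.fasta", "kmer_counts.tsv", "db_meta.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(
    buildReferenceDatabase(list(sA = Biostrings::DNAStringSet("ACGT"),
                                sA = Biostrings::DNAStringSet("ACGT"))),
    "duplicate strain ID")
  expect_error(buildReferenceDatabase(character(0)), "no genomes")
  expect_error(buildReferenceDatabase("/nonexistent/str.fasta"),
               "str.fasta")

  # strain whose only contig is under the minimum size: present, excluded
  genomes <- list(
    big = Biostrings::DNAStringSet(c(c1 = random_dna(12000, seed = 1))),
    tiny = Biostrings::DNAStringSet(c(c1 = random_dna(2000, seed = 2))))
  expect_warning(
    db <- buildReferenceDatabase(genomes, maxSubcontigSize = 12000,
                                 minContigSize = 10000, readSize = 150),
    "tiny")
  tab <- subcontigTable(db)
  expect_true("tiny" %in% strainNames(db))
  expect_true(all(tab$excluded[tab$strain_id == "tiny"]))
  # excluded subcontigs still get a count
  expect_true(all(tab$unique_kmers[tab$strain_id == "tiny"] >= 0))
})

test_that("unique k-mer fraction is reported per strain", {
  s <- random_dna(2000, seed = 77)
  genomes <- list(
    a = Biostrings::DNAStringSet(c(c1 = s)),
    b = Biostrings::DNAStringSet(c(c1 = s)),  # clone of a
    c = Biostrings::DNAStringSet(c(c1 = random_dna(2000))))
  db <- buildReferenceDatabase(genomes, minContigSize = 0, readSize = 15)
  frac <- uniqueKmerFraction(db)
  expect_equal(names(frac), c("a", "b", "c"))
  expect_equal(unname(frac[c("a", "b")]), c(0, 0))
  expect_gt(frac[["c"]], 0.95)
})
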