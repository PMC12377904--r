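# Fixture: two divergent strains plus a clone sharing a verbatim region
# with strain A, so unique / ambiguous / unmapped verdicts all occur.
make_map_fixture <- function(seed = 101L, L = 6000L) {
  set.seed(seed)
  gA <- random_dna(L)
  gB <- random_dna(L)
  # clone C = A with a single substitution block in the middle only
  gC <- paste0(substring(gA, 1, 2999), random_dna(200), substring(gA, 3200))
  genomes <- list(
    sA = Biostrings::DNAStringSet(c(c1 = gA)),
    sB = Biostrings::DNAStringSet(c(c1 = gB)),
    sC = Biostrings::DNAStringSet(c(c1 = gC)))
  db <- buildReferenceDatabase(genomes, minContigSize = 0, readSize = 75)
  list(db = db, gA = gA, gB = gB, gC = gC)
}

draw_pairs <- function(genome, n, readLen = 75L, insert = 250L,
                       region = NULL) {
  L <- nchar(genome)
  lo <- if (is.null(region)) 0L else region[1]
  hi <- if (is.null(region)) L - insert else region[2] - insert
  start <- sample(seq.int(lo, hi), n, replace = TRUE)
  r1 <- substring(genome, start + 1L, start + readLen)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(genome, start + insert - readLen + 1L, start + insert))))
  list(r1 = r1, r2 = r2, start = start)
}

test_that("read filter trims poly-G and drops short or ambiguous mates", {
  good <- strrep("ACGT", 40)                       # 160 b
  withN <- paste0(strrep("ACGT", 20), "N", strrep("ACGT", 20))
  f <- filterReadPairs(c(good, good), c(good, withN))
  expect_equal(f$kept, c(TRUE, FALSE))             # one N -> dropped

  short <- strrep("AC", 20)                        # 40 b
  f2 <- filterReadPairs(short, good)
  expect_equal(f2$kept, FALSE)                     # under 50 b -> dropped

  polyg <- paste0(substring(good, 1, 138), strrep("G", 12))
  f3 <- filterReadPairs(polyg, good)
  expect_true(f3$kept)
  expect_equal(nchar(f3$r1), 138L)                 # 12 trailing Gs trimmed

  nine <- paste0(substring(good, 1, 141), strrep("G", 9))
  f4 <- filterReadPairs(nine, good)
  expect_equal(nchar(f4$r1), 150L)                 # run below threshold kept
})

test_that("exact mapper distinguishes unique, ambiguous, unmapped", {
  fx <- make_map_fixture()
  db <- fx$db
  tab <- subcontigTable(db)

  # unique: pair from strain B (divergent)
  set.seed(1)
  p <- draw_pairs(fx$gB, 20)
  v <- mapFragments(p$r1, p$r2, db)
  expect_true(all(v %in% tab$subcontig_id[tab$strain_id == "sB"]))

  # ambiguous: pair wholly inside the region A and its clone C share
  p2 <- draw_pairs(fx$gA, 20, region = c(3300L, 6000L))
  expect_true(all(mapFragments(p2$r1, p2$r2, db) == "ambiguous"))

  # unique to A: pair covering A's private block
  p3 <- draw_pairs(fx$gA, 20, region = c(2900L, 3300L))
  v3 <- mapFragments(p3$r1, p3$r2, db)
  expect_true(all(v3 %in% tab$subcontig_id[tab$strain_id == "sA"]))

  # a single substitution makes the pair unmapped (perfect mode)
  r1mut <- vapply(p$r1, substitute_base, character(1), pos = 30L,
                  USE.NAMES = FALSE)
  expect_true(all(mapFragments(r1mut, p$r2, db) == "unmapped"))

  # both mates on the forward strand: no convergent hit
  fwd2 <- substring(fx$gB, p$start + 176L, p$start + 250L)
  expect_true(all(mapFragments(p$r1, fwd2, db) == "unmapped"))
})

test_that("mapper verdicts match the naive all-offsets oracle", {
  fx <- make_map_fixture(seed = 55L, L = 3000L)
  set.seed(2)
  cases <- list(
    draw_pairs(fx$gA, 15),
    draw_pairs(fx$gB, 15),
    draw_pairs(fx$gC, 15))
  r1 <- unlist(lapply(cases, `[[`, "r1"))
  r2 <- unlist(lapply(cases, `[[`, "r2"))
  # inject errors into a third of them
  idx <- seq(1, length(r1), by = 3)
  r1[idx] <- vapply(r1[idx], substitute_base, character(1), pos = 40L,
                    USE.NAMES = FALSE)
  got <- mapFragments(r1, r2, fx$db)
  naive <- vapply(seq_along(r1), function(i)
    oracle_map_pair_naive(fx$db, r1[i], r2[i]), character(1))
  expect_equal(got, naive)
})

test_that("fragment counting conserves totals and ignores order", {
  fx <- make_map_fixture(seed = 77L)
  empty <- countFragments(character(0), character(0), fx$db)
  expect_equal(totalMapped(empty), 0L)
  expect_equal(totalInput(empty), 0L)
  expect_true(all(fragmentCounts(empty) == 0L))

  set.seed(3)
  p <- draw_pairs(fx$gB, 200)
  c1 <- countFragments(p$r1, p$r2, fx$db)
  expect_equal(totalMapped(c1), sum(fragmentCounts(c1)))
  expect_lte(totalMapped(c1), totalInput(c1))
  expect_equal(totalInput(c1), 200L)

  perm <- sample(200)
  c2 <- countFragments(p$r1[perm], p$r2[perm], fx$db)
  expect_identical(fragmentCounts(c1), fragmentCounts(c2))
})

test_that("raising the substitution rate never increases mapped totals", {
  fx <- make_map_fixture(seed = 88L)
  set.seed(4)
  p <- draw_pairs(fx$gB, 300)
  # couple error draws across rates through one uniform matrix
  u1 <- matrix(runif(300 * 75), 300)
  u2 <- matrix(runif(300 * 75), 300)
  mutate_at <- function(reads, u, rate) {
    vapply(seq_along(reads), function(i) {
      s <- reads[i]
      for (j in which(u[i, ] < rate)) s <- substitute_base(s, j)
      s
    }, character(1))
  }
  mapped <- vapply(c(0, 0.002, 0.01, 0.05), function(rate) {
    cnt <- countFragments(mutate_at(p$r1, u1, rate),
                          mutate_at(p$r2, u2, rate), fx$db,
                          filter = FALSE)
    totalMapped(cnt)
  }, integer(1))
  expect_true(all(diff(mapped) <= 0L))
  expect_gt(mapped[1], mapped[4])
})

test_that("fragments inside a region shared verbatim are never counted", {
  fx <- make_map_fixture(seed = 99L)
  set.seed(5)
  p <- draw_pairs(fx$gA, 100, region = c(3300L, 6000L))
  cnt <- countFragments(p$r1, p$r2, fx$db, filter = FALSE)
  expect_equal(totalMapped(cnt), 0L)
})

test_that("SAM import applies the perfect-proper-pair contract", {
  fx <- make_map_fixture(seed = 111L)
  db <- fx$db
  tab <- subcontigTable(db)
  sq <- tab$subcontig_id[1]
  len <- subcontigTable(db)$seq_length[1]
  ref <- as.character(refSequences(db)[[1]])
  r1 <- substring(ref, 101, 175)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(ref, 251, 325))))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", sq, "\tLN:", len))
  rec <- function(qname, flag, pos, cigar, seqs, nm = "NM:i:0")
    paste(qname, flag, sq, pos, 60, cigar, "=",
          ifelse(flag == 99, 251, 101), 225, seqs, "*", nm, sep = "\t")
  samOk <- tempfile(fileext = ".sam")
  writeLines(c(hdr,
               rec("frag1", 99, 101, "75M", r1),
               rec("frag1", 147, 251, "75M", as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(r2))))),
             samOk)
  cnt <- importSamCounts(samOk, db)
  expect_equal(unname(fragmentCounts(cnt)[sq]), 1L)
  expect_equal(totalMapped(cnt), 1L)

  # soft-clipped alignment: not full-length, not counted
  samClip <- tempfile(fileext = ".sam")
  writeLines(c(hdr,
               rec("frag1", 99, 101, "5S70M", r1),
               rec("frag1", 147, 251, "75M", as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(r2))))),
             samClip)
  expect_equal(totalMapped(importSamCounts(samClip, db)), 0L)

  # secondary records only: ignored entirely
  samSec <- tempfile(fileext = ".sam")
  writeLines(c(hdr,
               rec("frag1", 355, 101, "75M", r1),
               rec("frag1", 403, 251, "75M", as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(r2))))),
             samSec)
  expect_equal(totalMapped(importSamCounts(samSec, db)), 0L)

  # unknown reference name -> error naming it
  samBad <- tempfile(fileext = ".sam")
  writeLines(c(hdr[1], "@SQ\tSN:not_a_subcontig\tLN:1000",
               paste("frag1", 99, "not_a_subcontig", 1, 60, "75M", "=",
                     251, 325, r1, "*", "NM:i:0", sep = "\t"),
               paste("frag1", 147, "not_a_subcontig", 251, 60, "75M", "=",
                     1, -325, r1, "*", "NM:i:0", sep = "\t")),
             samBad)
  expect_error(importSamCounts(samBad, db), "not_a_subcontig")

  # missing NM tag -> instructive error
  samNoNM <- tempfile(fileext = ".sam")
  writeLines(c(hdr,
               sub("\tNM:i:0", "", rec("frag1", 99, 101, "75M", r1)),
               sub("\tNM:i:0", "",
                   rec("frag1", 147, 251, "75M", as.character(
                     Biostrings::reverseComplement(
                       Biostrings::DNAString(r2)))))),
             samNoNM)
  expect_error(importSamCounts(samNoNM, db), "NM")
})
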