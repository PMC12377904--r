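# Synthetic community and read simulator: controlled strain relatedness,
# controlled assembly fragmentation, six abundance distributions, and
# substitution-only paired-end reads. All randomness flows from explicit
# seeds so every artifact is reproducible.

.BASES <- c("A", "C", "G", "T")

#' Generate an ancestor genome
#'
#' I.i.d. bases at the stated GC content; deterministic per seed.
#'
#' @param length genome length in bases.
#' @param gc GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return a single character string.
#' @export
generateAncestor <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, length, replace = TRUE, prob = prob), collapse = "")
}

#' Derive a strain by point substitution
#'
#' Each position is substituted to one of the three other bases with the
#' stated probability, emulating pairs of isolates at a controlled average
#' nucleotide divergence (near-clonal strains of one species down to
#' divergent lineages).
#'
#' @param parent parent genome (character string).
#' @param divergence substitution probability per base, in [0, 0.5].
#' @param seed RNG seed.
#' @return mutated genome string.
#' @export
mutateStrain <- function(parent, divergence, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  if (divergence == 0) return(parent)
  set.seed(seed)
  x <- strsplit(parent, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < divergence)
  if (length(hit)) {
    # draw uniformly among the three other bases
    cur <- match(x[hit], .BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

#' Add substitution errors to reads
#'
#' Substitutes each base independently with probability \code{rate}; used by
#' the read simulator for sequencing error.
#'
#' @param seqs character vector of sequences.
#' @param rate per-base substitution probability.
#' @return character vector with errors applied.
#' @export
addSubstitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(x)) < rate)
    if (length(hit)) {
      cur <- match(x[hit], .BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      x[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    paste(x, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Fragment a genome into contigs with a target N50
#'
#' Cuts the genome at random positions so the resulting contig lengths have
#' an N50 within a factor of two of the target; concatenating the contigs
#' reconstructs the genome exactly. Emulates assemblies of varying build
#' quality.
#'
#' @param genome genome string.
#' @param targetN50 target N50 in bases (at most the genome length).
#' @param seed RNG seed.
#' @return character vector of contig sequences, in genome order.
#' @export
fragmentAssembly <- function(genome, targetN50, seed = 1L) {
  L <- nchar(genome)
  stopifnot(targetN50 > 0, targetN50 <= L)
  m <- max(1L, as.integer(round(L / targetN50)))
  if (m == 1L) return(genome)
  set.seed(seed)
  lens <- NULL
  for (attempt in seq_len(100L)) {
    cuts <- sort(sample.int(L - 1L, m - 1L))
    cand <- diff(c(0L, cuts, L))
    if (computeN50(cand) >= 0.5 * targetN50 &&
        computeN50(cand) <= 2 * targetN50) { lens <- cand; break }
  }
  if (is.null(lens)) {  # deterministic equal split always lands in band
    lens <- diff(round(seq(0, L, length.out = m + 1L)))
  }
  ends <- cumsum(lens)
  starts <- c(0, ends[-length(ends)])
  substring(genome, starts + 1L, ends)
}

#' Draw a true abundance vector
#'
#' The six community scenarios: \code{uniform} (all equal);
#' \code{log-normal} (exp of a normal, renormalized);
#' \code{zero-inflated-log-normal} (each strain absent with probability
#' \code{pi0}, else log-normal); \code{exponential} (Exp(1) draws);
#' \code{log-step} (tiers separated by a constant fold step); and
#' \code{missing} (uniform with a subset absent).
#'
#' @param distribution one of \code{"uniform"}, \code{"log-normal"},
#'   \code{"zero-inflated-log-normal"}, \code{"exponential"},
#'   \code{"log-step"}, \code{"missing"}.
#' @param n number of strains.
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters (defaults 0, 1).
#' @param pi0 absence probability for the zero-inflated case (default 0.3).
#' @param tiers,step log-step tier count and fold separation (defaults 2
#'   tiers, 30-fold).
#' @param absent indices set to zero for \code{"missing"}; default drops
#'   each strain with probability 0.2.
#' @return numeric vector summing to 1 (absent strains 0).
#' @export
drawAbundances <- function(distribution, n, seed = 1L, meanlog = 0,
                           sdlog = 1, pi0 = 0.3, tiers = 2L, step = 30,
                           absent = NULL) {
  stopifnot(n >= 1)
  distribution <- match.arg(distribution,
    c("uniform", "log-normal", "zero-inflated-log-normal", "exponential",
      "log-step", "missing"))
  set.seed(seed)
  x <- switch(distribution,
    "uniform" = rep(1, n),
    "log-normal" = stats::rlnorm(n, meanlog, sdlog),
    "zero-inflated-log-normal" = {
      present <- stats::runif(n) >= pi0
      ifelse(present, stats::rlnorm(n, meanlog, sdlog), 0)
    },
    "exponential" = stats::rexp(n, 1),
    "log-step" = {
      tier <- ceiling(seq_len(n) / ceiling(n / tiers))
      step^(tiers - tier)
    },
    "missing" = {
      if (is.null(absent)) absent <- which(stats::runif(n) < 0.2)
      v <- rep(1, n)
      v[absent] <- 0
      v
    })
  if (sum(x) == 0) stop("all strains drawn absent; nothing to simulate")
  x / sum(x)
}

#' Construct a community design
#'
#' @param genomes named \link[Biostrings]{DNAStringSet} (or named character
#'   vector), one full genome per strain.
#' @param abundances numeric vector summing to 1, aligned with
#'   \code{genomes}.
#' @param contigLengths optional list of per-strain contig lengths (default:
#'   single-contig assemblies).
#' @param strainInfo optional \link[S4Vectors]{DataFrame} of provenance
#'   (\code{strain_id}, \code{parent_id}, \code{divergence}).
#' @param distribution label for the abundance scenario.
#' @param readLength,insertMean,insertSd,errorRate read simulation
#'   parameters (defaults 150 b mates, insert 400 +/- 50, error-free).
#' @param nFragments total read pairs to emit.
#' @param seed RNG seed for read simulation.
#' @return a [CommunityDesign].
#' @export
communityDesign <- function(genomes, abundances, contigLengths = NULL,
                            strainInfo = NULL, distribution = "custom",
                            readLength = 150L, insertMean = 400,
                            insertSd = 50, errorRate = 0, nFragments,
                            seed = 1L) {
  if (!methods::is(genomes, "DNAStringSet"))
    genomes <- Biostrings::DNAStringSet(unlist(genomes))
  if (is.null(contigLengths))
    contigLengths <- as.list(Biostrings::width(genomes))
  if (is.null(strainInfo))
    strainInfo <- S4Vectors::DataFrame(strain_id = names(genomes),
                                       parent_id = NA_character_,
                                       divergence = NA_real_)
  names(abundances) <- names(genomes)
  new("CommunityDesign", genomes = genomes,
      contigLengths = lapply(contigLengths, as.integer),
      strainInfo = strainInfo,
      abundances = abundances, distribution = distribution,
      readLength = as.integer(readLength), insertMean = insertMean,
      insertSd = insertSd, errorRate = errorRate,
      nFragments = as.integer(nFragments), seed = as.integer(seed))
}

#' Assembly contigs of a design
#'
#' The reference-side view of a design: each genome split into its assembly
#' contigs, as input for [buildReferenceDatabase()].
#'
#' @param design a [CommunityDesign].
#' @return named list of \link[Biostrings]{DNAStringSet}, one per strain.
#' @export
designContigs <- function(design) {
  out <- lapply(seq_along(design@genomes), function(i) {
    g <- as.character(design@genomes[[i]])
    lens <- design@contigLengths[[i]]
    ends <- cumsum(lens)
    starts <- c(0L, ends[-length(ends)])
    s <- Biostrings::DNAStringSet(substring(g, starts + 1L, ends))
    names(s) <- sprintf("c%d", seq_along(lens))
    s
  })
  names(out) <- names(design@genomes)
  out
}

#' Uniform community with divergent lineages and near-clonal pairs
#'
#' The benchmark scenario for uniqueness normalization: from one ancestor,
#' \code{nLineages + nPairs} lineages are derived at \code{lineageDivergence}
#' substitutions per base (pairwise divergence about twice that), and the
#' first \code{nPairs} lineages each receive a near-clonal partner at
#' \code{cloneDivergence}. Assemblies are fragmented to \code{targetN50},
#' abundances are uniform, and error-free paired reads are emitted at
#' \code{coverage} mean per-strain depth.
#'
#' Defaults: 100 kb genomes, 4 singleton lineages plus 4 clone pairs
#' (12 strains), 5\% lineage divergence, 0.2\% clone divergence (a few
#' hundred substitutions per 100 kb, typical of same-species isolates),
#' 20 kb target N50, 40x coverage.
#'
#' @param seed master seed; lineage, fragmentation and read seeds are
#'   derived from it by fixed offsets.
#' @param nLineages singleton lineages (default 4).
#' @param nPairs near-clonal pairs (default 4).
#' @param genomeLength ancestor length in bases (default 1e5).
#' @param gc GC fraction (default 0.5).
#' @param lineageDivergence per-lineage divergence from the ancestor
#'   (default 0.05).
#' @param cloneDivergence within-pair divergence (default 0.002).
#' @param targetN50 assembly fragmentation target (default 2e4).
#' @param coverage mean per-strain fold coverage (default 40).
#' @param readLength,insertMean,insertSd,errorRate read parameters.
#' @return a [CommunityDesign].
#' @export
uniformCloneDesign <- function(seed = 1L, nLineages = 4L, nPairs = 4L,
                               genomeLength = 100000L, gc = 0.5,
                               lineageDivergence = 0.05,
                               cloneDivergence = 0.002,
                               targetN50 = 20000L, coverage = 40,
                               readLength = 150L, insertMean = 400,
                               insertSd = 50, errorRate = 0) {
  seed <- as.integer(seed) %% 100000L
  root <- generateAncestor(genomeLength, gc, seed = seed * 7L + 11L)
  nTotalLineages <- nLineages + nPairs
  lineages <- lapply(seq_len(nTotalLineages), function(i)
    mutateStrain(root, lineageDivergence, seed = seed * 7L + 100L + i))
  strains <- list()
  info <- list()
  for (i in seq_len(nPairs)) {
    a <- sprintf("pair%d_a", i); b <- sprintf("pair%d_b", i)
    strains[[a]] <- lineages[[i]]
    strains[[b]] <- mutateStrain(lineages[[i]], cloneDivergence,
                                 seed = seed * 7L + 200L + i)
    info[[a]] <- c("root", lineageDivergence)
    info[[b]] <- c(a, cloneDivergence)
  }
  for (i in seq_len(nLineages)) {
    s <- sprintf("lineage%d", i)
    strains[[s]] <- lineages[[nPairs + i]]
    info[[s]] <- c("root", lineageDivergence)
  }
  genomes <- Biostrings::DNAStringSet(unlist(strains))
  contigs <- lapply(seq_along(strains), function(i)
    nchar(fragmentAssembly(strains[[i]], targetN50,
                           seed = seed * 7L + 300L + i)))
  n <- length(strains)
  nFrag <- ceiling(coverage * n * genomeLength / (2 * readLength))
  communityDesign(genomes,
                  abundances = rep(1 / n, n),
                  contigLengths = contigs,
                  strainInfo = S4Vectors::DataFrame(
                    strain_id = names(strains),
                    parent_id = vapply(info, `[`, character(1), 1L),
                    divergence = as.numeric(vapply(info, `[`,
                                                   character(1), 2L))),
                  distribution = "uniform",
                  readLength = readLength, insertMean = insertMean,
                  insertSd = insertSd, errorRate = errorRate,
                  nFragments = nFrag, seed = seed * 7L + 400L)
}

#' Divergent community with a drawn abundance composition
#'
#' Benchmark scenario for composition recovery: \code{n} divergent strains
#' (independent lineages from one ancestor at \code{lineageDivergence},
#' pairwise divergence about twice that), abundances drawn from one of the
#' six scenario distributions, read depth set so the least abundant present
#' strain reaches \code{minPresentCoverage} fold coverage.
#'
#' @param distribution passed to [drawAbundances()].
#' @param seed master seed.
#' @param n number of strains (default 10).
#' @param genomeLength genome length (default 3e4).
#' @param lineageDivergence divergence from the shared ancestor
#'   (default 0.05).
#' @param minPresentCoverage fold coverage guaranteed to the least abundant
#'   present strain (default 12).
#' @param readLength,insertMean,insertSd,errorRate read parameters.
#' @param ... further arguments to [drawAbundances()].
#' @return a [CommunityDesign].
#' @export
compositionDesign <- function(distribution, seed = 1L, n = 10L,
                              genomeLength = 30000L,
                              lineageDivergence = 0.05,
                              minPresentCoverage = 12,
                              readLength = 150L, insertMean = 400,
                              insertSd = 50, errorRate = 0, ...) {
  seed <- as.integer(seed) %% 100000L
  root <- generateAncestor(genomeLength, 0.5, seed = seed * 13L + 17L)
  strains <- lapply(seq_len(n), function(i)
    mutateStrain(root, lineageDivergence, seed = seed * 13L + 100L + i))
  names(strains) <- sprintf("strain%02d", seq_len(n))
  ab <- drawAbundances(distribution, n, seed = seed * 13L + 500L, ...)
  # equal genome lengths: per-strain coverage = 2*readLength*nFrag*a_i / L
  minA <- min(ab[ab > 0])
  nFrag <- ceiling(minPresentCoverage * genomeLength /
                   (2 * readLength * minA))
  communityDesign(Biostrings::DNAStringSet(unlist(strains)),
                  abundances = ab, distribution = distribution,
                  readLength = readLength, insertMean = insertMean,
                  insertSd = insertSd, errorRate = errorRate,
                  nFragments = nFrag, seed = seed * 13L + 900L)
}

#' Simulate paired-end reads from a community design
#'
#' Fragments are allotted to strains by a multinomial draw with weights
#' proportional to abundance times genome length (so expected coverage is
#' proportional to abundance); fragment starts are uniform on the genome;
#' insert lengths are normal, truncated to [2 x read length, genome length];
#' mates are read inward from opposite strands; substitution errors are
#' i.i.d. at the design's error rate. Byte-identical output per seed.
#'
#' @param design a [CommunityDesign].
#' @return list with \code{r1}, \code{r2}
#'   (\link[Biostrings]{DNAStringSet}, names \code{strain|serial}) and
#'   \code{truth} (\link[S4Vectors]{DataFrame}: \code{strain_id},
#'   \code{true_abundance}, \code{fragments}).
#' @export
simulateReads <- function(design) {
  set.seed(design@seed)
  genomes <- as.character(design@genomes)
  L <- nchar(genomes)
  rl <- design@readLength
  if (any(L < 2 * rl)) stop("genome shorter than one fragment")
  w <- design@abundances * L
  nPer <- as.vector(stats::rmultinom(1, design@nFragments, w))
  r1 <- r2 <- character(0)
  ids <- character(0)
  for (i in seq_along(genomes)) {
    n <- nPer[i]
    if (n == 0L) next
    ins <- round(stats::rnorm(n, design@insertMean, design@insertSd))
    bad <- which(ins < 2 * rl | ins > L[i])
    tries <- 0L
    while (length(bad)) {
      tries <- tries + 1L
      if (tries > 1000L) stop("cannot draw insert sizes inside the genome")
      ins[bad] <- round(stats::rnorm(length(bad), design@insertMean,
                                     design@insertSd))
      bad <- bad[ins[bad] < 2 * rl | ins[bad] > L[i]]
    }
    start <- floor(stats::runif(n) * (L[i] - ins + 1))  # 0-based
    a <- substring(genomes[i], start + 1L, start + rl)
    b <- substring(genomes[i], start + ins - rl + 1L, start + ins)
    b <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(b)))
    if (design@errorRate > 0) {
      a <- addSubstitutions(a, design@errorRate)
      b <- addSubstitutions(b, design@errorRate)
    }
    r1 <- c(r1, a)
    r2 <- c(r2, b)
    ids <- c(ids, sprintf("%s|%d", names(design@genomes)[i], seq_len(n)))
  }
  r1 <- Biostrings::DNAStringSet(r1)
  r2 <- Biostrings::DNAStringSet(r2)
  names(r1) <- names(r2) <- ids
  list(r1 = r1, r2 = r2,
       truth = S4Vectors::DataFrame(
         strain_id = names(design@genomes),
         true_abundance = as.numeric(design@abundances),
         fragments = nPer))
}

#' Write simulated reads and truth to disk
#'
#' Writes \code{sim_R1.fastq}, \code{sim_R2.fastq} (constant quality,
#' uncompressed so repeated runs are byte-identical), \code{truth.tsv}, and
#' per-strain assembly FASTAs under \code{genomes/} ready for
#' [buildReferenceDatabase()].
#'
#' @param design a [CommunityDesign].
#' @param sim result of [simulateReads()] on \code{design}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeSimulatedReads <- function(design, sim, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(sim$r1)))
  q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(sim$r2)))
  Biostrings::writeXStringSet(sim$r1, file.path(dir, "sim_R1.fastq"),
                              format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(sim$r2, file.path(dir, "sim_R2.fastq"),
                              format = "fastq", qualities = q2)
  utils::write.table(as.data.frame(sim$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  contigs <- designContigs(design)
  for (s in names(contigs))
    Biostrings::writeXStringSet(contigs[[s]],
                                file.path(dir, "genomes",
                                          paste0(s, ".fasta")))
  invisible(dir)
}
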