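#' Jensen-Shannon divergence (base 2)
#'
#' \eqn{JSD(p, q) = KL(p\|m)/2 + KL(q\|m)/2} with \eqn{m = (p+q)/2},
#' logarithms base 2 (so values lie in [0, 1]; 0 means identical
#' compositions) and the \eqn{0 \log 0 = 0} convention, under which strains
#' absent from both vectors contribute nothing.
#'
#' @param p,q non-negative vectors of equal length; normalized to sum 1
#'   before comparison.
#' @return divergence in [0, 1].
#' @examples
#' jsDivergence(c(1, 0), c(0.5, 0.5))  # 0.311278
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  stopifnot(all(p >= 0), all(q >= 0), sum(p) > 0, sum(q) > 0)
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Coefficient of variation, in percent
#'
#' 100 times the sample standard deviation (n-1 denominator) over the mean;
#' the flatness benchmark for uniform-abundance communities (0 for a
#' perfectly uniform estimate).
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return percent CV.
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("coefficient of variation undefined for mean <= 0")
  100 * stats::sd(values) / m
}

#' Pearson correlation of log10 abundances
#'
#' Both vectors are log10-transformed; zeros (-Inf in log space) are
#' substituted with the minimum finite log10 value across both vectors
#' minus 1, then the ordinary Pearson correlation is taken.
#'
#' @param truth,estimate abundance vectors of equal length (n >= 3).
#' @return correlation; NA with a warning when a transformed vector is
#'   constant.
#' @export
logPearson <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("truth and estimate must have equal length")
  if (length(truth) < 3L) stop("need at least three strains")
  lt <- log10(truth)
  le <- log10(estimate)
  finite <- c(lt[is.finite(lt)], le[is.finite(le)])
  if (length(finite) == 0L) stop("all abundances are zero")
  sub <- min(finite) - 1
  lt[!is.finite(lt)] <- sub
  le[!is.finite(le)] <- sub
  if (stats::sd(lt) == 0 || stats::sd(le) == 0) {
    warning("constant vector after log transform; correlation undefined")
    return(NA_real_)
  }
  stats::cor(lt, le)
}

#' Fold-range: max over min
#'
#' @param values positive numeric vector.
#' @return max(values)/min(values), >= 1.
#' @export
foldRange <- function(values) {
  if (any(values <= 0)) stop("fold range requires positive values")
  max(values) / min(values)
}

#' Presence/absence precision, recall and F1
#'
#' "Present" is the positive class; a strain is called present when its
#' reported abundance is greater than zero.
#'
#' @param truthPresent,calledPresent logical vectors of equal length.
#' @return named numeric: \code{precision}, \code{recall}, \code{f1}
#'   (NA where undefined).
#' @export
presenceF1 <- function(truthPresent, calledPresent) {
  if (length(truthPresent) != length(calledPresent))
    stop("vectors must have equal length")
  tp <- sum(truthPresent & calledPresent)
  fp <- sum(!truthPresent & calledPresent)
  fn <- sum(truthPresent & !calledPresent)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Benchmark the full pipeline on simulated designs
#'
#' For each design: simulate reads, build the reference from the design's
#' assembly contigs, count perfect-unique fragments, quantify, and score
#' both the wpFUKM estimate and the FPKM baseline against the truth. CV and
#' fold-range are reported for uniform designs, presence/recall/F1 for
#' designs containing absent strains; JSD and log-Pearson always.
#'
#' @param designs list of [CommunityDesign] objects (names become design
#'   labels).
#' @param percentile wpFUKM percentile (default 60).
#' @param minContigSize,overlap,maxSubcontigSize reference build parameters
#'   (defaults 10000, 500, smallest N50).
#' @return \link[S4Vectors]{DataFrame}, one row per design x estimator.
#' @export
benchmarkRun <- function(designs, percentile = 60, minContigSize = 10000L,
                         overlap = 500L, maxSubcontigSize = NULL) {
  if (is.null(names(designs)))
    names(designs) <- sprintf("design%d", seq_along(designs))
  rows <- list()
  for (nm in names(designs)) {
    design <- designs[[nm]]
    db <- buildReferenceDatabase(designContigs(design),
                                 maxSubcontigSize = maxSubcontigSize,
                                 minContigSize = minContigSize,
                                 readSize = design@readLength,
                                 overlap = overlap)
    sim <- simulateReads(design)
    counts <- countFragments(sim$r1, sim$r2, db)
    report <- strainAbundance(db, counts, percentile = percentile)
    tab <- report@strains[match(names(design@genomes),
                                report@strains$strain_id), ]
    truth <- as.numeric(design@abundances)
    for (est in c("wpFUKM", "FPKM")) {
      v <- if (est == "wpFUKM") tab$wpfukm else tab$fpkm
      share <- if (sum(v) > 0) v / sum(v) else v
      uniform <- design@distribution == "uniform"
      hasAbsent <- any(truth == 0)
      pr <- if (hasAbsent) presenceF1(truth > 0, v > 0)
            else c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
      rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
        design = nm,
        distribution = design@distribution,
        estimator = est,
        jsd = if (sum(share) > 0) jsDivergence(truth, share) else NA_real_,
        cv_pct = if (uniform && all(v > 0)) coefficientOfVariation(v)
                 else NA_real_,
        fold_range = if (all(v > 0)) foldRange(v) else NA_real_,
        # constant compositions (uniform/missing) carry no correlation signal
        log_pearson = if (length(unique(truth)) > 1)
          logPearson(truth, share) else NA_real_,
        precision = pr[["precision"]],
        recall = pr[["recall"]],
        f1 = pr[["f1"]])
    }
  }
  do.call(rbind, rows)
}
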