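#' Euler region counts for three sets
#'
#' Exact cardinalities of the 7 regions of a three-set Euler/Venn diagram
#' (A-only, B-only, C-only, AB, AC, BC, ABC) within a universe.
#'
#' @param setA,setB,setC character vectors, subsets of `universe`.
#' @param universe all element ids.
#' @return named integer vector with the 7 region counts plus
#'   `outside` (universe members in no set) and `universe`.
#' @export
euler_regions <- function(setA, setB, setC, universe) {
  sets <- list(A = unique(setA), B = unique(setB), C = unique(setC))
  for (nm in names(sets)) {
    if (!all(sets[[nm]] %in% universe)) {
      rhythmod_stop("setstats", sprintf("set %s has elements outside the universe", nm))
    }
  }
  inA <- universe %in% sets$A
  inB <- universe %in% sets$B
  inC <- universe %in% sets$C
  c(A_only = sum(inA & !inB & !inC),
    B_only = sum(!inA & inB & !inC),
    C_only = sum(!inA & !inB & inC),
    AB = sum(inA & inB & !inC),
    AC = sum(inA & !inB & inC),
    BC = sum(!inA & inB & inC),
    ABC = sum(inA & inB & inC),
    outside = sum(!inA & !inB & !inC),
    universe = length(universe))
}

#' Hypergeometric over/under-representation test
#'
#' For a category with `K` members in a background of size `N`, and `k` hits
#' in a foreground of size `n`, computes the upper-tail probability
#' `p_over = P(X >= k)` and lower-tail `p_under = P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  The category is called overrepresented
#' when `p_over < 0.05` and underrepresented when `p_over > 0.95`.
#'
#' @param k category hits in the foreground.
#' @param n foreground size.
#' @param K category size in the background.
#' @param N background size.
#' @param alpha call threshold (default 0.05, with 1 - alpha for "under").
#' @return list with `k`, `n`, `K`, `N`, `p_over`, `p_under`, `call`.
#' @export
hypergeom_over_under <- function(k, n, K, N, alpha = 0.05) {
  if (k > n || n > N || k > K || K > N || k < 0) {
    rhythmod_stop("setstats", "inconsistent counts: need k <= min(n, K), n <= N, K <= N")
  }
  p_over <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_under <- stats::phyper(k, K, N - K, n)
  call <- if (p_over < alpha) "over" else if (p_over > 1 - alpha) "under" else "none"
  list(k = k, n = n, K = K, N = N, p_over = p_over, p_under = p_under,
       call = call)
}

#' Category enrichment of a foreground set
#'
#' Runs [hypergeom_over_under()] for every category of an annotation table,
#' comparing category frequency in the foreground against the background
#' (e.g. rhythmic vs expressed transcripts, or expressed vs the whole
#' array).  No multiple-testing correction is applied across categories.
#'
#' @param foreground foreground transcript ids (subset of background).
#' @param background background transcript ids.
#' @param annotation data frame `transcript_id`, `category` (one row per id).
#' @param exclude categories ignored (default `"unannotated"`).
#' @return data frame: `category`, `k`, `n`, `K`, `N`, `p_over`, `p_under`,
#'   `call`.
#' @export
enrich_categories <- function(foreground, background, annotation,
                              exclude = "unannotated") {
  if (!all(foreground %in% background)) {
    rhythmod_stop("setstats", "foreground must be a subset of the background")
  }
  if (anyDuplicated(annotation$transcript_id)) {
    rhythmod_stop("setstats", "annotation must list each transcript once")
  }
  ann <- annotation[annotation$transcript_id %in% background &
                      !(annotation$category %in% exclude), , drop = FALSE]
  cats <- sort(unique(ann$category))
  N <- length(background)
  n <- length(foreground)
  rows <- lapply(cats, function(cc) {
    ids <- ann$transcript_id[ann$category == cc]
    res <- hypergeom_over_under(sum(foreground %in% ids), n, length(ids), N)
    data.frame(category = cc, k = res$k, n = res$n, K = res$K, N = res$N,
               p_over = res$p_over, p_under = res$p_under, call = res$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson chi-square test against reference proportions
#'
#' Compares observed category counts with expected counts
#' `E = total * reference_props` (e.g. two Euler diagrams, one turned into
#' proportions).
#'
#' @param observed non-negative category counts (total > 0).
#' @param reference_props reference proportions summing to 1.
#' @return list with `statistic`, `df`, `p_value`, `n`.
#' @export
chisq_compare <- function(observed, reference_props) {
  if (length(observed) != length(reference_props)) {
    rhythmod_stop("setstats", "observed and reference lengths differ")
  }
  if (abs(sum(reference_props) - 1) > 1e-8) {
    rhythmod_stop("setstats", "reference proportions must sum to 1")
  }
  total <- sum(observed)
  if (total <= 0) rhythmod_stop("setstats", "observed total must be positive")
  expected <- total * reference_props
  if (any(expected == 0)) {
    rhythmod_stop("setstats", "zero expected count; pool categories before testing")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), n = total)
}

#' Histogram of peak times
#'
#' Counts phases in half-open bins `[b, b + bin_h)` covering one period.
#'
#' @param phases phases in hours (wrapped into `[0, period)`).
#' @param bin_h bin width; must divide the period.
#' @param period_h cycle length.
#' @return named integer vector of counts, names `ZT00`, `ZT02`, ...
#' @export
phase_histogram <- function(phases, bin_h = 2, period_h = 24) {
  if (period_h %% bin_h != 0) {
    rhythmod_stop("setstats", "bin width must divide the period")
  }
  starts <- seq(0, period_h - bin_h, by = bin_h)
  idx <- floor((phases %% period_h) / bin_h) + 1
  counts <- tabulate(idx, nbins = length(starts))
  stats::setNames(counts, sprintf("ZT%02d", starts))
}

#' Percentage rounded to one decimal
#'
#' `100 * count / total`, rounded half away from zero to one decimal, the
#' convention used for reported percentages.
#'
#' @param count numerator (0 <= count <= total).
#' @param total denominator (> 0).
#' @return percentage with one decimal.
#' @examples
#' percent(6705, 9822)  # 68.3
#' @export
percent <- function(count, total) {
  if (any(total <= 0)) rhythmod_stop("setstats", "total must be positive")
  if (any(count < 0) || any(count > total)) {
    rhythmod_stop("setstats", "count must be in [0, total]")
  }
  x <- 1000 * count / total
  trunc(x + 0.5 * sign(x)) / 10
}

#' Fraction of phases peaking in the light interval
#'
#' A phase counts as a day peak when it is strictly before dusk
#' (`phase < photoperiod_h`); a phase exactly at dusk counts as night.
#'
#' @param phases phases in `[0, period)`.
#' @param photoperiod_h light interval length, hours.
#' @return proportion in `[0, 1]`.
#' @export
day_night_fraction <- function(phases, photoperiod_h) {
  if (length(phases) == 0) return(NA_real_)
  mean(phases < photoperiod_h)
}
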