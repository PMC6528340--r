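#' @include metrics-tfd.R
NULL

#' Energy difference against a reference search
#'
#' `search - reference`, in kcal/mol: negative values mean the search found
#' a better (lower-energy) conformation than the reference method.
#'
#' @param searchBest,referenceBest energies in kcal/mol, or
#'   [SearchResult-class] objects (their best energies are used).
#' @return numeric difference.
#' @export
deltaE <- function(searchBest, referenceBest) {
  e1 <- if (is(searchBest, "SearchResult")) bestEnergy(searchBest) else searchBest
  e2 <- if (is(referenceBest, "SearchResult")) bestEnergy(referenceBest) else referenceBest
  e1 - e2
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped (signed-rank convention); at least 5
#' informative pairs are required. The exact distribution is used for up to
#' 25 informative pairs without ties in the absolute differences; otherwise
#' the normal approximation with continuity and tie correction applies. The
#' conventional decision threshold in this package's benchmarks is a 5%
#' significance level.
#'
#' @param x,y equal-length paired samples.
#' @return list with `p.value`, `statistic` (V), `n` (informative pairs) and
#'   `method` (`"exact"` or `"approximate"`).
#' @export
pairedWilcoxon <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must be paired samples of equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5)
    stop(errorCondition(
      paste0("insufficient informative pairs for the signed-rank test (",
             n, " after dropping zero differences; at least 5 required)"),
      class = c("torsbo_insufficient_pairs_error", "error")))
  ties <- any(duplicated(abs(d)))
  useExact <- n <= 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    d, alternative = "two.sided", mu = 0, exact = useExact,
    correct = !useExact))
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic), n = n,
       method = if (useExact) "exact" else "approximate")
}
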