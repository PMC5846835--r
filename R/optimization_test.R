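#' @include alt_codes.R impact_metrics.R
NULL

#' Empirical cumulative-distribution p-value
#'
#' Proportion of ensemble values less than or equal to the observed value
#' (ties count as <=, the standard empirical CDF convention).  For a
#' category whose impact the canonical code minimizes, small p means the
#' canonical value sits in the lower tail of the alternative-code
#' distribution; 1 - p is the fraction of alternatives it outperforms.
#'
#' @param observed Scalar observed value.
#' @param ensemble Non-empty numeric vector of ensemble values.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' ecdf_p(2, 1:10)  # 0.2
ecdf_p <- function(observed, ensemble) {
  stopifnot(length(observed) == 1L, is.finite(observed))
  if (length(ensemble) == 0L) stop("ensemble must be non-empty")
  mean(ensemble <= observed)
}

# Vectorized scan over all 13,824 permutation-triple codes.
#
# vmat: 576 x k matrix of per-transition impact values (columns are
# independent impact tables).  Returns, for every code (identity first)
# and every column, the S/N/SS/NN/SN category totals, plus the per-code
# category counts.  Works in row chunks so memory stays bounded by one
# chunk of membership masks plus the accumulators.
ensemble_scan <- function(vmat, chunk = 1024L) {
  stopifnot(is.matrix(vmat), nrow(vmat) == 576L)
  ti <- transition_index()
  lab0 <- label_int(canonical_code())
  triples <- enumerate_triples()
  mp <- triple_map_parts()
  n <- nrow(triples)
  k <- ncol(vmat)
  tot <- colSums(vmat)
  S <- matrix(0, n, k); SS <- matrix(0, n, k); NN <- matrix(0, n, k)
  cntS <- integer(n); cntSS <- integer(n); cntNN <- integer(n)
  for (start in seq.int(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    mapm <- mp$M1[triples$p1[rows], , drop = FALSE] +
            mp$M2[triples$p2[rows], , drop = FALSE] +
            mp$M3[triples$p3[rows], , drop = FALSE]
    labm <- matrix(lab0[mapm], nrow = length(rows))
    syn <- labm[, ti$from_idx, drop = FALSE] ==
           labm[, ti$to_idx, drop = FALSE]
    sync <- labm[, ti$rc_from_idx, drop = FALSE] ==
            labm[, ti$rc_to_idx, drop = FALSE]
    both_s <- syn & sync
    both_n <- (!syn) & (!sync)
    S[rows, ] <- syn %*% vmat
    SS[rows, ] <- both_s %*% vmat
    NN[rows, ] <- both_n %*% vmat
    cntS[rows] <- rowSums(syn)
    cntSS[rows] <- rowSums(both_s)
    cntNN[rows] <- rowSums(both_n)
  }
  totm <- matrix(tot, n, k, byrow = TRUE)
  list(totals = list(S = S, N = totm - S, SS = SS, NN = NN,
                     SN = totm - SS - NN),
       counts = list(S = cntS, N = 576L - cntS, SS = cntSS, NN = cntNN,
                     SN = 576L - cntSS - cntNN))
}

ENSEMBLE_CATEGORIES <- c("N", "S", "NN", "SN", "SS")

#' Category totals across the full alternative-code ensemble
#'
#' Batch evaluation: given one or many 576-long impact vectors, returns
#' the category statistic for the canonical code and for each of the
#' 13,823 alternative codes, plus the empirical p-value per column.  This
#' is the vectorized workhorse behind [run_ensemble_test()]; use it
#' directly when scanning many impact tables (e.g. many synthetic seeds).
#'
#' @param impacts An [impact_table()], a numeric vector of length 576 in
#'   [enumerate_transitions()] order, or a 576 x k matrix (columns are
#'   separate impact tables).
#' @param category One of \code{"S"}, \code{"N"}, \code{"SS"},
#'   \code{"NN"}, \code{"SN"}.
#' @param mode \code{"sum"} or \code{"mean"}.
#' @return List with \code{canonical} (length k), \code{ensemble}
#'   (13,823 x k matrix) and \code{p} (length k empirical p-values).
#' @export
ensemble_category_totals <- function(impacts, category = "S", mode = "sum") {
  category <- match.arg(category, ENSEMBLE_CATEGORIES)
  mode <- match.arg(mode, c("sum", "mean"))
  vmat <- if (inherits(impacts, "impact_table")) {
    matrix(impact_values(impacts), ncol = 1)
  } else if (is.matrix(impacts)) impacts else matrix(impacts, ncol = 1)
  sc <- ensemble_scan(vmat)
  totals <- sc$totals[[category]]
  if (mode == "mean") totals <- totals / pmax(sc$counts[[category]], 1L)
  canonical <- totals[1L, ]
  ensemble <- totals[-1L, , drop = FALSE]
  p <- vapply(seq_len(ncol(totals)),
              function(j) ecdf_p(canonical[j], ensemble[, j]), numeric(1))
  list(canonical = canonical, ensemble = ensemble, p = p)
}

#' Ensemble optimization test of the canonical genetic code
#'
#' The headline analysis.  For each requested category, computes the
#' canonical code's category statistic from the impact table, recomputes
#' the same statistic under every one of the 13,823 degeneracy-preserving
#' alternative codes (exhaustive, not sampled -- the result is
#' deterministic given the impact table), and reports the empirical
#' p-value: the fraction of alternatives with a statistic less than or
#' equal to the canonical one.  The canonical code itself is not a member
#' of the ensemble.
#'
#' @param impacts An [impact_table()] (576 transitions).
#' @param categories Categories to evaluate (default all five).
#' @param mode \code{"sum"} or \code{"mean"}; default follows the metric
#'   convention (sum for dFLUX/dCORR, mean for dTRX).
#' @return Object of class \code{"ensemble_test"}: list with a
#'   \code{summary} data frame (metric, category, mode, canonical_value,
#'   empirical_p, n_alternatives), the per-category \code{ensemble} value
#'   matrix, and bookkeeping metadata.  Because transitions are directed,
#'   sums are uniformly doubled relative to unordered-pair bookkeeping;
#'   p-values are unaffected (recorded in the metadata).
#' @export
run_ensemble_test <- function(impacts,
                              categories = ENSEMBLE_CATEGORIES,
                              mode = NULL) {
  stopifnot(inherits(impacts, "impact_table"))
  categories <- match.arg(categories, ENSEMBLE_CATEGORIES,
                          several.ok = TRUE)
  metric <- attr(impacts, "metric")
  if (is.null(mode)) mode <- default_mode(metric)
  mode <- match.arg(mode, c("sum", "mean"))
  sc <- ensemble_scan(matrix(impact_values(impacts), ncol = 1))
  ens <- matrix(NA_real_, nrow = 13823L, ncol = length(categories),
                dimnames = list(NULL, categories))
  canonical <- stats::setNames(numeric(length(categories)), categories)
  p <- canonical
  for (cat in categories) {
    totals <- sc$totals[[cat]][, 1L]
    # a code with an empty category contributes a mean of 0: no
    # substitutions in the category, no impact (SS is empty under 384 of
    # the 13,824 permutation codes; S and N never are)
    if (mode == "mean") totals <- totals / pmax(sc$counts[[cat]], 1L)
    canonical[cat] <- totals[1L]
    ens[, cat] <- totals[-1L]
    p[cat] <- ecdf_p(totals[1L], totals[-1L])
  }
  summary <- data.frame(metric = metric, category = categories,
                        mode = mode,
                        canonical_value = unname(canonical),
                        empirical_p = unname(p),
                        n_alternatives = 13823L)
  structure(list(summary = summary, ensemble = ens, canonical = canonical,
                 metric = metric, mode = mode, n_alternatives = 13823L,
                 directed_transitions = TRUE,
                 tie_convention = "ensemble <= canonical"),
            class = "ensemble_test")
}

#' @export
print.ensemble_test <- function(x, ...) {
  cat("<ensemble_test> metric:", x$metric, " mode:", x$mode,
      " alternatives:", x$n_alternatives, "\n")
  s <- x$summary
  s$outperforms_pct <- round(100 * (1 - s$empirical_p), 1)
  print(s, row.names = FALSE, ...)
  cat("empirical_p = fraction of alternatives <= canonical;",
      "outperforms_pct = 100*(1-p)\n")
  invisible(x)
}

#' Pearson correlation between two impact tables
#'
#' Correlates per-transition impact values across the 576 transitions,
#' aligning on (from, to).
#'
#' @param a,b [impact_table()] objects over the same transitions.
#' @return Pearson r.
#' @export
metric_correlation <- function(a, b) {
  stopifnot(inherits(a, "impact_table"), inherits(b, "impact_table"))
  key_a <- paste(a$from, a$to)
  key_b <- paste(b$from, b$to)
  idx <- match(key_a, key_b)
  if (anyNA(idx)) stop("impact tables cover different transitions")
  va <- a$value
  vb <- b$value[idx]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(va, vb)
}
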