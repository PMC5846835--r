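#' @include code_tables.R
NULL

#' Summarize a codon profile's atomic fluctuations
#'
#' Reduces the per-atom fluctuation vector over the 5-nucleotide mask to a
#' single scalar by the arithmetic mean (scale-stable across mask sizes;
#' a \code{sum} reduction is available for sensitivity checks).
#'
#' @param profile A [codon_profile()] object.
#' @param reduce \code{"mean"} (default) or \code{"sum"}.
#' @return Scalar fluctuation summary (Angstrom).
#' @export
summarize_flux <- function(profile, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  flux <- if (inherits(profile, "codon_profile")) profile$flux else profile
  if (length(flux) == 0L) stop("empty fluctuation mask")
  if (any(!is.finite(flux)) || any(flux < 0)) {
    stop("fluctuations must be finite and non-negative")
  }
  if (reduce == "mean") mean(flux) else sum(flux)
}

#' Summarize a codon profile's atomic correlation matrix
#'
#' Mean of the strictly off-diagonal entries of the mask correlation
#' matrix (all atom pairs; the diagonal is identically 1 and carries no
#' information).
#'
#' @param profile A [codon_profile()] object or a square correlation matrix.
#' @param tol Symmetry tolerance.
#' @return Scalar mean off-diagonal correlation (r).
#' @export
summarize_corr <- function(profile, tol = 1e-6) {
  cm <- if (inherits(profile, "codon_profile")) profile$corr else profile
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("correlation matrix must be square")
  }
  if (max(abs(cm - t(cm))) > tol) stop("correlation matrix is not symmetric")
  n <- nrow(cm)
  if (n < 2L) stop("correlation matrix must span at least 2 atoms")
  (sum(cm) - sum(diag(cm))) / (n * (n - 1))
}

#' Per-transition impact: absolute before/after difference
#'
#' @param before,after Scalar mask summaries for the origin and mutated
#'   codon.
#' @return \code{abs(before - after)}.
#' @export
transition_impact <- function(before, after) {
  stopifnot(all(is.finite(before)), all(is.finite(after)))
  abs(before - after)
}

#' Impact table over all 576 transitions from codon profiles
#'
#' Summarizes each codon's profile to a scalar (mask-mean fluctuation for
#' dFLUX, mean off-diagonal correlation for dCORR) and scores every
#' directed single-base transition by the absolute before/after difference.
#'
#' @param profiles A [codon_profile_set()] of all 64 codons.
#' @param metric \code{"dFLUX"} or \code{"dCORR"}.
#' @param reduce Mask reduction for dFLUX, see [summarize_flux()].
#' @return An \code{impact_table}: data frame with \code{from}, \code{to},
#'   \code{position}, \code{value} plus a \code{metric} attribute.
#' @export
impact_table <- function(profiles, metric = c("dFLUX", "dCORR"),
                         reduce = "mean") {
  metric <- match.arg(metric)
  profiles <- as_codon_profile_set(profiles)
  summary_fn <- switch(metric,
                       dFLUX = function(p) summarize_flux(p, reduce = reduce),
                       dCORR = summarize_corr)
  per_codon <- vapply(profiles, summary_fn, numeric(1))[codons()]
  tr <- enumerate_transitions()
  ti <- transition_index()
  tr$value <- transition_impact(per_codon[ti$from_idx], per_codon[ti$to_idx])
  new_impact_table(tr, metric)
}

new_impact_table <- function(df, metric) {
  stopifnot(nrow(df) == 576L, !is.null(df$value), all(df$value >= 0))
  structure(df, metric = metric,
            class = c("impact_table", "data.frame"))
}

#' @export
print.impact_table <- function(x, ...) {
  cat("<impact_table> metric:", attr(x, "metric"),
      " transitions:", nrow(x), "\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# impact values as a vector in transition_index() order
impact_values <- function(impacts) {
  stopifnot(inherits(impacts, "impact_table"))
  impacts$value
}

default_mode <- function(metric) {
  # category totals are sums for the MD metrics, means for dTRX
  if (identical(metric, "dTRX")) "mean" else "sum"
}

#' Category total of an impact table under a genetic code
#'
#' Sums (dFLUX/dCORR convention) or averages (dTRX convention) the
#' per-transition impacts over the transitions falling in one
#' synonymous/nonsynonymous category under \code{code}.  Transitions are
#' directed, so relative to an unordered-pair bookkeeping every category
#' sum is doubled uniformly; empirical p-values are unaffected.
#'
#' @param impacts An [impact_table()].
#' @param code A [genetic_code()].
#' @param category One of \code{"S"}, \code{"N"} (coding strand) or
#'   \code{"SS"}, \code{"NN"}, \code{"SN"} (both strands).
#' @param mode \code{"sum"} or \code{"mean"}; defaults by metric.
#' @return Scalar category total.
#' @export
category_total <- function(impacts, code = canonical_code(),
                           category = c("S", "N", "SS", "NN", "SN"),
                           mode = NULL) {
  category <- match.arg(category)
  if (is.null(mode)) mode <- default_mode(attr(impacts, "metric"))
  mode <- match.arg(mode, c("sum", "mean"))
  v <- impact_values(impacts)
  cls <- if (category %in% c("S", "N")) {
    classify_transition(impacts, code)
  } else {
    strand_classify(impacts, code)
  }
  keep <- cls == category
  if (!any(keep)) {
    if (mode == "sum") return(0)
    stop("category ", category, " is empty under this code; mean undefined")
  }
  if (mode == "sum") sum(v[keep]) else mean(v[keep])
}

#' Export an impact table as TSV
#'
#' Columns: from_codon, to_codon, position, coding_class, strand_class,
#' metric, value (classes under \code{code}).
#'
#' @param impacts An [impact_table()].
#' @param file Output path.
#' @param code Code used for the class annotation columns.
#' @export
write_impact_table <- function(impacts, file, code = canonical_code()) {
  out <- data.frame(from_codon = impacts$from,
                    to_codon = impacts$to,
                    position = impacts$position,
                    coding_class = classify_transition(impacts, code),
                    strand_class = strand_classify(impacts, code),
                    metric = attr(impacts, "metric"),
                    value = impacts$value)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
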