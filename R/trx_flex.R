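#' @include code_tables.R impact_metrics.R
NULL

#' Load a dinucleotide TRX flexibility table
#'
#' Sixteen lines \code{MN<TAB>value}, where MN is a dinucleotide read
#' 5'->3' on the coding strand and the value is the percent of time the
#' phosphate linkage between M and N spends in the BII backbone
#' conformation (0 = stiff, always BI; 43 = very flexible).
#'
#' @param file Path to the table; defaults to the scale shipped with the
#'   package (transcribed from the published NMR-derived scale).
#' @return Named numeric vector of length 16, class \code{"trx_table"}.
#' @export
load_trx_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "trx_dinucleotide_table.tsv",
                        package = "codonmd", mustWork = TRUE)
  }
  tab <- utils::read.table(file, header = FALSE, sep = "\t",
                           comment.char = "#",
                           col.names = c("dinuc", "value"),
                           colClasses = c("character", "numeric"))
  dn <- substr(toupper(chartr("U", "T", tab$dinuc)), 1, 2)
  if (any(grepl("[^ACGT]", dn))) stop("invalid base in TRX table")
  expected <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  if (!setequal(dn, expected) || length(dn) != 16L) {
    stop("TRX table must contain each of the 16 dinucleotides exactly once")
  }
  v <- stats::setNames(tab$value, dn)[sort(expected)]
  if (any(!is.finite(v)) || any(v < 0) || any(v > 43)) {
    stop("TRX values must lie in [0, 43] (percent BII occupancy)")
  }
  structure(v, class = "trx_table")
}

#' @rdname load_trx_table
#' @export
trx_table <- function() {
  if (is.null(.codonmd_cache$trx)) .codonmd_cache$trx <- load_trx_table()
  .codonmd_cache$trx
}

#' @export
print.trx_table <- function(x, ...) {
  cat("<trx_table> percent BII per dinucleotide step\n")
  print(unclass(x), ...)
  invisible(x)
}

#' TRX flexibility score of a sequence
#'
#' Mean flexibility per phosphate linkage: the sum of the dinucleotide
#' TRX values over the L-1 steps of the sequence, divided by L-1.
#'
#' @param seq Character vector of base strings (each of length >= 2;
#'   RNA accepted and normalized).
#' @param table A [trx_table()].
#' @return Numeric vector of scores (percent BII).
#' @export
#' @examples
#' trx_score("ATGCA", trx_table())
trx_score <- function(seq, table = trx_table()) {
  stopifnot(inherits(table, "trx_table"))
  seq <- chartr("U", "T", toupper(as.character(seq)))
  if (any(nchar(seq) < 2L)) stop("sequences must have length >= 2")
  if (any(grepl("[^ACGT]", seq))) stop("invalid base in sequence")
  vapply(seq, function(s) {
    L <- nchar(s)
    steps <- substring(s, 1:(L - 1), 2:L)
    sum(table[steps]) / (L - 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Sliding-window TRX scan of a sequence
#'
#' @param seq A single base string.
#' @param window Window length (>= 2).
#' @param table A [trx_table()].
#' @return Data frame with window \code{start} and \code{score}.
#' @export
trx_scan <- function(seq, window = 25L, table = trx_table()) {
  seq <- chartr("U", "T", toupper(as.character(seq)))
  stopifnot(length(seq) == 1L, window >= 2L)
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than window")
  starts <- seq_len(L - window + 1L)
  data.frame(start = starts,
             score = trx_score(substring(seq, starts,
                                         starts + window - 1L), table))
}

# all 16 flank pairs (left, right) around the codon
flank_pairs <- function() {
  g <- expand.grid(right = DNA_BASES, left = DNA_BASES,
                   stringsAsFactors = FALSE)
  g[, c("left", "right")]
}

#' Flexibility impact of one codon transition (dTRX)
#'
#' Scores the 5-nucleotide window (codon plus one flanking base on each
#' side) before and after the substitution and takes the absolute
#' difference, averaged over all 16 left/right flanking-base pairs (the
#' window convention matches the MD mask; flank averaging removes the
#' arbitrary choice of sequence context).
#'
#' @param from,to Codon strings differing at one position.
#' @param table A [trx_table()].
#' @param flanks \code{"average"} (default: mean over all 16 flank pairs)
#'   or a length-2 character vector \code{c(left, right)} for one fixed
#'   context.
#' @return Non-negative scalar (percent BII).
#' @export
dtrx_transition <- function(from, to, table = trx_table(),
                            flanks = "average") {
  from <- normalize_codon(from)
  to <- normalize_codon(to)
  if (is.na(from) || is.na(to)) stop("invalid codon")
  if (sum(strsplit(from, "")[[1]] != strsplit(to, "")[[1]]) != 1L) {
    stop("transition must change exactly one position")
  }
  fp <- if (identical(flanks, "average")) {
    flank_pairs()
  } else {
    stopifnot(length(flanks) == 2L, all(flanks %in% DNA_BASES))
    data.frame(left = flanks[1], right = flanks[2])
  }
  before <- trx_score(paste0(fp$left, from, fp$right), table)
  after <- trx_score(paste0(fp$left, to, fp$right), table)
  mean(abs(before - after))
}

#' dTRX impact table over all 576 transitions
#'
#' @param table A [trx_table()].
#' @param flanks Flank policy, see [dtrx_transition()].
#' @return An [impact_table()] with metric \code{"dTRX"}.
#' @export
dtrx_impact_table <- function(table = trx_table(), flanks = "average") {
  tr <- enumerate_transitions()
  tr$value <- mapply(dtrx_transition, tr$from, tr$to,
                     MoreArgs = list(table = table, flanks = flanks))
  new_impact_table(tr, "dTRX")
}

#' Mean dTRX over one category under a genetic code
#'
#' Convenience wrapper: the category mean of the dTRX impact table (the
#' dTRX category statistic is a mean, not a sum).
#'
#' @param code A [genetic_code()].
#' @param table A [trx_table()].
#' @param category See [category_total()].
#' @return Scalar mean dTRX (percent BII).
#' @export
dtrx_category_mean <- function(code = canonical_code(), table = trx_table(),
                               category = c("S", "N", "SS", "NN", "SN")) {
  category <- match.arg(category)
  category_total(dtrx_impact_table(table), code, category, mode = "mean")
}
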