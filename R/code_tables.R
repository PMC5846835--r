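#' @include codonmd-package.R
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 codons in canonical order
#'
#' Codons are ordered lexicographically over the DNA alphabet A < C < G < T,
#' with the first position varying slowest.  This ordering is the fixed
#' internal indexing used throughout the package.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' head(codons())
codons <- function() {
  if (is.null(.codonmd_cache$codons)) {
    g <- expand.grid(p3 = DNA_BASES, p2 = DNA_BASES, p1 = DNA_BASES,
                     stringsAsFactors = FALSE)
    .codonmd_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .codonmd_cache$codons
}

# normalize codon strings: uppercase, U -> T; returns NA for invalid codons
normalize_codon <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- nchar(x) != 3L | grepl("[^ACGT]", x)
  x[bad] <- NA_character_
  x
}

codon_index <- function(codon) {
  idx <- match(normalize_codon(codon), codons())
  if (anyNA(idx)) {
    stop("invalid codon(s): ",
         paste(unique(codon[is.na(idx)]), collapse = ", "))
  }
  idx
}

# reverse complement of codon strings (anticodon frame, read 5'->3')
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# index map: revcomp_index()[i] is the codon index of revcomp(codons()[i])
revcomp_index <- function() {
  if (is.null(.codonmd_cache$rc_idx)) {
    .codonmd_cache$rc_idx <- match(revcomp(codons()), codons())
  }
  .codonmd_cache$rc_idx
}

#' Construct a genetic code object
#'
#' A genetic code is a complete assignment of the 64 codons to 21 labels:
#' the 20 amino acids (three-letter names) plus \code{"STOP"}.  STOP is
#' treated as an ordinary 21st label with degeneracy 3, so STOP-to-STOP
#' substitutions are synonymous and STOP/amino-acid exchanges are
#' nonsynonymous.
#'
#' @param assignment Named character vector: names are codons (DNA or RNA
#'   alphabet), values are labels.  All 64 codons must be assigned.
#' @param name Short identifying name for the code.
#' @return Object of class \code{"genetic_code"}: a character vector of 64
#'   labels in [codons()] order with a \code{name} attribute.
#' @export
genetic_code <- function(assignment, name = "unnamed") {
  if (is.null(names(assignment))) {
    stop("assignment must be a named character vector (names = codons)")
  }
  idx <- codon_index(names(assignment))
  if (anyDuplicated(idx)) stop("duplicate codon assignments")
  if (length(idx) != 64L) {
    stop("all 64 codons must be assigned; got ", length(idx))
  }
  labels <- character(64)
  labels[idx] <- as.character(assignment)
  structure(labels, names = codons(), class = "genetic_code", name = name)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", attr(x, "name"), "\n", sep = "")
  deg <- degeneracy(x)
  cat("  labels: ", length(deg), "; degeneracy: ",
      paste0(names(deg), "=", deg, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read a genetic code from a plain-text table
#'
#' Format: one row per codon, \code{codon<TAB>label}, 64 rows; lines
#' starting with \code{#} are ignored.  The canonical code ships with the
#' package in this format.
#'
#' @param file Path to the table.
#' @param name Name for the resulting code.
#' @return A [genetic_code()] object.
#' @export
load_code_table <- function(file, name = basename(file)) {
  tab <- utils::read.table(file, header = FALSE, sep = "\t",
                           comment.char = "#", col.names = c("codon", "label"),
                           colClasses = "character")
  genetic_code(stats::setNames(tab$label, tab$codon), name = name)
}

#' The canonical (standard) genetic code
#'
#' @return A [genetic_code()] object for the standard codon table.
#' @export
#' @examples
#' translate("ATG", canonical_code())
canonical_code <- function() {
  if (is.null(.codonmd_cache$canonical)) {
    f <- system.file("extdata", "standard_genetic_code.tsv",
                     package = "codonmd", mustWork = TRUE)
    .codonmd_cache$canonical <- load_code_table(f, name = "standard")
  }
  .codonmd_cache$canonical
}

#' Translate codons under a genetic code
#'
#' @param codon Character vector of codons (RNA \code{U} accepted).
#' @param code A [genetic_code()]; defaults to the canonical code.
#' @return Character vector of labels.
#' @export
translate <- function(codon, code = canonical_code()) {
  stopifnot(inherits(code, "genetic_code"))
  unname(code[codon_index(codon)])
}

#' Degeneracy vector of a genetic code
#'
#' Number of codons assigned to each label.  Every degeneracy-preserving
#' alternative code shares the canonical vector (e.g. Leu = 6, Met = 1,
#' STOP = 3).
#'
#' @param code A [genetic_code()].
#' @return Named integer vector, sorted by label; sums to 64.
#' @export
degeneracy <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  tab <- table(unclass(code))
  stats::setNames(as.integer(tab), names(tab))
}

#' Enumerate all directed single-base codon transitions
#'
#' Every ordered pair of codons differing at exactly one position: 64
#' codons x 3 positions x 3 alternative bases = 576 directed transitions.
#' Ordering is deterministic: by origin codon ([codons()] order), then
#' position 1-3, then replacement base A < C < G < T.
#'
#' @return Data frame with columns \code{from}, \code{to} (codon strings)
#'   and \code{position} (integer 1-3), 576 rows.
#' @export
enumerate_transitions <- function() {
  tr <- transition_index()
  data.frame(from = codons()[tr$from_idx],
             to = codons()[tr$to_idx],
             position = tr$position,
             stringsAsFactors = FALSE)
}

# cached integer bookkeeping for the 576 transitions
transition_index <- function() {
  if (is.null(.codonmd_cache$transitions)) {
    cs <- codons()
    from <- integer(0); to <- integer(0); pos <- integer(0)
    for (i in seq_along(cs)) {
      b <- strsplit(cs[i], "", fixed = TRUE)[[1]]
      for (p in 1:3) {
        for (alt in setdiff(DNA_BASES, b[p])) {
          nb <- b
          nb[p] <- alt
          from <- c(from, i)
          to <- c(to, match(paste(nb, collapse = ""), cs))
          pos <- c(pos, p)
        }
      }
    }
    rc <- revcomp_index()
    .codonmd_cache$transitions <- list(
      from_idx = from, to_idx = to, position = pos,
      rc_from_idx = rc[from], rc_to_idx = rc[to])
  }
  .codonmd_cache$transitions
}

# integer label vector (1..21) for a code, in codons() order
label_int <- function(code) {
  match(unclass(code), sort(unique(unclass(canonical_code()))))
}

#' Classify transitions as synonymous or nonsynonymous
#'
#' A transition is synonymous (\code{"S"}) iff both codons map to the same
#' label under \code{code} (STOP counting as its own label), otherwise
#' nonsynonymous (\code{"N"}).
#'
#' @param transitions Data frame with \code{from} and \code{to} codon
#'   columns; defaults to all 576 transitions.
#' @param code A [genetic_code()].
#' @return Character vector of \code{"S"}/\code{"N"}.
#' @export
classify_transition <- function(transitions = enumerate_transitions(),
                                code = canonical_code()) {
  stopifnot(inherits(code, "genetic_code"))
  same <- translate(transitions$from, code) == translate(transitions$to, code)
  ifelse(same, "S", "N")
}

#' Classify transitions by strand symmetry
#'
#' Each coding-strand transition induces a complementary-strand transition:
#' the reverse complement of each codon, read 5'->3' (the anticodon frame).
#' Both are classified as synonymous/nonsynonymous under \code{code}:
#' \code{"SS"} if both synonymous, \code{"NN"} if both nonsynonymous,
#' \code{"SN"} if mixed (order pooled).
#'
#' @inheritParams classify_transition
#' @return Character vector of \code{"SS"}/\code{"NN"}/\code{"SN"}.
#' @export
strand_classify <- function(transitions = enumerate_transitions(),
                            code = canonical_code()) {
  coding <- classify_transition(transitions, code)
  comp <- data.frame(from = revcomp(normalize_codon(transitions$from)),
                     to = revcomp(normalize_codon(transitions$to)))
  lagging <- classify_transition(comp, code)
  ifelse(coding == "S" & lagging == "S", "SS",
         ifelse(coding == "N" & lagging == "N", "NN", "SN"))
}

#' Fully classified transition table
#'
#' All 576 directed transitions with coding-strand class (S/N) and strand
#' class (SS/NN/SN) under a code.
#'
#' @param code A [genetic_code()].
#' @return Data frame with columns \code{from}, \code{to}, \code{position},
#'   \code{coding_class}, \code{strand_class}.
#' @export
classify_transitions <- function(code = canonical_code()) {
  tr <- enumerate_transitions()
  tr$coding_class <- classify_transition(tr, code)
  tr$strand_class <- strand_classify(tr, code)
  tr
}
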