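# Independent brute-force oracles.  These deliberately avoid the package's
# own bookkeeping: the codon table comes from Biostrings, reverse
# complements from Biostrings, and every count is a literal loop.

oracle_code_map <- function() {
  # one-letter labels are fine: the oracles only ever compare labels
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
}

oracle_all_codons <- function() {
  b <- c("A", "C", "G", "T")
  out <- character(0)
  for (x in b) for (y in b) for (z in b) out <- c(out, paste0(x, y, z))
  out
}

# all directed pairs differing at exactly one position
oracle_transitions <- function() {
  cods <- oracle_all_codons()
  from <- character(0); to <- character(0)
  for (a in cods) for (b in cods) {
    if (a == b) next
    diff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (diff == 1L) {
      from <- c(from, a)
      to <- c(to, b)
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

oracle_classify <- function(from, to, code_map) {
  unname(ifelse(code_map[from] == code_map[to], "S", "N"))
}

oracle_strand_classify <- function(from, to, code_map) {
  coding <- oracle_classify(from, to, code_map)
  lagging <- oracle_classify(oracle_revcomp(from), oracle_revcomp(to),
                             code_map)
  ifelse(coding == "S" & lagging == "S", "SS",
         ifelse(coding == "N" & lagging == "N", "NN", "SN"))
}

# explicit alternative code: permute base letters per position, then look
# the permuted codon up in the base map
oracle_alt_code_map <- function(perm1, perm2, perm3,
                                base_map = oracle_code_map()) {
  cods <- oracle_all_codons()
  out <- character(length(cods))
  names(out) <- cods
  for (cd in cods) {
    b <- strsplit(cd, "")[[1]]
    key <- paste0(perm1[[b[1]]], perm2[[b[2]]], perm3[[b[3]]])
    out[[cd]] <- base_map[[key]]
  }
  out
}

# named base permutation (c(A=...,C=...,G=...,T=...)) from a row of
# codonmd::base_permutations()
oracle_perm_from_row <- function(row) {
  b <- c("A", "C", "G", "T")
  stats::setNames(b[row], b)
}

oracle_ecdf_p <- function(observed, ensemble) {
  n <- 0L
  for (v in ensemble) if (v <= observed) n <- n + 1L
  n / length(ensemble)
}

oracle_category_sum <- function(values, from, to, code_map, category) {
  cls <- if (category %in% c("S", "N")) {
    oracle_classify(from, to, code_map)
  } else {
    oracle_strand_classify(from, to, code_map)
  }
  sum(values[cls == category])
}
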