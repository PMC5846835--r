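#' @include code_tables.R
NULL

#' The 24 permutations of the DNA alphabet
#'
#' Bijections of \{A, C, G, T\} in lexicographic order of their images, so
#' the identity permutation is row 1.  Row \code{p} gives, for each base
#' index 1-4 (A, C, G, T), the index of its image.
#'
#' @return 24 x 4 integer matrix.
#' @export
base_permutations <- function() {
  if (is.null(.codonmd_cache$perms)) {
    g <- expand.grid(d = 1:4, c = 1:4, b = 1:4, a = 1:4)[, 4:1]
    ok <- apply(g, 1, function(r) length(unique(r)) == 4L)
    m <- as.matrix(g[ok, , drop = FALSE])
    dimnames(m) <- list(NULL, DNA_BASES)
    .codonmd_cache$perms <- m
  }
  .codonmd_cache$perms
}

#' Enumerate all position-wise base-permutation triples
#'
#' Alternative genetic codes are generated by choosing one permutation of
#' the base alphabet independently at each codon position: 24^3 = 13,824
#' triples, of which the identity triple (first row) reproduces the
#' canonical code and the remaining 13,823 define the alternative-code
#' ensemble.  The ordering is deterministic: lexicographic in
#' (pi1, pi2, pi3) with pi3 varying fastest.
#'
#' @return Data frame with integer columns \code{p1}, \code{p2}, \code{p3}
#'   (row indices into [base_permutations()]) and logical
#'   \code{is_identity}; 13,824 rows, identity first.
#' @export
enumerate_triples <- function() {
  g <- expand.grid(p3 = 1:24, p2 = 1:24, p1 = 1:24)[, c("p1", "p2", "p3")]
  rownames(g) <- NULL
  g$is_identity <- g$p1 == 1L & g$p2 == 1L & g$p3 == 1L
  g
}

# position-wise codon index decomposition, cached:
# b1/b2/b3[c] = base index (1..4) at that position of codons()[c]
codon_base_index <- function() {
  if (is.null(.codonmd_cache$base_idx)) {
    m <- do.call(rbind, strsplit(codons(), "", fixed = TRUE))
    .codonmd_cache$base_idx <- list(b1 = match(m[, 1], DNA_BASES),
                                    b2 = match(m[, 2], DNA_BASES),
                                    b3 = match(m[, 3], DNA_BASES))
  }
  .codonmd_cache$base_idx
}

# 24 x 64 contribution matrices: codon_map = M1[p1, ] + M2[p2, ] + M3[p3, ]
triple_map_parts <- function() {
  if (is.null(.codonmd_cache$map_parts)) {
    b <- codon_base_index()
    P <- base_permutations()
    .codonmd_cache$map_parts <- list(
      M1 = 16L * (P[, b$b1] - 1L),
      M2 = 4L * (P[, b$b2] - 1L),
      M3 = P[, b$b3])
  }
  .codonmd_cache$map_parts
}

# codon index remapping for one triple: new_code reads base_code at
# (pi1 b1, pi2 b2, pi3 b3)
codon_map_for_triple <- function(p1, p2, p3) {
  mp <- triple_map_parts()
  mp$M1[p1, ] + mp$M2[p2, ] + mp$M3[p3, ]
}

#' Build an alternative genetic code from a permutation triple
#'
#' The new code assigns to codon (b1, b2, b3) the label the base code
#' assigns to (pi1(b1), pi2(b2), pi3(b3)).  Because each position is
#' permuted by a bijection, the per-label degeneracy of the base code is
#' preserved exactly.
#'
#' @param triple Integer vector of length 3 (rows of [base_permutations()]
#'   for positions 1-3), or a single row of [enumerate_triples()].
#' @param base_code The code being reorganized (default canonical).
#' @return A [genetic_code()] object.
#' @export
#' @examples
#' alt <- build_code(c(2, 1, 1))   # permute position 1 only
#' degeneracy(alt)["Leu"]          # still 6
build_code <- function(triple, base_code = canonical_code()) {
  if (is.data.frame(triple)) {
    stopifnot(nrow(triple) == 1L)
    triple <- c(triple$p1, triple$p2, triple$p3)
  }
  stopifnot(length(triple) == 3L, all(triple %in% 1:24))
  map <- codon_map_for_triple(triple[1], triple[2], triple[3])
  labels <- unclass(base_code)[map]
  structure(stats::setNames(labels, codons()), class = "genetic_code",
            name = sprintf("%s_pi%d.%d.%d", attr(base_code, "name"),
                           triple[1], triple[2], triple[3]))
}

#' Write a genetic code to the packaged plain-text format
#'
#' @param code A [genetic_code()].
#' @param file Output path; format matches [load_code_table()].
#' @export
write_code_table <- function(code, file) {
  stopifnot(inherits(code, "genetic_code"))
  writeLines(paste(codons(), unclass(code), sep = "\t"), file)
  invisible(file)
}
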