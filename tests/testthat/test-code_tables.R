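test_that("translate follows the canonical table and normalizes RNA input", {
  expect_identical(translate("ATG"), "Met")
  expect_identical(translate("TAA"), "STOP")
  expect_identical(translate("AUG"), "Met")
  expect_identical(translate(c("aaa", "uuu")), c("Lys", "Phe"))
  expect_error(translate("AXG"), "invalid codon")
  expect_error(translate("AT"), "invalid codon")

  # full agreement with the Biostrings table (modulo label spelling):
  # the partition of codons into synonymous groups must be identical
  omap <- oracle_code_map()
  ours <- translate(codons())
  group_strings <- function(cods, labs) {
    sort(vapply(split(cods, labs),
                function(g) paste(sort(g), collapse = ","), character(1)),
         method = "radix") |> unname()
  }
  expect_identical(group_strings(codons(), ours),
                   group_strings(names(omap), unname(omap)))
})

test_that("translate under a position-1 A<->C permutation routes through CTG", {
  P <- base_permutations()
  swap_ac <- which(apply(P, 1, function(r) all(r == c(2, 1, 3, 4))))
  alt <- build_code(c(swap_ac, 1, 1))
  expect_identical(translate("ATG", alt), translate("CTG"))
  expect_identical(translate("ATG", alt), "Leu")
})

test_that("genetic_code validates its assignment", {
  cc <- canonical_code()
  expect_error(genetic_code(unclass(cc)[1:63]), "64")
  dup <- stats::setNames(unclass(cc), names(cc))
  names(dup)[2] <- names(dup)[1]
  expect_error(genetic_code(dup), "duplicate")
  expect_error(genetic_code(unname(unclass(cc))), "named")
})

test_that("canonical degeneracy matches the standard table", {
  deg <- degeneracy(canonical_code())
  expect_identical(sum(deg), 64L)
  expect_identical(deg[["Leu"]], 6L)
  expect_identical(deg[["Met"]], 1L)
  expect_identical(deg[["Trp"]], 1L)
  expect_identical(deg[["STOP"]], 3L)
  # the full degeneracy multiset agrees with the Biostrings oracle
  expect_identical(sort(as.integer(deg)),
                   sort(as.integer(table(oracle_code_map()))))
})

test_that("code tables round-trip through the text format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  alt <- build_code(c(5, 7, 2))
  write_code_table(alt, f)
  back <- load_code_table(f, name = "back")
  expect_identical(unclass(back), unclass(alt), ignore_attr = TRUE)
})

test_that("enumerate_transitions yields the 576 single-base substitutions", {
  tr <- enumerate_transitions()
  expect_identical(nrow(tr), 576L)
  expect_true(all(tr$from != tr$to))
  expect_identical(as.integer(table(tr$from)), rep(9L, 64))
  expect_setequal(tr$to[tr$from == "AAA" & tr$position == 3],
                  c("AAC", "AAG", "AAT"))
  # exact agreement with the brute-force pair enumeration
  orc <- oracle_transitions()
  expect_setequal(paste(tr$from, tr$to), paste(orc$from, orc$to))
})

test_that("coding-strand classification matches the examples and oracle", {
  tr <- enumerate_transitions()
  cls <- classify_transition(tr)
  pick <- function(f, t) cls[tr$from == f & tr$to == t]
  expect_identical(pick("AAA", "AAG"), "S")   # Lys -> Lys
  expect_identical(pick("AAA", "AGA"), "N")   # Lys -> Arg
  expect_identical(pick("TAA", "TAG"), "S")   # STOP -> STOP
  expect_identical(cls, oracle_classify(tr$from, tr$to, oracle_code_map()))
})

test_that("classification is symmetric under transition reversal", {
  tr <- enumerate_transitions()
  rev <- data.frame(from = tr$to, to = tr$from)
  key <- paste(tr$from, tr$to)
  rkey <- paste(rev$from, rev$to)
  for (code in list(canonical_code(), build_code(c(3, 11, 24)))) {
    expect_identical(classify_transition(tr, code),
                     classify_transition(rev, code)[match(key, rkey)])
    expect_identical(strand_classify(tr, code),
                     strand_classify(rev, code)[match(key, rkey)])
  }
})

test_that("strand classification matches the worked examples and oracle", {
  tr <- enumerate_transitions()
  scls <- strand_classify(tr)
  pick <- function(f, t) scls[tr$from == f & tr$to == t]
  expect_identical(pick("GGG", "GGA"), "SN")  # Gly/Gly but Pro/Ser on lagging
  expect_identical(pick("TCG", "TCT"), "SS")  # Ser/Ser and Arg/Arg
  expect_identical(scls,
                   oracle_strand_classify(tr$from, tr$to, oracle_code_map()))
})

test_that("strand class is invariant under the complement involution", {
  tr <- enumerate_transitions()
  comp <- data.frame(from = oracle_revcomp(tr$from),
                     to = oracle_revcomp(tr$to))
  expect_identical(strand_classify(tr), strand_classify(comp))
})

test_that("the 576 transitions partition into categories under any code", {
  withr::local_seed(42)
  triples <- enumerate_triples()
  rows <- sample(2:nrow(triples), 5)
  for (r in rows) {
    code <- build_code(triples[r, ])
    cls <- classify_transition(enumerate_transitions(), code)
    scls <- strand_classify(enumerate_transitions(), code)
    expect_identical(sum(cls == "S") + sum(cls == "N"), 576L)
    expect_identical(sum(scls == "SS") + sum(scls == "NN") +
                       sum(scls == "SN"), 576L)
  }
})
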