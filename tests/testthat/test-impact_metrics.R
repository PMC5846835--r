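# small helper: profile set with prescribed per-codon flux levels
flat_profile_set <- function(levels, n_atoms = 2L) {
  codon_profile_set(lapply(codons(), function(cd) {
    codon_profile(cd, rep(levels[[cd]], n_atoms), diag(n_atoms))
  }))
}

test_that("summarize_flux is the mask mean and validates input", {
  p <- codon_profile("ATG", c(1, 1, 1), diag(3))
  expect_identical(summarize_flux(p), 1)
  expect_identical(summarize_flux(codon_profile("ATG", c(0.5, 1.5),
                                                diag(2))), 1)
  expect_identical(summarize_flux(c(0.5, 1.5), reduce = "sum"), 2)
  # linearity in a scale factor
  x <- c(0.2, 0.7, 1.1)
  expect_equal(summarize_flux(3 * x), 3 * summarize_flux(x))
  expect_error(summarize_flux(numeric(0)), "empty")
  expect_error(codon_profile("ATG", c(-1, 1), diag(2)), "non-negative")
})

test_that("summarize_corr is the mean off-diagonal and validates input", {
  expect_identical(summarize_corr(diag(3)), 0)
  expect_identical(summarize_corr(matrix(1, 4, 4)), 1)
  m <- matrix(0.5, 3, 3); diag(m) <- 1
  expect_identical(summarize_corr(m), 0.5)
  bad <- diag(3); bad[1, 2] <- 0.9
  expect_error(summarize_corr(bad), "symmetric")
  expect_error(summarize_corr(matrix(0.1, 2, 3)), "square")
})

test_that("transition_impact is the symmetric absolute difference", {
  expect_equal(transition_impact(1.2, 1.0), 0.2)
  expect_identical(transition_impact(0.7, 0.7), 0)
  expect_identical(transition_impact(0.3, 1.9), transition_impact(1.9, 0.3))
  expect_error(transition_impact(NaN, 1), "finite")
})

test_that("impact tables are non-negative and reversal-symmetric", {
  withr::local_seed(21)
  ps <- generate_profiles("iid_noise", noise_sd = 0.1, n_replicates = 2,
                          n_atoms_per_base = 1, seed = 33)
  for (metric in c("dFLUX", "dCORR")) {
    imp <- impact_table(ps, metric)
    expect_identical(nrow(imp), 576L)
    expect_true(all(imp$value >= 0))
    ridx <- match(paste(imp$to, imp$from), paste(imp$from, imp$to))
    expect_equal(imp$value, imp$value[ridx])
  }
})

test_that("category totals behave on constant impact tables", {
  lv <- stats::setNames(rep(1, 64), codons())
  imp <- impact_table(flat_profile_set(lv), "dFLUX")
  imp$value <- rep(0.25, 576)  # constant table
  cls <- classify_transition(imp)
  k <- sum(cls == "S")
  expect_equal(category_total(imp, category = "S", mode = "sum"), k * 0.25)
  expect_equal(category_total(imp, category = "S", mode = "mean"), 0.25)
  expect_equal(category_total(imp, category = "N", mode = "mean"), 0.25)
})

test_that("synonymous-neutral profiles give a zero canonical S total", {
  ps <- generate_profiles("aa_determined", noise_sd = 0, n_replicates = 2,
                          n_atoms_per_base = 2, seed = 5)
  for (metric in c("dFLUX", "dCORR")) {
    imp <- impact_table(ps, metric)
    expect_identical(category_total(imp, category = "S"), 0)
  }
})

test_that("S + N category sums equal the full-table sum under every code", {
  withr::local_seed(17)
  ps <- generate_profiles("iid_noise", noise_sd = 0.1, n_replicates = 2,
                          n_atoms_per_base = 1, seed = 99)
  imp <- impact_table(ps, "dFLUX")
  total <- sum(imp$value)
  triples <- enumerate_triples()
  for (r in c(1, sample(2:nrow(triples), 10))) {
    code <- build_code(triples[r, ])
    expect_equal(category_total(imp, code, "S") +
                   category_total(imp, code, "N"), total)
    expect_equal(category_total(imp, code, "SS") +
                   category_total(imp, code, "NN") +
                   category_total(imp, code, "SN"), total)
  }
})

test_that("category totals agree with the brute-force oracle on alt codes", {
  withr::local_seed(29)
  P <- base_permutations()
  ps <- generate_profiles("gc_linear", noise_sd = 0.02, n_replicates = 2,
                          n_atoms_per_base = 1, seed = 3)
  imp <- impact_table(ps, "dFLUX")
  for (i in 1:20) {
    tr <- sample(24, 3, replace = TRUE)
    code <- build_code(tr)
    omap <- oracle_alt_code_map(oracle_perm_from_row(P[tr[1], ]),
                                oracle_perm_from_row(P[tr[2], ]),
                                oracle_perm_from_row(P[tr[3], ]),
                                base_map = oracle_code_map())
    for (cat in c("S", "N", "SS", "NN", "SN")) {
      expect_equal(category_total(imp, code, cat, mode = "sum"),
                   oracle_category_sum(imp$value, imp$from, imp$to,
                                       omap, cat))
    }
  }
})

test_that("impact tables export with class annotations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lv <- stats::setNames(seq(1, 2, length.out = 64), codons())
  imp <- impact_table(flat_profile_set(lv), "dFLUX")
  write_impact_table(imp, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 576L)
  expect_setequal(names(back),
                  c("from_codon", "to_codon", "position", "coding_class",
                    "strand_class", "metric", "value"))
  expect_equal(back$value, imp$value)
})
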