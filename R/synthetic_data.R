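#' @include md_io.R
NULL

#' Generate synthetic per-codon MD summary profiles
#'
#' Stands in for replicate molecular dynamics runs of all 64 codons so
#' the whole analysis pipeline can be exercised at desk scale.  Three
#' statistical models control how the codon's fluctuation level depends
#' on sequence:
#' \describe{
#'   \item{aa_determined}{the base fluctuation level (and the latent
#'     correlation structure) is a function of the codon's canonical
#'     amino-acid label only, so with \code{noise_sd = 0} all synonymous
#'     codons have identical profiles and every synonymous impact is
#'     exactly zero.  Label levels are drawn once per label from
#'     Normal(\code{intercept}, \code{level_sd}).}
#'   \item{gc_linear}{fluctuation level = \code{intercept} +
#'     \code{gc_slope} x (number of G/C bases in the codon), emulating
#'     GC-content-dependent stiffness.}
#'   \item{iid_noise}{each codon draws an independent level from
#'     Normal(\code{intercept}, \code{level_sd}); the canonical code is
#'     then statistically exchangeable with every alternative code.}
#' }
#' Atom-level and replicate-level Gaussian noise with standard deviation
#' \code{noise_sd} is added on top in every model.  Correlation matrices
#' are built from a few random latent modes (orthogonal mixing, then
#' normalized), which guarantees symmetric positive semi-definite
#' matrices with unit diagonal.  Everything is fully determined by
#' \code{seed}.
#'
#' @param model Generative model, see above.
#' @param intercept Baseline fluctuation level (Angstrom); default 1.0.
#' @param gc_slope Fluctuation increment per G/C base (Angstrom); default
#'   0.1 (gc_linear only).
#' @param noise_sd Replicate/atom noise SD (Angstrom); default 0.05.
#' @param level_sd SD of the per-label (aa_determined) or per-codon
#'   (iid_noise) level draw; default 0.25.
#' @param n_atoms_per_base Backbone atoms per nucleotide in the mask;
#'   default 4, giving 20 mask atoms over the 5-nucleotide window.
#' @param n_replicates Replicate simulations averaged per codon; default
#'   50, matching an implicit-solvent replicate set.
#' @param seed Integer seed; required for reproducibility.
#' @return A [codon_profile_set()] of 64 profiles.
#' @export
#' @examples
#' ps <- generate_profiles("aa_determined", noise_sd = 0, n_replicates = 2,
#'                         seed = 1)
#' summarize_flux(ps[["CTA"]]) == summarize_flux(ps[["CTG"]])  # both Leu
generate_profiles <- function(model = c("aa_determined", "gc_linear",
                                        "iid_noise"),
                              intercept = 1.0, gc_slope = 0.1,
                              noise_sd = 0.05, level_sd = 0.25,
                              n_atoms_per_base = 4L, n_replicates = 50L,
                              seed = 1L) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0, level_sd >= 0, n_atoms_per_base >= 1L,
            n_replicates >= 1L)
  n_atoms <- 5L * as.integer(n_atoms_per_base)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  code <- canonical_code()
  labels <- sort(unique(unclass(code)))
  lab_level <- stats::setNames(stats::rnorm(length(labels), intercept,
                                            level_sd), labels)
  # latent correlation modes per label (aa_determined keys corr on the
  # amino acid so synonymous codons share structure exactly)
  n_modes <- 3L
  lab_modes <- lapply(labels, function(l) {
    matrix(stats::rnorm(n_atoms * n_modes), n_atoms, n_modes)
  })
  names(lab_modes) <- labels

  gc_count <- vapply(strsplit(codons(), "", fixed = TRUE),
                     function(b) sum(b %in% c("G", "C")), integer(1))
  names(gc_count) <- codons()

  profiles <- lapply(codons(), function(cd) {
    lab <- unclass(code)[[cd]]
    level <- switch(model,
      aa_determined = lab_level[[lab]],
      gc_linear = intercept + gc_slope * gc_count[[cd]],
      iid_noise = stats::rnorm(1, intercept, level_sd))
    modes <- switch(model,
      aa_determined = lab_modes[[lab]],
      matrix(stats::rnorm(n_atoms * n_modes), n_atoms, n_modes))
    flux_acc <- numeric(n_atoms)
    corr_acc <- matrix(0, n_atoms, n_atoms)
    for (r in seq_len(n_replicates)) {
      fl <- level + stats::rnorm(n_atoms, 0, noise_sd)
      flux_acc <- flux_acc + pmax(fl, 0)
      w <- modes + matrix(stats::rnorm(n_atoms * n_modes, 0, noise_sd),
                          n_atoms, n_modes)
      cv <- tcrossprod(w) + diag(0.1, n_atoms)
      corr_acc <- corr_acc + stats::cov2cor(cv)
    }
    codon_profile(cd, flux_acc / n_replicates, corr_acc / n_replicates,
                  n_replicates = n_replicates)
  })
  codon_profile_set(profiles)
}

#' Expected per-transition dFLUX under the noiseless gc_linear model
#'
#' Analytic oracle companion to [generate_profiles()]: with
#' \code{noise_sd = 0} the gc_linear model gives every transition an
#' impact of \code{gc_slope} times the absolute change in codon G/C
#' count, i.e. 0 for A<->T and C<->G substitutions and \code{gc_slope}
#' otherwise.
#'
#' @param gc_slope Slope used in the generator.
#' @return An [impact_table()] with metric \code{"dFLUX"}.
#' @export
gc_linear_expected_impacts <- function(gc_slope = 0.1) {
  tr <- enumerate_transitions()
  gc_count <- vapply(strsplit(codons(), "", fixed = TRUE),
                     function(b) sum(b %in% c("G", "C")), integer(1))
  ti <- transition_index()
  tr$value <- gc_slope * abs(gc_count[ti$from_idx] - gc_count[ti$to_idx])
  new_impact_table(tr, "dFLUX")
}
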