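#' @include code_tables.R
NULL

#' Per-codon molecular dynamics summary profile
#'
#' Holds replicate-averaged summaries for one codon over the backbone-atom
#' mask of the 5-nucleotide window (codon plus one flanking base each
#' side): a per-atom fluctuation vector (Angstrom) and an atomic
#' correlation matrix over the same atoms.
#'
#' @param codon Codon string (RNA accepted).
#' @param flux Numeric vector of non-negative per-atom fluctuations.
#' @param corr Square symmetric correlation matrix with unit diagonal,
#'   dimension \code{length(flux)}.
#' @param n_replicates Number of replicate simulations averaged.
#' @param tol Tolerance for the symmetry/unit-diagonal checks.
#' @return Object of class \code{"codon_profile"}.
#' @export
codon_profile <- function(codon, flux, corr, n_replicates = 1L, tol = 1e-6) {
  codon <- normalize_codon(codon)
  if (is.na(codon)) stop("invalid codon")
  flux <- as.numeric(flux)
  if (length(flux) == 0L || any(!is.finite(flux)) || any(flux < 0)) {
    stop("flux must be a non-empty vector of non-negative finite values")
  }
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("corr must be a square matrix")
  }
  if (nrow(corr) != length(flux)) {
    stop("corr dimension must match the flux mask (", length(flux), " atoms)")
  }
  if (max(abs(corr - t(corr))) > tol) stop("corr must be symmetric")
  if (max(abs(diag(corr) - 1)) > tol) stop("corr must have unit diagonal")
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  structure(list(codon = codon, flux = flux, corr = corr,
                 n_replicates = as.integer(n_replicates)),
            class = "codon_profile")
}

#' @export
print.codon_profile <- function(x, ...) {
  cat("<codon_profile>", x$codon, "-", length(x$flux), "mask atoms,",
      x$n_replicates, "replicate(s)\n")
  invisible(x)
}

#' Bundle 64 codon profiles into a profile set
#'
#' @param profiles List of [codon_profile()] objects, one per codon; all
#'   must share the same mask dimension.
#' @return Named list of class \code{"codon_profile_set"} in [codons()]
#'   order.
#' @export
codon_profile_set <- function(profiles) {
  stopifnot(is.list(profiles))
  cods <- vapply(profiles, function(p) p$codon, character(1))
  missing <- setdiff(codons(), cods)
  if (length(missing)) {
    stop("missing profiles for codon(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cods)) stop("duplicate codon profiles")
  dims <- vapply(profiles, function(p) length(p$flux), integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all 64 profiles must share identical mask dimensions")
  }
  profiles <- profiles[match(codons(), cods)]
  structure(stats::setNames(profiles, codons()), class = "codon_profile_set")
}

as_codon_profile_set <- function(x) {
  if (inherits(x, "codon_profile_set")) x else codon_profile_set(x)
}

#' @export
print.codon_profile_set <- function(x, ...) {
  cat("<codon_profile_set> 64 codons,", length(x[[1]]$flux), "mask atoms,",
      x[[1]]$n_replicates, "replicate(s)\n")
  invisible(x)
}

#' Read a per-atom fluctuation table
#'
#' Parses the two-column whitespace-delimited dialect written by
#' trajectory-analysis tools (atom index, RMSF in Angstrom).  Lines
#' starting with \code{#} and blank lines are skipped.
#'
#' @param file Path to the table.
#' @return Data frame with \code{atom_index} and \code{fluctuation}.
#' @export
read_rmsf <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(atom_index = integer(0), fluctuation = numeric(0)))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  parse_row <- function(k) {
    f <- fields[[k]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 2L || anyNA(v)) {
      stop("malformed fluctuation row at line ", idx[k], ": '",
           lines[idx[k]], "'")
    }
    v
  }
  m <- t(vapply(seq_along(fields), parse_row, numeric(2)))
  rec <- data.frame(atom_index = as.integer(m[, 1]), fluctuation = m[, 2])
  if (any(rec$fluctuation < 0)) stop("negative fluctuation value")
  if (is.unsorted(rec$atom_index, strictly = TRUE)) {
    stop("atom indices must be strictly increasing")
  }
  rec
}

#' Read a square atomic correlation matrix
#'
#' Whitespace-delimited numeric text; \code{#} comment lines skipped.  The
#' matrix is checked to be square, symmetric within \code{tol} (then
#' symmetrized) and unit-diagonal within \code{tol} (then snapped to 1).
#'
#' @param file Path to the matrix file.
#' @param tol Tolerance (default 1e-6).
#' @return Numeric matrix.
#' @export
read_corr_matrix <- function(file, tol = 1e-6) {
  m <- as.matrix(utils::read.table(file, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("correlation matrix contains non-numeric entries")
  if (nrow(m) != ncol(m)) {
    stop("correlation matrix is not square: ", nrow(m), " x ", ncol(m))
  }
  if (max(abs(m - t(m))) > tol) {
    stop("correlation matrix asymmetric beyond tolerance ", tol)
  }
  if (max(abs(diag(m) - 1)) > tol) {
    stop("correlation matrix diagonal differs from 1 beyond tolerance ", tol)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Build replicate-averaged profiles from per-replicate summaries
#'
#' Fluctuation vectors are averaged per atom over replicates, correlation
#' matrices entry-wise, then the backbone mask is applied.  Inputs are
#' assumed to be production-window summaries (equilibration already
#' discarded upstream).
#'
#' @param flux_reps Named list (by codon) of lists of numeric per-atom
#'   fluctuation vectors, one per replicate.
#' @param corr_reps Named list (by codon) of lists of square correlation
#'   matrices, aligned with \code{flux_reps}.
#' @param mask Integer vector of atom indices forming the 5-nucleotide
#'   backbone mask; default keeps all atoms.
#' @return A [codon_profile_set()].
#' @export
build_profiles <- function(flux_reps, corr_reps, mask = NULL) {
  cods <- names(flux_reps)
  missing <- setdiff(codons(), normalize_codon(cods))
  if (length(missing)) {
    stop("missing replicate data for codon(s): ",
         paste(missing, collapse = ", "))
  }
  if (!identical(sort(names(corr_reps)), sort(cods))) {
    stop("flux and correlation replicate lists must cover the same codons")
  }
  profiles <- lapply(cods, function(cd) {
    fl <- flux_reps[[cd]]
    cl <- corr_reps[[cd]]
    if (!length(fl) || !length(cl)) stop("no replicates for codon ", cd)
    nat <- unique(vapply(fl, length, integer(1)))
    ncr <- unique(vapply(cl, nrow, integer(1)))
    if (length(nat) != 1L || length(ncr) != 1L || nat != ncr) {
      stop("inconsistent replicate dimensions for codon ", cd)
    }
    flux <- Reduce(`+`, fl) / length(fl)
    corr <- Reduce(`+`, cl) / length(cl)
    m <- if (is.null(mask)) seq_len(nat) else as.integer(mask)
    if (!length(m) || any(m < 1L) || any(m > nat)) {
      stop("mask indices out of range for codon ", cd)
    }
    codon_profile(cd, flux[m], corr[m, m, drop = FALSE],
                  n_replicates = length(fl))
  })
  codon_profile_set(profiles)
}

#' Write a profile set to one consolidated TSV
#'
#' Long format with columns \code{codon}, \code{kind} (\code{flux} or
#' \code{corr}), \code{i}, \code{j} (atom indices; \code{j} is \code{NA}
#' for flux rows), \code{value}, \code{n_replicates}.  Only the upper
#' triangle (including diagonal) of each correlation matrix is stored.
#'
#' @param profiles A [codon_profile_set()].
#' @param file Output path.
#' @export
write_profiles <- function(profiles, file) {
  profiles <- as_codon_profile_set(profiles)
  rows <- lapply(profiles, function(p) {
    n <- length(p$flux)
    ut <- which(upper.tri(p$corr, diag = TRUE), arr.ind = TRUE)
    rbind(
      data.frame(codon = p$codon, kind = "flux", i = seq_len(n), j = NA,
                 value = p$flux, n_replicates = p$n_replicates),
      data.frame(codon = p$codon, kind = "corr", i = ut[, 1], j = ut[, 2],
                 value = p$corr[ut], n_replicates = p$n_replicates))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a consolidated profile TSV written by [write_profiles()]
#'
#' @param file Path to the TSV.
#' @return A [codon_profile_set()].
#' @export
read_profiles <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("codon", "kind", "i", "j", "value", "n_replicates")
  if (!all(need %in% names(tab))) {
    stop("profile file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  profiles <- lapply(split(tab, tab$codon), function(d) {
    fl <- d[d$kind == "flux", ]
    cr <- d[d$kind == "corr", ]
    flux <- fl$value[order(fl$i)]
    n <- length(flux)
    cm <- matrix(0, n, n)
    cm[cbind(cr$i, cr$j)] <- cr$value
    cm[cbind(cr$j, cr$i)] <- cr$value
    codon_profile(d$codon[1], flux, cm, n_replicates = d$n_replicates[1])
  })
  codon_profile_set(unname(profiles))
}
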