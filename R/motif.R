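## Nucleotide profiles (PWMs and PSSVs), information content and the
## scrambled-PWM controls.

#' Construct a nucleotide profile (PWM or PSSV)
#'
#' A profile is a tibble with columns `pos`, `A`, `C`, `G`, `T`: one
#' probability row per motif position.  PWMs additionally carry the counts
#' and pseudocount they were built from as attributes.
#'
#' @param x An L x 4 matrix (A C G T columns) of per-position probabilities,
#'   or a data frame with `pos`, `A`, `C`, `G`, `T` columns.
#' @param positions Optional position labels (default `1:L`).
#' @param type `"pwm"` or `"pssv"`.
#' @return A tibble of class `c(type, "nt_profile")`.
#' @export
new_profile <- function(x, positions = NULL, type = c("pssv", "pwm")) {
  type <- match.arg(type)
  m <- profile_matrix(x)
  if (any(abs(rowSums(m) - 1) > 1e-6)) abort("Profile rows must sum to 1.")
  if (is.null(positions)) positions <- profile_positions(x)
  if (is.null(positions)) positions <- seq_len(nrow(m))
  out <- tibble::tibble(pos = positions, A = m[, 1], C = m[, 2],
                        G = m[, 3], T = m[, 4])
  class(out) <- c(type, "nt_profile", class(out))
  out
}

## Coerce profile-like inputs to a plain L x 4 numeric matrix.
profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 4L) abort("Profile matrix must have 4 columns (A, C, G, T).")
    m <- x
  } else if (is.data.frame(x)) {
    if (!all(NUC %in% names(x))) abort("Profile data frame needs A, C, G, T columns.")
    m <- as.matrix(x[, NUC])
  } else {
    abort("Cannot interpret this object as a nucleotide profile.")
  }
  colnames(m) <- NUC
  m
}

profile_positions <- function(x) {
  if (is.data.frame(x) && "pos" %in% names(x)) x$pos else
    if (is.matrix(x)) seq_len(nrow(x)) else NULL
}

#' @describeIn new_profile Long format (`pos`, `nucleotide`, `prob`).
#' @param ... Unused.
#' @export
tidy.nt_profile <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::all_of(NUC),
                      names_to = "nucleotide", values_to = "prob")
}

#' Build a position weight matrix from site groups
#'
#' Column-wise nucleotide counts over the selected species' sequences
#' (optionally restricted to a column range), plus a pseudocount per cell,
#' normalized per column.  A single-species PWM is the classical
#' within-species motif model; pooling orthologous sequence from several
#' species gives the multi-species variant.
#'
#' @param groups Site-group tibble.
#' @param species Character vector of species to pool; default all.
#' @param columns Columns to include (1-based); default all.
#' @param pseudocount Added to every cell before normalization (default 0.5).
#' @return A `pwm` profile with `counts` and `pseudocount` attributes.
#' @export
build_pwm <- function(groups, species = NULL, columns = NULL, pseudocount = 0.5) {
  if (is.null(species)) species <- unique(groups$species)
  if (length(species) == 0L) abort("`species` must be non-empty.")
  seqs <- groups$seq[groups$species %in% species]
  if (length(seqs) == 0L) abort("No sequences for the requested species.")
  L0 <- unique(nchar(seqs))
  if (length(L0) != 1L) abort("Sequences have unequal lengths.")
  if (is.null(columns)) columns <- seq_len(L0)
  if (any(columns < 1L | columns > L0)) abort("`columns` out of range.")
  counts <- t(vapply(columns, function(cc) {
    tabulate(encode_nuc(substring(seqs, cc, cc)), nbins = 4)
  }, numeric(4)))
  colnames(counts) <- NUC
  if (pseudocount < 0) abort("`pseudocount` must be >= 0.")
  prob <- normalize_rows(counts + pseudocount)
  out <- new_profile(prob, positions = seq_along(columns), type = "pwm")
  attr(out, "counts") <- counts
  attr(out, "pseudocount") <- pseudocount
  attr(out, "species") <- species
  out
}

#' Scramble the columns of a PWM
#'
#' Returns a PWM whose column `i` is column `order[i]` of the input (orders
#' are 1-based, as conventionally printed).  Scrambled motifs keep the
#' column composition — hence the information content — of the original
#' while destroying its positional arrangement, and serve as controls.
#'
#' @param pwm A profile.
#' @param order A permutation of `1:L`.
#' @return A profile of the same class.
#' @export
#' @examples
#' scramble_pwm(new_profile(matrix(0.25, 4, 4)), c(2, 1, 4, 3))
scramble_pwm <- function(pwm, order) {
  m <- profile_matrix(pwm)
  L <- nrow(m)
  if (length(order) != L || !setequal(order, seq_len(L))) {
    abort(sprintf("`order` must be a permutation of 1..%d.", L))
  }
  out <- new_profile(m[order, , drop = FALSE], positions = seq_len(L),
                     type = if (inherits(pwm, "pwm")) "pwm" else "pssv")
  if (!is.null(attr(pwm, "counts"))) {
    attr(out, "counts") <- attr(pwm, "counts")[order, , drop = FALSE]
    attr(out, "pseudocount") <- attr(pwm, "pseudocount")
  }
  out
}

#' The three published scrambled CTCF column orders
#'
#' Column orders (1-based positions in the original 19-column core motif)
#' for the three scrambled CTCF control motifs.
#'
#' @format A named list of three integer vectors.
#' @export
ctcf_scramble_orders <- list(
  scramble1 = c(8L, 12L, 18L, 2L, 15L, 17L, 6L, 4L, 11L, 5L, 16L, 19L, 14L, 13L, 9L, 1L, 3L, 10L, 7L),
  scramble2 = c(11L, 5L, 4L, 9L, 2L, 16L, 10L, 12L, 14L, 7L, 6L, 8L, 18L, 19L, 3L, 13L, 15L, 17L, 1L),
  scramble3 = c(13L, 16L, 9L, 5L, 7L, 6L, 4L, 11L, 1L, 2L, 12L, 17L, 18L, 8L, 10L, 15L, 3L, 14L, 19L)
)

#' Information content of a profile, in bits
#'
#' \deqn{I = \sum_{i=1}^{L} \big(2 + \sum_{j=1}^{4} W_{ij}\log_2 W_{ij}\big)}
#' — the total sequence-logo height, with the uniform background hard-coded
#' in the `2 +` term and \eqn{0\log 0 \equiv 0}.
#'
#' @param x A profile (or L x 4 probability matrix).
#' @return Total information in bits, between 0 and 2L.
#' @export
information_content <- function(x) {
  m <- profile_matrix(x)
  lg <- ifelse(m > 0, log2(m), 0)
  sum(2 + rowSums(m * lg))
}

#' Relative information loss of a PSSV against its PWM
#'
#' \eqn{(I_{PWM} - I_{PSSV}) / I_{PWM}}: the fraction of the PWM's
#' information the fitted stationary vectors fail to retain.  Negative when
#' the PSSV is sharper than the PWM.
#'
#' @param pwm,pssv Profiles of equal length.
#' @return A single fraction.
#' @export
information_loss <- function(pwm, pssv) {
  if (nrow(profile_matrix(pwm)) != nrow(profile_matrix(pssv))) {
    abort("PWM and PSSV must have the same number of positions.")
  }
  i_pwm <- information_content(pwm)
  if (i_pwm <= 0) abort("PWM has zero information content; loss is undefined.")
  (i_pwm - information_content(pssv)) / i_pwm
}
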