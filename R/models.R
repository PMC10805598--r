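## Nucleotide substitution models.  Convention throughout: transition
## matrices are column-stochastic with T[alpha, beta] = P(descendant alpha |
## ancestor beta); columns index the ancestor.  Alphabet order A, C, G, T.

#' Construct a substitution model
#'
#' @param family `"F81"` or `"HKY85"`.
#' @param pi Stationary vector (4 probabilities, A C G T order).
#' @param kappa Transition/transversion rate ratio; required for HKY85,
#'   forbidden for F81.
#' @return A `subst_model` object.
#' @export
#' @examples
#' subst_model("F81", mammal_background)
#' subst_model("HKY85", mammal_background, kappa = 2)
subst_model <- function(family = c("F81", "HKY85"), pi = mammal_background,
                        kappa = NULL) {
  family <- match.arg(family)
  pi <- check_simplex(pi)
  if (family == "HKY85") {
    if (is.null(kappa)) abort("HKY85 requires `kappa`.")
    if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
      abort("`kappa` must be a single positive number.")
    }
  } else if (!is.null(kappa)) {
    abort("`kappa` is only meaningful for HKY85.")
  }
  structure(list(family = family, pi = pi, kappa = kappa),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s, pi = (%s)%s\n", x$family,
              paste(sprintf("%.3f", x$pi), collapse = ", "),
              if (is.null(x$kappa)) "" else sprintf(", kappa = %.3f", x$kappa)))
  invisible(x)
}

#' F81 transition probability matrix
#'
#' The Felsenstein 1981 model in proximity form: with \eqn{q = e^{-t}},
#' \deqn{T_{\alpha\beta}(q) = q\,\delta_{\alpha\beta} + (1-q)\,\pi_\alpha,}
#' i.e. with probability \eqn{q} the nucleotide is unchanged over the branch
#' and with probability \eqn{1-q} it is redrawn from the stationary vector.
#'
#' @param q Proximity in \[0, 1\] (`q = 0` is the infinite-time limit,
#'   admitted for closed-form checks).
#' @param pi Stationary vector.
#' @return A 4x4 column-stochastic matrix, `T[alpha, beta] = P(alpha | beta)`.
#' @export
#' @examples
#' f81_transition(0.5, c(0.3, 0.2, 0.2, 0.3))
f81_transition <- function(q, pi) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    abort("`q` must be a single value in [0, 1].")
  }
  pi <- check_simplex(pi)
  T <- q * diag(4) + (1 - q) * matrix(pi, 4, 4)
  dimnames(T) <- list(NUC, NUC)
  T
}

#' HKY85 transition probability matrix
#'
#' Closed-form transition probabilities for the Hasegawa-Kishino-Yano 1985
#' model.  The generator is left unnormalized with transversion rate 1 and
#' transition rate `kappa`, so that at `kappa = 1` the model coincides
#' exactly with F81 at proximity \eqn{q = e^{-t}} — one shared time unit
#' across both families.
#'
#' @param t Evolutionary time (\eqn{\ge 0}; `Inf` gives the stationary limit).
#' @param pi Stationary vector.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return A 4x4 column-stochastic matrix, `T[alpha, beta] = P(alpha | beta)`.
#' @export
#' @examples
#' hky85_transition(0.3, mammal_background, kappa = 2)
hky85_transition <- function(t, pi, kappa) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) abort("`t` must be a single value >= 0.")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) abort("`kappa` must be > 0.")
  pi <- check_simplex(pi)
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  eb <- exp(-t)
  eR <- exp(-(piR * kappa + piY) * t)   # purine-transition eigenmode
  eY <- exp(-(piY * kappa + piR) * t)   # pyrimidine-transition eigenmode
  T <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  grp <- c(A = "R", C = "Y", G = "R", T = "Y")
  for (b in NUC) {
    for (a in NUC) {
      if (grp[a] != grp[b]) {
        T[a, b] <- pi[a] * (1 - eb)                       # transversion
      } else {
        pg <- if (grp[a] == "R") piR else piY
        eg <- if (grp[a] == "R") eR else eY
        other <- 1 - pg
        if (a == b) {
          T[a, b] <- pi[a] + pi[a] * (other / pg) * eb + ((pg - pi[a]) / pg) * eg
        } else {
          T[a, b] <- pi[a] + pi[a] * (other / pg) * eb - (pi[a] / pg) * eg
        }
      }
    }
  }
  T
}

#' Residual of the stationarity condition
#'
#' For a column-stochastic transition matrix `T` and a candidate stationary
#' vector, returns \eqn{\max_\alpha |\sum_\beta T_{\alpha\beta}\pi_\beta -
#' \pi_\alpha|}: zero iff `pi` is unchanged by one step of the model.
#'
#' @param T 4x4 column-stochastic matrix.
#' @param pi Candidate stationary vector.
#' @return A single non-negative residual.
#' @export
stationarity_check <- function(T, pi) {
  pi <- check_simplex(pi)
  max(abs(as.vector(T %*% pi) - pi))
}

## Transition matrix over one branch of proximity q under a model.
branch_matrix <- function(model, q) {
  if (model$family == "F81") {
    f81_transition(q, model$pi)
  } else {
    hky85_transition(if (q == 0) Inf else -log(q), model$pi, model$kappa)
  }
}
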