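## Maximum-likelihood inference: branch proximities (and kappa) on neutral
## columns, per-position stationary vectors (PSSVs) within motifs, marginal
## ancestral nucleotide posteriors at the root, and conditional PSSVs.
##
## Optimization parameterization (a package choice): q via logit, pi via
## softmax over 3 free coordinates, BFGS with numerical gradients,
## convergence judged on the log-likelihood.

## --- site-group plumbing --------------------------------------------------

## Keep only groups whose species set equals the tree's leaf set; returns
## the filtered tibble (message when groups are dropped).
complete_groups <- function(groups, tree, quiet = FALSE) {
  leaves <- tree$leaf_order
  keep <- groups |>
    dplyr::group_by(.data$site_id) |>
    dplyr::filter(!anyDuplicated(.data$species),
                  length(.data$species) == length(leaves),
                  all(sort(.data$species) == sort(leaves))) |>
    dplyr::ungroup()
  dropped <- dplyr::n_distinct(groups$site_id) - dplyr::n_distinct(keep$site_id)
  if (dropped > 0L && !quiet) {
    message(sprintf("Excluded %d site group(s) not covering all %d tree leaves.",
                    dropped, length(leaves)))
  }
  keep
}

## Sequences as a site x species character matrix (one string per cell).
group_seq_matrix <- function(groups, tree) {
  wide <- groups |>
    dplyr::select("site_id", "species", "seq") |>
    tidyr::pivot_wider(names_from = "species", values_from = "seq")
  L <- unique(nchar(unlist(wide[tree$leaf_order])))
  if (length(L) != 1L) abort("Site groups have unequal sequence lengths.")
  m <- as.matrix(wide[, tree$leaf_order, drop = FALSE])
  rownames(m) <- wide$site_id
  attr(m, "L") <- L
  m
}

## Integer pattern matrix (groups x leaves) at one alignment column.
patterns_at_column <- function(seq_mat, column) {
  chars <- substring(seq_mat, column, column)
  out <- matrix(encode_nuc(chars), nrow = nrow(seq_mat),
                dimnames = dimnames(seq_mat))
  storage.mode(out) <- "integer"
  out
}

## Collapse duplicate patterns: list(P = unique int matrix, n = counts).
aggregate_patterns <- function(P) {
  key <- as.vector(P %*% 4^(seq_len(ncol(P)) - 1))
  ord <- !duplicated(key)
  cnt <- as.vector(table(factor(key, levels = key[ord])))
  list(P = P[ord, , drop = FALSE], n = cnt)
}

## --- branch-proximity fitting ---------------------------------------------

#' Fit branch proximities (and kappa) on neutral positions
#'
#' Estimates one proximity \eqn{\hat q = e^{-\hat t}} per branch (plus the
#' transition/transversion ratio \eqn{\kappa} under HKY85) by maximizing the
#' log-likelihood of the observed nucleotides at presumed neutrally evolving
#' columns, with the stationary vector fixed to the genomic background.
#' Proximities are shared across positions; by default the neutral columns
#' are the outermost flank column on each side.
#'
#' Under a reversible model the two branches meeting at the root are only
#' identified through their product; both are reported, but only the product
#' is meaningful.
#'
#' @param groups Site-group tibble (`site_id`, `species`, `seq`, ...); groups
#'   not covering every tree leaf are excluded.
#' @param tree A `pssv_tree` giving the topology (branch lengths are
#'   re-estimated).
#' @param neutral_columns Integer column indices (1-based) of the neutral
#'   positions; default `c(1, L)`.
#' @param model `"F81"` or `"HKY85"`.
#' @param background Stationary vector assumed at neutral positions.
#' @param kappa_init,q_init Optimizer starting values.
#' @return A `branch_fit` with the fitted tree, `logLik`, convergence flag
#'   and (for HKY85) `kappa`; see [tidy.branch_fit()] / [glance.branch_fit()].
#' @export
fit_branch_proximities <- function(groups, tree,
                                   neutral_columns = NULL,
                                   model = c("F81", "HKY85"),
                                   background = mammal_background,
                                   kappa_init = 2, q_init = 0.9) {
  model <- match.arg(model)
  background <- check_simplex(background)
  groups <- complete_groups(groups, tree)
  sm <- group_seq_matrix(groups, tree)
  L <- attr(sm, "L")
  if (is.null(neutral_columns)) neutral_columns <- unique(c(1L, L))
  if (length(neutral_columns) < 1L) abort("Need at least one neutral column.")
  n_groups <- nrow(sm)
  if (n_groups < 50L) {
    warn(sprintf("Only %d site group(s): proximity estimates may be unstable.", n_groups))
  }
  P <- do.call(rbind, lapply(neutral_columns, function(cc) patterns_at_column(sm, cc)))
  agg <- aggregate_patterns(P)

  root_id <- tree$root$id
  ids <- setdiff(seq_len(tree$n_nodes), root_id)
  qvec <- rep(NA_real_, tree$n_nodes)

  if (model == "F81") {
    decomp <- decompose_sum_of_stars(tree)
    negll <- function(par) {
      qvec[ids] <- inv_logit(par)
      lik <- fast_likelihood(decomp, agg$P, background, qvec)
      -sum(agg$n * log(pmax(lik, 1e-300)))
    }
    par0 <- rep(logit(q_init), length(ids))
  } else {
    negll <- function(par) {
      qvec[ids] <- inv_logit(par[seq_along(ids)])
      m <- subst_model("HKY85", background, kappa = exp(par[length(par)]))
      partials <- prune_root_partials(tree, agg$P, m, q = qvec)
      lik <- as.vector(background %*% partials)
      -sum(agg$n * log(pmax(lik, 1e-300)))
    }
    par0 <- c(rep(logit(q_init), length(ids)), log(kappa_init))
  }

  opt <- optim(par0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  qhat <- rep(NA_real_, tree$n_nodes)
  qhat[ids] <- inv_logit(opt$par[seq_along(ids)])
  boundary <- which(qhat > 1 - 1e-6)
  if (length(boundary) > 0L) {
    qhat[boundary] <- 1 - 1e-9
    warn(sprintf("%d branch proximit%s at the q = 1 boundary (no observed substitutions); clamped.",
                 length(boundary), if (length(boundary) == 1L) "y" else "ies"))
  }
  if (opt$convergence != 0L) {
    warn(sprintf("Optimizer did not report convergence (code %d).", opt$convergence))
  }
  structure(list(
    tree = set_branch_proximities(tree, qhat),
    family = model,
    kappa = if (model == "HKY85") exp(opt$par[length(opt$par)]) else NULL,
    background = background,
    logLik = -opt$value,
    converged = opt$convergence == 0L,
    boundary_ids = boundary,
    n_groups = n_groups,
    neutral_columns = neutral_columns,
    n_patterns = nrow(agg$P)
  ), class = "branch_fit")
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit> %s, logLik = %.3f, %d groups, %s\n",
              x$family, x$logLik, x$n_groups,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$kappa)) cat(sprintf("  kappa = %.4f\n", x$kappa))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_branch_proximities One row per branch with fitted `t`, `q`.
#' @param x A `branch_fit`.
#' @param ... Unused.
#' @export
tidy.branch_fit <- function(x, ...) tidy(x$tree)

#' @describeIn fit_branch_proximities One-row fit summary.
#' @export
glance.branch_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$logLik,
    kappa = if (is.null(x$kappa)) NA_real_ else x$kappa,
    converged = x$converged,
    n_groups = x$n_groups,
    n_patterns = x$n_patterns,
    n_neutral_columns = length(x$neutral_columns)
  )
}

## --- PSSV fitting ---------------------------------------------------------

fit_pi_one_column <- function(tree, agg, family, kappa, decomp, floor) {
  emp <- tabulate(rep(as.vector(t(agg$P)), times = rep(agg$n, each = ncol(agg$P))),
                  nbins = 4)
  pi0 <- (emp + 1) / sum(emp + 4)
  par0 <- log(pi0[1:3] / pi0[4])
  qvec <- branch_q(tree)
  negll <- function(par) {
    pi <- softmax4(par)
    lik <- if (family == "F81") {
      fast_likelihood(decomp, agg$P, pi, qvec)
    } else {
      m <- subst_model("HKY85", pi, kappa = kappa)
      as.vector(pi %*% prune_root_partials(tree, agg$P, m))
    }
    -sum(agg$n * log(pmax(lik, 1e-300)))
  }
  opt <- optim(par0, negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  pi_hat <- softmax4(opt$par)
  floored <- any(pi_hat < floor)
  pi_hat <- pmax(pi_hat, floor)
  pi_hat <- pi_hat / sum(pi_hat)
  list(pi = pi_hat, logLik = -opt$value,
       converged = opt$convergence == 0L, floored = floored)
}

#' Fit position-specific stationary vectors
#'
#' With the branch proximities (and, for HKY85, kappa) fixed, maximizes the
#' likelihood of the observed nucleotides at each requested column
#' independently over the column's stationary vector \eqn{\pi} on the
#' 3-simplex.  The fitted rows form the PSSV: the long-term nucleotide
#' distribution the evolutionary model infers at each motif position,
#' combining mutation and (purifying) selection.
#'
#' @inheritParams fit_branch_proximities
#' @param tree A fitted `pssv_tree` (e.g. `fit_branch_proximities(...)$tree`).
#' @param columns Columns to fit (1-based); default all.
#' @param kappa Fixed kappa (HKY85 only).
#' @param floor Probability floor applied to fitted components to avoid
#'   boundary log-singularities (default 1e-6).
#' @return A `pssv_fit`; its `$pssv` element is a `pssv` profile tibble
#'   (`pos`, `A`, `C`, `G`, `T`).
#' @export
fit_pssv <- function(groups, tree, columns = NULL,
                     model = c("F81", "HKY85"), kappa = NULL, floor = 1e-6) {
  model <- match.arg(model)
  if (model == "HKY85" && is.null(kappa)) abort("HKY85 requires `kappa` (fit it with fit_branch_proximities).")
  groups <- complete_groups(groups, tree)
  sm <- group_seq_matrix(groups, tree)
  L <- attr(sm, "L")
  if (is.null(columns)) columns <- seq_len(L)
  if (any(columns < 1L | columns > L)) abort("`columns` out of range.")
  decomp <- if (model == "F81") decompose_sum_of_stars(tree) else NULL
  fits <- lapply(columns, function(cc) {
    agg <- aggregate_patterns(patterns_at_column(sm, cc))
    fit_pi_one_column(tree, agg, model, kappa, decomp, floor)
  })
  mat <- do.call(rbind, lapply(fits, `[[`, "pi"))
  colnames(mat) <- NUC
  floored <- vapply(fits, `[[`, logical(1), "floored")
  if (any(floored)) {
    warn(sprintf("Stationary components at column(s) %s hit the %g floor (nucleotide unseen).",
                 paste(columns[floored], collapse = ", "), floor))
  }
  nonconv <- !vapply(fits, `[[`, logical(1), "converged")
  if (any(nonconv)) {
    warn(sprintf("Optimizer non-convergence at column(s) %s.",
                 paste(columns[nonconv], collapse = ", ")))
  }
  structure(list(
    pssv = new_profile(mat, positions = columns, type = "pssv"),
    columns = columns,
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    converged = !nonconv,
    family = model,
    kappa = kappa,
    floor = floor,
    n_groups = nrow(sm)
  ), class = "pssv_fit")
}

#' @export
print.pssv_fit <- function(x, ...) {
  cat(sprintf("<pssv_fit> %s, %d position(s), %d groups, total logLik = %.3f\n",
              x$family, length(x$columns), x$n_groups, sum(x$logLik)))
  print(x$pssv)
  invisible(x)
}

#' @describeIn fit_pssv Long-format fitted PSSV (`pos`, `nucleotide`, `prob`).
#' @param x A `pssv_fit`.
#' @param ... Unused.
#' @export
tidy.pssv_fit <- function(x, ...) tidy(x$pssv)

#' @describeIn fit_pssv One-row fit summary.
#' @export
glance.pssv_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_positions = length(x$columns),
    n_groups = x$n_groups,
    logLik = sum(x$logLik),
    all_converged = all(x$converged),
    information_bits = information_content(x$pssv)
  )
}

## --- ancestral posteriors -------------------------------------------------

#' Posterior distribution of the root (ancestral) nucleotide
#'
#' For each site group, computes \eqn{p(\alpha \mid leaves) \propto
#' P(leaves \mid root = \alpha)\, b_\alpha} at one alignment column, where
#' the prior \eqn{b} is the genomic background.  The conditional likelihoods
#' are the pruning root partials; the transition probabilities use the
#' background stationary vector (override via `transition_pi`).
#'
#' @inheritParams fit_pssv
#' @param position Alignment column (1-based).
#' @param prior Prior over the root nucleotide (default background).
#' @param transition_pi Stationary vector used inside the transition
#'   probabilities (default background).
#' @return Tibble `site_id`, `position`, `A`, `C`, `G`, `T`; rows sum to 1.
#' @export
ancestral_posterior <- function(groups, tree, position,
                                model = c("F81", "HKY85"), kappa = NULL,
                                prior = mammal_background,
                                transition_pi = mammal_background) {
  model <- match.arg(model)
  prior <- check_simplex(prior, "prior")
  if (model == "HKY85" && is.null(kappa)) abort("HKY85 requires `kappa`.")
  groups <- complete_groups(groups, tree)
  sm <- group_seq_matrix(groups, tree)
  if (position < 1L || position > attr(sm, "L")) abort("`position` out of range.")
  P <- patterns_at_column(sm, position)
  m <- if (model == "F81") subst_model("F81", transition_pi)
       else subst_model("HKY85", transition_pi, kappa = kappa)
  partials <- prune_root_partials(tree, P, m)
  post <- partials * prior
  tot <- colSums(post)
  if (any(tot <= 0)) abort("Zero total likelihood at the root: check proximities.")
  post <- t(post) / tot
  tibble::tibble(
    site_id = rownames(P),
    position = position,
    A = post[, 1], C = post[, 2], G = post[, 3], T = post[, 4]
  )
}

#' Conditional PSSV given an ancestral nucleotide
#'
#' Refits the PSSV on the subset of site groups whose posterior probability
#' of ancestral nucleotide `nucleotide` at `position` exceeds `threshold`
#' (strictly).  Differences between PSSVs conditioned on different ancestral
#' nucleotides at the same position reveal positional coupling /
#' compensatory pressure.
#'
#' @inheritParams fit_pssv
#' @inheritParams ancestral_posterior
#' @param nucleotide The conditioning ancestral nucleotide, one of A/C/G/T.
#' @param threshold Posterior cutoff (default 0.5, strict inequality; ties
#'   at the threshold are excluded).
#' @param min_groups Warn when the selected subset is smaller than this.
#' @return A `conditional_pssv` (a `pssv_fit` plus `n_selected`,
#'   `site_ids`, and the condition).
#' @export
conditional_pssv <- function(groups, tree, position, nucleotide,
                             columns = NULL, model = c("F81", "HKY85"),
                             kappa = NULL, threshold = 0.5,
                             prior = mammal_background,
                             transition_pi = mammal_background,
                             min_groups = 30, floor = 1e-6) {
  model <- match.arg(model)
  if (!nucleotide %in% NUC) abort("`nucleotide` must be one of A, C, G, T.")
  post <- ancestral_posterior(groups, tree, position, model = model,
                              kappa = kappa, prior = prior,
                              transition_pi = transition_pi)
  sel <- post$site_id[post[[nucleotide]] > threshold]
  if (length(sel) == 0L) {
    abort(sprintf(
      "No site group has posterior P(root = %s at column %d) > %g; cannot fit a conditional PSSV.",
      nucleotide, position, threshold))
  }
  if (length(sel) < min_groups) {
    warn(sprintf("Conditional subset has only %d group(s); PSSV may be noisy.", length(sel)))
  }
  sub <- dplyr::filter(groups, .data$site_id %in% sel)
  fit <- fit_pssv(sub, tree, columns = columns, model = model,
                  kappa = kappa, floor = floor)
  fit$n_selected <- length(sel)
  fit$site_ids <- sel
  fit$condition <- list(position = position, nucleotide = nucleotide,
                        threshold = threshold)
  class(fit) <- c("conditional_pssv", class(fit))
  fit
}

#' @export
print.conditional_pssv <- function(x, ...) {
  cat(sprintf("<conditional_pssv> root %s at column %d (posterior > %g): %d group(s)\n",
              x$condition$nucleotide, x$condition$position,
              x$condition$threshold, x$n_selected))
  NextMethod()
}

#' @describeIn conditional_pssv Adds the condition and subset size.
#' @param x A `conditional_pssv`.
#' @param ... Unused.
#' @export
glance.conditional_pssv <- function(x, ...) {
  g <- NextMethod()
  dplyr::mutate(g,
                condition_position = x$condition$position,
                condition_nucleotide = x$condition$nucleotide,
                n_selected = x$n_selected)
}

## --- Jensen-Shannon profile -----------------------------------------------

#' Per-position Jensen-Shannon divergence between two profiles
#'
#' \eqn{JSD(p, q) = \frac12 KL(p\|m) + \frac12 KL(q\|m)} with
#' \eqn{m = (p+q)/2}, logs base 2, so values lie in \[0, 1\] bits; used to
#' compare conditional PSSVs position by position.
#'
#' @param a,b Profiles (`pssv`/`pwm` tibbles, plain `pos A C G T` data
#'   frames, or L x 4 matrices) of equal length.
#' @return Tibble `pos`, `jsd`.
#' @export
jsd_profile <- function(a, b) {
  ma <- profile_matrix(a)
  mb <- profile_matrix(b)
  if (nrow(ma) != nrow(mb)) abort("Profiles have different lengths.")
  tibble::tibble(
    pos = profile_positions(a),
    jsd = vapply(seq_len(nrow(ma)),
                 function(i) js_divergence(ma[i, ], mb[i, ]), numeric(1))
  )
}
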