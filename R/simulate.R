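## Simulator of aligned TFBS site groups evolving along a tree under
## F81/HKY85 with per-position stationary vectors — the generative model the
## inference machinery assumes, used to validate every fitting operation by
## parameter recovery.

## Sample one descendant state per position given the parent states.
evolve_branch <- function(parent, q, pim, family, kappa) {
  L <- length(parent)
  if (family == "F81") {
    ## with probability q copy the parent, else redraw from the column's pi
    keep <- runif(L) < q
    child <- parent
    redraw <- which(!keep)
    for (l in redraw) child[l] <- sample.int(4L, 1L, prob = pim[l, ])
    child
  } else {
    t <- -log(q)
    child <- integer(L)
    for (l in seq_len(L)) {
      T <- hky85_transition(t, pim[l, ], kappa)
      child[l] <- sample.int(4L, 1L, prob = T[, parent[l]])
    }
    child
  }
}

simulate_one_site <- function(tree, pim, family, kappa, coupling) {
  L <- nrow(pim)
  root <- vapply(seq_len(L), function(l) sample.int(4L, 1L, prob = pim[l, ]),
                 integer(1))
  ## ancestral-state coupling: a root nucleotide at one position redirects
  ## the root draw at another; descendant evolution stays per-column
  for (rule in coupling) {
    if (root[rule$position] == rule$nucleotide_idx) {
      root[rule$target] <- sample.int(4L, 1L, prob = rule$pi)
    }
  }
  leaves <- list()
  rec <- function(node, state) {
    if (length(node$children) == 0L) {
      leaves[[node$name]] <<- state
      return(invisible())
    }
    for (ch in node$children) {
      rec(ch, evolve_branch(state, ch$q, pim, family, kappa))
    }
  }
  rec(tree$root, root)
  list(root = root, leaves = leaves)
}

#' Simulate orthologous TFBS site groups along a tree
#'
#' For every simulated site and position, a root nucleotide is drawn from
#' that position's stationary vector (optionally redirected by ancestral
#' coupling rules), then propagated down the tree with the exact model
#' transition matrices \eqn{T_{\alpha\beta}(q)}.  The latent root sequences
#' are returned alongside the leaf data so ancestral-inference accuracy can
#' be scored against the truth.
#'
#' @param tree A `pssv_tree` with proximities on every branch.
#' @param pi Either a single stationary vector (every position identical) or
#'   a profile / L x 4 matrix of per-position stationary vectors.
#' @param n_sites Number of site groups to simulate.
#' @param model `"F81"` or `"HKY85"`.
#' @param kappa Transition/transversion ratio (HKY85 only).
#' @param coupling Optional list of rules, each
#'   `list(position =, nucleotide =, target =, pi =)`: when the root draw at
#'   `position` equals `nucleotide`, the root at `target` is redrawn from
#'   `pi`.
#' @param seed Mandatory integer seed; one master seed expands into
#'   per-site substreams, so each site's draw is independent of order.
#' @return A list with `groups` (site-group tibble; the reference species is
#'   the tree's first leaf) and `roots` (tibble `site_id`, `root_seq`).
#' @export
#' @examples
#' tr <- study_topology("primates")
#' sim <- simulate_groups(tr, mammal_background, n_sites = 5, seed = 1)
#' sim$groups
simulate_groups <- function(tree, pi, n_sites, model = c("F81", "HKY85"),
                            kappa = NULL, coupling = NULL, seed) {
  model <- match.arg(model)
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  if (n_sites < 1L) abort("`n_sites` must be >= 1.")
  if (model == "HKY85" && is.null(kappa)) abort("HKY85 requires `kappa`.")
  pim <- if (is.null(dim(pi)) && !is.data.frame(pi)) {
    matrix(check_simplex(pi), 1, 4)
  } else profile_matrix(pi)
  L <- nrow(pim)
  coupling <- lapply(coupling, function(rule) {
    if (rule$position < 1L || rule$position > L ||
        rule$target < 1L || rule$target > L) {
      abort("Coupling rule references an out-of-range position.")
    }
    rule$nucleotide_idx <- encode_nuc(rule$nucleotide)
    rule$pi <- check_simplex(rule$pi)
    rule
  })
  if (anyNA(branch_q(tree)[-tree$root$id])) abort("Tree branches need proximities.")
  leaves <- tree$leaf_order
  sites <- lapply(seq_len(n_sites), function(i) {
    withr::with_seed(substream_seed(seed, i),
                     simulate_one_site(tree, pim, model, kappa, coupling))
  })
  ids <- sprintf("site%05d", seq_len(n_sites))
  groups <- tidyr::expand_grid(site_id = ids, species = leaves) |>
    dplyr::mutate(
      chrom = "synthetic",
      start = (match(.data$site_id, ids) - 1L) * L,
      end = .data$start + L,
      strand = "+",
      seq = purrr::map2_chr(
        match(.data$site_id, ids), .data$species,
        function(i, sp) paste(NUC[sites[[i]]$leaves[[sp]]], collapse = "")
      )
    )
  roots <- tibble::tibble(
    site_id = ids,
    root_seq = vapply(sites, function(s) paste(NUC[s$root], collapse = ""), "")
  )
  list(groups = groups, roots = roots)
}

#' Inject lineage-specific site turnover
#'
#' Emulates loss of a binding site in some lineages: for a random fraction
#' of (site group, non-reference species) pairs, the selected columns are
#' resampled i.i.d. from the background — the site no longer constrains that
#' lineage.  Used to reproduce, qualitatively, the weakening of multi-species
#' PWMs relative to single-species PWMs.
#'
#' @param groups Site-group tibble (first species of each group is the
#'   reference and is never perturbed).
#' @param rate Fraction of (group, non-reference species) pairs to resample.
#' @param background Stationary vector for the resampled columns.
#' @param seed Integer seed.
#' @param columns Columns to resample (default all).
#' @return The modified site-group tibble.
#' @export
inject_turnover <- function(groups, rate, background = mammal_background,
                            seed, columns = NULL) {
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1].")
  background <- check_simplex(background)
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  L <- unique(nchar(groups$seq))
  if (length(L) != 1L) abort("Sequences have unequal lengths.")
  if (is.null(columns)) columns <- seq_len(L)
  ref <- groups |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(ref_species = dplyr::first(.data$species))
  groups <- dplyr::left_join(groups, ref, by = "site_id")
  withr::with_seed(substream_seed(seed, 0L), {
    eligible <- which(groups$species != groups$ref_species)
    hit <- eligible[runif(length(eligible)) < rate]
    for (i in hit) {
      s <- seq_to_int(groups$seq[i])
      s[columns] <- sample.int(4L, length(columns), replace = TRUE, prob = background)
      groups$seq[i] <- paste(NUC[s], collapse = "")
    }
  })
  dplyr::select(groups, -"ref_species")
}
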