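## Two interchangeable per-column likelihood evaluators over one rooted tree:
##   * prune_likelihood(): Felsenstein's pruning algorithm, any model — the
##     reference engine, evaluated per pattern by post-order recursion.
##   * fast_likelihood(): the sum-of-stars evaluator, F81 only — the tree is
##     rewritten once, symbolically, as a weighted sum of products of star
##     trees; re-evaluation under new q or pi needs no tree traversal.

## --- site patterns --------------------------------------------------------

## Normalize patterns to an integer matrix (rows = patterns, columns in tree
## leaf order, entries 1..4).  Accepts a named character vector (one
## pattern), a character matrix, or an integer matrix with leaf colnames.
as_pattern_matrix <- function(pattern, leaf_order) {
  if (is.null(dim(pattern))) {
    if (is.null(names(pattern))) abort("A single site pattern must be named by leaf.")
    pattern <- matrix(pattern, nrow = 1, dimnames = list(NULL, names(pattern)))
  }
  if (is.null(colnames(pattern))) abort("Pattern matrix must have leaf-name columns.")
  if (!setequal(colnames(pattern), leaf_order) ||
      ncol(pattern) != length(leaf_order)) {
    abort(sprintf(
      "Pattern leaves {%s} do not match tree leaves {%s}.",
      paste(sort(colnames(pattern)), collapse = ","),
      paste(sort(leaf_order), collapse = ",")))
  }
  pattern <- pattern[, leaf_order, drop = FALSE]
  if (is.character(pattern)) {
    pattern <- matrix(encode_nuc(pattern), nrow = nrow(pattern),
                      dimnames = dimnames(pattern))
  }
  storage.mode(pattern) <- "integer"
  pattern
}

## --- Felsenstein pruning --------------------------------------------------

## Flatten a tree once: postorder node ids, children lists, leaf columns.
flatten_tree <- function(tree) {
  children <- vector("list", tree$n_nodes)
  leaf_col <- integer(tree$n_nodes)
  post <- integer(0)
  rec <- function(node) {
    kid_ids <- vapply(node$children, `[[`, integer(1), "id")
    children[[node$id]] <<- kid_ids
    if (length(kid_ids) == 0L) {
      leaf_col[node$id] <<- match(node$name, tree$leaf_order)
    }
    for (ch in node$children) rec(ch)
    post <<- c(post, node$id)
  }
  rec(tree$root)
  list(post = post, children = children, leaf_col = leaf_col,
       root_id = tree$root$id, q = branch_q(tree))
}

## Conditional likelihoods at the root, one 4-vector per pattern:
## partials[alpha, i] = P(pattern i | root state alpha).
prune_root_partials <- function(tree, patterns, model, q = NULL) {
  P <- as_pattern_matrix(patterns, tree$leaf_order)
  flat <- flatten_tree(tree)
  if (!is.null(q)) flat$q <- q
  if (anyNA(flat$q[-flat$root_id])) abort("Tree has branches without q; fit or supply them.")
  ## transposed transition matrices, one per non-root node
  tT <- vector("list", tree$n_nodes)
  for (id in seq_len(tree$n_nodes)) {
    if (id != flat$root_id) tT[[id]] <- t(branch_matrix(model, flat$q[id]))
  }
  n <- nrow(P)
  out <- matrix(NA_real_, 4, n)
  L <- matrix(0, 4, tree$n_nodes)
  I4 <- diag(4)
  for (i in seq_len(n)) {
    for (id in flat$post) {
      kids <- flat$children[[id]]
      if (length(kids) == 0L) {
        L[, id] <- I4[, P[i, flat$leaf_col[id]]]
      } else {
        v <- rep(1, 4)
        for (k in kids) v <- v * as.vector(tT[[k]] %*% L[, k])
        L[, id] <- v
      }
    }
    out[, i] <- L[, flat$root_id]
  }
  rownames(out) <- NUC
  out
}

#' Phylogenetic site likelihood by Felsenstein pruning
#'
#' The standard post-order dynamic program: conditional likelihood vectors
#' are propagated from the leaves to the root and contracted with the root
#' prior `model$pi`.  Works for any substitution model and any (possibly
#' multifurcating) rooted tree; used as the reference engine against which
#' the sum-of-stars evaluator is checked.
#'
#' @param tree A `pssv_tree` with proximities on every branch.
#' @param pattern A named character vector (leaf -> nucleotide), or a
#'   character/integer matrix with one pattern per row and leaf-name columns.
#' @param model A [subst_model()].
#' @return Numeric vector of per-pattern likelihoods (length 1 for a single
#'   pattern).
#' @export
#' @examples
#' tr <- read_newick("((A:0.1,C:0.2):0.3,T:0.4);")
#' prune_likelihood(tr, c(A = "A", C = "A", T = "G"), subst_model("F81"))
prune_likelihood <- function(tree, pattern, model) {
  partials <- prune_root_partials(tree, pattern, model)
  as.vector(model$pi %*% partials)
}

## --- sum-of-stars decomposition ------------------------------------------

## Decomposition node: list(id, name, leaf, children).
strip_node <- function(node) {
  list(id = node$id, name = node$name,
       leaf = length(node$children) == 0L,
       children = lapply(node$children, strip_node))
}

is_star_node <- function(node) {
  length(node$children) > 0L &&
    all(vapply(node$children, `[[`, logical(1), "leaf"))
}

make_star <- function(node) {
  list(leaf_names = vapply(node$children, `[[`, character(1), "name"),
       leaf_ids = vapply(node$children, `[[`, integer(1), "id"))
}

## Depth-first, leftmost-first search for a star node strictly below `node`;
## returns found flag, the star, its branch id, and the merged/pruned trees.
split_first_star <- function(node) {
  for (j in seq_along(node$children)) {
    ch <- node$children[[j]]
    if (ch$leaf) next
    if (is_star_node(ch)) {
      merged <- node
      merged$children <- append(node$children[-j], ch$children, after = j - 1L)
      pruned <- node
      pruned$children <- node$children[-j]
      return(list(found = TRUE, star = make_star(ch), star_id = ch$id,
                  merged = merged, pruned = pruned))
    }
    r <- split_first_star(ch)
    if (r$found) {
      merged <- node; merged$children[[j]] <- r$merged
      pruned <- node; pruned$children[[j]] <- r$pruned
      return(list(found = TRUE, star = r$star, star_id = r$star_id,
                  merged = merged, pruned = pruned))
    }
  }
  list(found = FALSE)
}

## After removing a star subtree, its former parent may be left with no
## children; a childless internal node contributes sum_beta T_{beta alpha} = 1
## and is dropped (recursively — the removal can cascade to the root).
drop_childless <- function(node) {
  if (length(node$children) == 0L) return(node)
  kids <- lapply(node$children, drop_childless)
  keep <- vapply(kids, function(k) k$leaf || length(k$children) > 0L, logical(1))
  node$children <- kids[keep]
  node
}

#' Decompose a tree into a sum of products of star trees
#'
#' Under F81 the likelihood of any rooted tree equals a weighted sum of
#' products of star-tree likelihoods.  Repeatedly, a star node (a node all of
#' whose children are leaves) with proximity \eqn{q_j} to its parent is
#' either unmutated (weight \eqn{q_j}; its leaves are merged into the parent,
#' keeping their own proximities) or mutated and independent of its parent
#' (weight \eqn{1-q_j}; the star splits off as a standalone factor).  The
#' rewriting is symbolic: weights are products of \eqn{q_j} / \eqn{1-q_j}
#' factors tied to branch identities, so new proximities need no
#' re-decomposition.
#'
#' @param tree A `pssv_tree` (>= 1 leaf).
#' @return A `star_decomposition`: a list of terms, each with `fac_id` /
#'   `fac_sign` (sign 1 means \eqn{q}, 2 means \eqn{1-q}) and a list of star
#'   trees (`leaf_names`, `leaf_ids`).
#' @export
#' @examples
#' tr <- read_newick("((A:0.9,C:0.9)b:0.8,T:0.9)a;", lengths = "proximity")
#' decompose_sum_of_stars(tr)
decompose_sum_of_stars <- function(tree) {
  if (n_leaves(tree) < 1L) abort("Tree must have at least one leaf.")
  if (n_leaves(tree) > 12L) {
    warn(sprintf(paste0(
      "Tree has %d leaves; the sum-of-stars method is impractical beyond ",
      "about 12 leaves (term count grows exponentially)."), n_leaves(tree)))
  }
  todo <- list(list(fac_id = integer(0), fac_sign = integer(0),
                    main = strip_node(tree$root), stars = list()))
  done <- list()
  while (length(todo) > 0L) {
    term <- todo[[1L]]; todo <- todo[-1L]
    repeat {
      m <- term$main
      if (is.null(m) || length(m$children) == 0L) {
        ## a bare root evaluates to sum(pi) = 1 and drops out
        term$main <- NULL
        break
      }
      if (is_star_node(m)) {
        term$stars <- c(list(make_star(m)), term$stars)
        term$main <- NULL
        break
      }
      r <- split_first_star(m)
      if (!r$found) abort("Internal error: no star node found in a non-star tree.")
      other <- term
      other$fac_id <- c(other$fac_id, r$star_id)
      other$fac_sign <- c(other$fac_sign, 2L)
      other$main <- drop_childless(r$pruned)
      other$stars <- c(other$stars, list(r$star))
      todo <- c(todo, list(other))
      term$fac_id <- c(term$fac_id, r$star_id)
      term$fac_sign <- c(term$fac_sign, 1L)
      term$main <- r$merged
    }
    term$main <- NULL
    done <- c(done, list(term))
  }
  labels <- tidy(tree)
  structure(list(
    terms = done,
    leaf_order = tree$leaf_order,
    n_nodes = tree$n_nodes,
    branch_labels = setNames(labels$label, labels$id)
  ), class = "star_decomposition")
}

#' @export
print.star_decomposition <- function(x, ...) {
  cat(sprintf("<star_decomposition> %d term(s) over %d leaves\n",
              length(x$terms), length(x$leaf_order)))
  for (tm in x$terms) {
    w <- if (length(tm$fac_id) == 0L) "1" else paste(
      ifelse(tm$fac_sign == 1L, sprintf("q[%s]", x$branch_labels[as.character(tm$fac_id)]),
             sprintf("(1-q[%s])", x$branch_labels[as.character(tm$fac_id)])),
      collapse = " * ")
    s <- paste(vapply(tm$stars, function(st) paste0(
      "star(", paste(st$leaf_names, collapse = ","), ")"), ""), collapse = " * ")
    cat("  ", w, " : ", s, "\n", sep = "")
  }
  invisible(x)
}

## Evaluated numeric weight of each term for a given q assignment.
term_weights <- function(decomp, q) {
  vapply(decomp$terms, function(tm) {
    if (length(tm$fac_id) == 0L) return(1)
    f <- q[tm$fac_id]
    if (anyNA(f)) abort("Missing proximity for a branch referenced by the decomposition.")
    prod(ifelse(tm$fac_sign == 1L, f, 1 - f))
  }, numeric(1))
}

#' Evaluate one star tree over a site pattern
#'
#' A star factor is \eqn{\sum_\alpha \pi_\alpha \prod_k [q_k
#' \delta_{S_k\alpha} + (1-q_k)\pi_{S_k}]}: a sum over the star root with one
#' scalar factor per leaf — O(alphabet) per leaf rather than the O(alphabet^2)
#' matrix products of pruning.
#'
#' @param star One star from a [decompose_sum_of_stars()] term.
#' @param pattern Named character vector, or pattern matrix (see
#'   [prune_likelihood()]); only the star's leaves are read.
#' @param pi Stationary vector.
#' @param q Numeric proximity vector indexed by node id.
#' @return Numeric vector of per-pattern star factors.
#' @export
eval_star <- function(star, pattern, pi, q) {
  pi <- check_simplex(pi)
  if (length(star$leaf_ids) == 0L) return(1)
  if (is.null(dim(pattern))) {
    pattern <- matrix(pattern, nrow = 1, dimnames = list(NULL, names(pattern)))
  }
  if (is.character(pattern)) {
    pattern <- matrix(encode_nuc(pattern), nrow = nrow(pattern),
                      dimnames = dimnames(pattern))
  }
  n <- nrow(pattern)
  G <- matrix(1, n, 4)
  for (k in seq_along(star$leaf_ids)) {
    qk <- q[star$leaf_ids[k]]
    if (is.na(qk)) abort(sprintf("No proximity supplied for branch id %d.", star$leaf_ids[k]))
    obs <- pattern[, star$leaf_names[k]]
    a <- (1 - qk) * pi[obs]
    Fk <- matrix(a, n, 4)
    Fk[cbind(seq_len(n), obs)] <- a + qk
    G <- G * Fk
  }
  as.vector(G %*% pi)
}

#' Fast F81 site likelihood from a star decomposition
#'
#' Evaluates \eqn{\sum_{terms} w(q) \prod_s star_s} for one or many site
#' patterns, reusing the symbolic decomposition.  Equals
#' [prune_likelihood()] under F81 to machine precision; the saving over
#' pruning is that no per-pattern tree traversal is performed.
#'
#' @param decomp A [decompose_sum_of_stars()] result.
#' @param pattern Pattern(s) as in [prune_likelihood()].
#' @param pi Stationary vector.
#' @param q Proximity vector indexed by node id (defaults must be supplied;
#'   take `branch_q(tree)` via `tidy(tree)` or pass the fitted tree's values).
#' @return Numeric vector of per-pattern likelihoods.
#' @export
#' @examples
#' tr <- read_newick("((A:0.1,C:0.2):0.3,T:0.4);")
#' d <- decompose_sum_of_stars(tr)
#' fast_likelihood(d, c(A = "A", C = "A", T = "G"), mammal_background, tree_q(tr))
fast_likelihood <- function(decomp, pattern, pi, q) {
  pi <- check_simplex(pi)
  P <- as_pattern_matrix(pattern, decomp$leaf_order)
  w <- term_weights(decomp, q)
  total <- numeric(nrow(P))
  for (i in seq_along(decomp$terms)) {
    if (w[i] == 0) next
    v <- rep(w[i], nrow(P))
    for (st in decomp$terms[[i]]$stars) {
      v <- v * eval_star(st, P, pi, q)
    }
    total <- total + v
  }
  total
}

#' Branch proximities of a tree as an id-indexed vector
#'
#' Convenience accessor returning the vector expected by
#' [fast_likelihood()] and [eval_star()]: `q[id]` for every non-root node,
#' `NA` at the root slot.
#'
#' @param tree A `pssv_tree`.
#' @return Numeric vector of length `tree$n_nodes`.
#' @export
tree_q <- function(tree) branch_q(tree)

#' Per-pattern site likelihood with automatic engine choice
#'
#' Uses the sum-of-stars evaluator for F81 on trees of at most 12 leaves and
#' falls back to Felsenstein pruning otherwise (HKY85, or larger trees where
#' the star expansion is impractical).
#'
#' @inheritParams prune_likelihood
#' @param engine `"auto"`, `"star"` or `"prune"`.
#' @return Numeric vector of per-pattern likelihoods.
#' @export
site_likelihood <- function(tree, pattern, model, engine = c("auto", "star", "prune")) {
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (model$family == "F81" && n_leaves(tree) <= 12L) "star" else "prune"
  }
  if (engine == "star") {
    if (model$family != "F81") abort("The sum-of-stars engine supports F81 only.")
    if (n_leaves(tree) > 12L) {
      warn("More than 12 leaves: falling back to pruning.")
      engine <- "prune"
    }
  }
  if (engine == "star") {
    d <- decompose_sum_of_stars(tree)
    fast_likelihood(d, pattern, model$pi, branch_q(tree))
  } else {
    prune_likelihood(tree, pattern, model)
  }
}
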