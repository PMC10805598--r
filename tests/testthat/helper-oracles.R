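# Shared fixtures and independent oracles, all built in code.

# Random point on the 3-simplex, bounded away from the boundary.
random_simplex <- function() {
  x <- stats::rexp(4) + 0.05
  x / sum(x)
}

# Random rooted tree over n leaves, possibly multifurcating, with random
# proximities q ~ U(qmin, 1).  Returns a pssv_tree.
random_tree <- function(n_leaves, qmin = 0.05, p_multi = 0.3) {
  leaves <- paste0("L", seq_len(n_leaves))
  build <- function(names) {
    if (length(names) == 1L) return(names)
    k <- if (length(names) > 2L && stats::runif(1) < p_multi) {
      sample(3:min(length(names), 4L), 1L)
    } else 2L
    grp <- split(names, sort(rep_len(seq_len(k), length(names))))
    paste0("(", paste(vapply(grp, build, ""), collapse = ","), ")")
  }
  skel <- paste0(build(sample(leaves)), ";")
  # attach a random proximity to every non-root node
  out <- gsub("(L[0-9]+|\\))(?=[,)\\;])", "\\1:Q", skel, perl = TRUE)
  out <- sub(":Q;", ";", out)   # the root carries no branch
  while (grepl(":Q", out, fixed = TRUE)) {
    q <- stats::runif(1, qmin, 1)
    out <- sub(":Q", sprintf(":%.12f", q), out, fixed = TRUE)
  }
  read_newick(out, lengths = "proximity")
}

random_pattern <- function(tree) {
  setNames(sample(c("A", "C", "G", "T"), length(tree$leaf_order), replace = TRUE),
           tree$leaf_order)
}

# Every possible site pattern over the tree's leaves (4^n rows).
all_patterns <- function(tree) {
  leaves <- tree$leaf_order
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), length(leaves)),
                              stringsAsFactors = FALSE))
  m <- as.matrix(g)
  colnames(m) <- leaves
  m
}

# Independent likelihood oracle: explicit enumeration over all internal-node
# state assignments; product of transition-matrix entries over every branch,
# root prior over the root state.
brute_force_likelihood <- function(tree, pattern, model) {
  edges <- tidy(tree)
  tmat <- lapply(seq_len(nrow(edges)), function(i) {
    if (is.na(edges$q[i])) return(NULL)
    if (model$family == "F81") f81_transition(edges$q[i], model$pi)
    else hky85_transition(-log(edges$q[i]), model$pi, model$kappa)
  })
  internal <- edges$id[!edges$is_leaf]
  leaf_rows <- edges[edges$is_leaf, ]
  root_id <- edges$id[is.na(edges$parent_id)]
  states <- as.matrix(do.call(expand.grid, rep(list(1:4), length(internal))))
  total <- 0
  nuc <- c("A", "C", "G", "T")
  for (r in seq_len(nrow(states))) {
    st <- setNames(states[r, ], internal)
    p <- model$pi[st[[as.character(root_id)]]]
    for (i in seq_len(nrow(edges))) {
      if (is.na(edges$parent_id[i])) next
      child_state <- if (edges$is_leaf[i]) match(pattern[[edges$label[i]]], nuc)
                     else st[[as.character(edges$id[i])]]
      parent_state <- st[[as.character(edges$parent_id[i])]]
      p <- p * tmat[[i]][child_state, parent_state]
    }
    total <- total + p
  }
  unname(total)
}

# The worked three-leaf example tree, proximity dialect.
fig_tree <- function(q1 = 0.9, q2 = 0.85, q3 = 0.8, q4 = 0.75) {
  read_newick(sprintf("((A:%g,C:%g)b:%g,T:%g)a;", q1, q2, q4, q3),
              lengths = "proximity")
}

# Tree with every proximity replaced by a constant.
with_q <- function(tree, q) {
  b <- tidy(tree)
  qv <- rep(NA_real_, tree$n_nodes)
  qv[b$id[!is.na(b$q)]] <- q
  set_branch_proximities(tree, qv)
}

# Site groups whose every sequence is i.i.d. background (no phylogenetic
# signal), built directly rather than via the simulator.
iid_groups <- function(tree, n_sites, L, pi, seed) {
  withr::with_seed(seed, {
    tidyr::expand_grid(site_id = sprintf("s%05d", seq_len(n_sites)),
                       species = tree$leaf_order) |>
      dplyr::mutate(chrom = "synthetic", start = 0L, end = L, strand = "+",
                    seq = vapply(seq_len(dplyr::n()), function(i) {
                      paste(sample(c("A", "C", "G", "T"), L, TRUE, prob = pi),
                            collapse = "")
                    }, ""))
  })
}

# One profile row as a plain numeric 4-vector.
profile_row <- function(profile, i) {
  as.numeric(profile[profile$pos == i, c("A", "C", "G", "T")])
}
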