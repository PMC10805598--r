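## Rooted phylogenetic trees with per-branch evolutionary time t (mutation
## rate mu = 1) and "proximity" q = exp(-t).  Trees are plain nested lists;
## every node carries a stable integer id assigned in preorder so that the
## symbolic star decomposition and the fitted q's can refer to branches by
## identity regardless of later re-parameterizations.

new_node <- function(name = NA_character_, children = list(), t = NA_real_) {
  list(name = name, children = children, t = t, q = NA_real_, id = NA_integer_)
}

## Assign preorder ids and q = exp(-t); returns the annotated node.
annotate_node <- function(node, next_id) {
  node$id <- next_id$i
  next_id$i <- next_id$i + 1L
  if (!is.na(node$t)) node$q <- exp(-node$t)
  node$children <- lapply(node$children, annotate_node, next_id = next_id)
  node
}

collect_leaves <- function(node) {
  if (length(node$children) == 0L) return(node$name)
  unlist(lapply(node$children, collect_leaves))
}

count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, integer(1)))
}

new_pssv_tree <- function(root) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 1L
  root <- annotate_node(root, counter)
  leaves <- collect_leaves(root)
  if (anyDuplicated(leaves)) {
    abort(sprintf("Duplicate leaf name(s): %s",
                  paste(unique(leaves[duplicated(leaves)]), collapse = ", ")))
  }
  structure(
    list(root = root, leaf_order = leaves, n_nodes = counter$i - 1L),
    class = "pssv_tree"
  )
}

## --- Newick I/O -----------------------------------------------------------

phylo_to_node <- function(phy, v, ntip, lens) {
  is_tip <- v <= ntip
  name <- if (is_tip) phy$tip.label[v]
          else if (!is.null(phy$node.label)) {
            lb <- phy$node.label[v - ntip]
            if (is.null(lb) || is.na(lb) || !nzchar(lb)) NA_character_ else lb
          } else NA_character_
  rows <- which(phy$edge[, 1] == v)
  children <- lapply(rows, function(r) {
    child <- phylo_to_node(phy, phy$edge[r, 2], ntip, lens)
    child$t <- lens[r]
    child
  })
  n <- new_node(name = name, children = children)
  n
}

#' Read a rooted tree from a Newick string or file
#'
#' Branch lengths may be given either as evolutionary time \eqn{t} (with the
#' mutation rate fixed to 1, so time is in expected mutation events) or
#' directly as proximities \eqn{q = e^{-t}}.  Both are stored on every
#' non-root branch; the root carries neither.
#'
#' @param text A Newick string (terminated by `;`) or the path of a file
#'   containing one.
#' @param lengths Either `"time"` (default; lengths are \eqn{t \ge 0}) or
#'   `"proximity"` (lengths are \eqn{q \in (0, 1]}).
#' @return A `pssv_tree`: a rooted, possibly multifurcating tree whose
#'   branches carry both `t` and `q`, with a deterministic depth-first
#'   `leaf_order`.
#' @export
#' @examples
#' tr <- read_newick("((A:0.1,C:0.2):0.3,T:0.4);")
#' tidy(tr)
read_newick <- function(text, lengths = c("time", "proximity")) {
  lengths <- match.arg(lengths)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  ## cheap structural pre-check so malformed input reports an offset
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) abort(sprintf("Malformed Newick: unbalanced ')' at offset %d.", i))
  }
  if (depth != 0L) abort("Malformed Newick: unbalanced '(' — missing closing parenthesis.")

  if (!grepl("(", text, fixed = TRUE)) {
    ## degenerate single-leaf tree, e.g. "A:0.5;" — below ape's minimum
    m <- regmatches(text, regexec("^([^:;,()]+)(:([0-9eE.+-]+))?;$", text))[[1]]
    if (length(m) == 0L) abort("Malformed Newick string.")
    leaf <- new_node(name = m[2])
    leaf$t <- if (nzchar(m[4])) as.numeric(m[4]) else NA_real_
    root <- new_node(children = list(leaf))
    return(finish_tree(new_pssv_tree(convert_lengths_node(root, lengths))))
  }

  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(sprintf("Malformed Newick: %s", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Malformed Newick string.")
  ntip <- length(phy$tip.label)
  lens <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else phy$edge.length
  root <- phylo_to_node(phy, ntip + 1L, ntip, lens)
  finish_tree(new_pssv_tree(convert_lengths_node(root, lengths)))
}

## Interpret the raw branch-length slot according to the dialect.
convert_lengths_node <- function(node, lengths) {
  if (!is.na(node$t)) {
    v <- node$t
    if (lengths == "proximity") {
      if (v <= 0 || v > 1) abort(sprintf("Proximity %g outside (0, 1].", v))
      node$t <- -log(v)
    } else {
      if (v < 0) abort(sprintf("Negative branch length %g.", v))
    }
  }
  node$children <- lapply(node$children, convert_lengths_node, lengths = lengths)
  node
}

finish_tree <- function(tree) {
  qs <- tidy(tree)$q
  qs <- qs[!is.na(qs)]
  if (any(qs <= 0 | qs > 1)) abort("All proximities must lie in (0, 1].")
  tree
}

node_to_newick <- function(node, lengths) {
  lab <- if (is.na(node$name)) "" else node$name
  core <- if (length(node$children) == 0L) lab
  else paste0("(", paste(vapply(node$children, node_to_newick, "", lengths = lengths),
                         collapse = ","), ")", lab)
  if (is.na(node$t)) return(core)
  v <- if (lengths == "proximity") node$q else node$t
  paste0(core, ":", sprintf("%.15g", v))
}

#' Write a tree as a Newick string
#'
#' @param tree A `pssv_tree`.
#' @param lengths Write branch lengths as `"time"` (t) or `"proximity"` (q).
#' @param path Optional file path; if given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, lengths = c("time", "proximity"), path = NULL) {
  lengths <- match.arg(lengths)
  s <- paste0(node_to_newick(tree$root, lengths), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

## --- Study topologies -----------------------------------------------------

#' Fixed primate and mammal study topologies
#'
#' The two species sets used throughout: five primates (human, chimpanzee,
#' gorilla, orangutan, rhesus) and seven mammals (human, rhesus, mouse, cat,
#' dog, pig, horse), with the standard published branching orders.  Branch
#' lengths are placeholders (t = 0.1 on every branch) meant to be replaced by
#' [fit_branch_proximities()] or by user-supplied values.
#'
#' @param which `"primates"` or `"mammals"`.
#' @return A `pssv_tree`.
#' @export
#' @examples
#' study_topology("primates")$leaf_order
study_topology <- function(which = c("primates", "mammals")) {
  which <- match.arg(which)
  nwk <- switch(which,
    primates = "((((human:0.1,chimpanzee:0.1):0.1,gorilla:0.1):0.1,orangutan:0.1):0.1,rhesus:0.1);",
    mammals  = "(((human:0.1,rhesus:0.1):0.1,mouse:0.1):0.1,((cat:0.1,dog:0.1):0.1,(pig:0.1,horse:0.1):0.1):0.1);"
  )
  read_newick(nwk, lengths = "time")
}

## --- Accessors ------------------------------------------------------------

n_leaves <- function(tree) length(tree$leaf_order)

walk_branches <- function(node, parent_id, acc) {
  lab <- if (!is.na(node$name)) node$name
         else paste(collect_leaves(node), collapse = "+")
  acc[[length(acc) + 1L]] <- list(
    id = node$id, label = lab, parent_id = parent_id,
    t = node$t, q = node$q, is_leaf = length(node$children) == 0L
  )
  for (ch in node$children) acc <- walk_branches(ch, node$id, acc)
  acc
}

#' @describeIn read_newick Tidy view of a tree: one row per node with its
#'   branch (to the parent) time `t` and proximity `q`; the root row has
#'   `NA` for both.
#' @param x A `pssv_tree`.
#' @param ... Unused.
#' @export
tidy.pssv_tree <- function(x, ...) {
  rows <- walk_branches(x$root, NA_integer_, list())
  tibble::tibble(
    id = vapply(rows, `[[`, integer(1), "id"),
    label = vapply(rows, `[[`, character(1), "label"),
    parent_id = vapply(rows, `[[`, integer(1), "parent_id"),
    is_leaf = vapply(rows, `[[`, logical(1), "is_leaf"),
    t = vapply(rows, `[[`, numeric(1), "t"),
    q = vapply(rows, `[[`, numeric(1), "q")
  )
}

## q vector indexed by node id (NA at the root) — the canonical branch map.
branch_q <- function(tree) {
  b <- tidy(tree)
  q <- rep(NA_real_, tree$n_nodes)
  q[b$id] <- b$q
  q
}

set_q_node <- function(node, q) {
  if (!is.na(node$id) && !is.na(q[node$id])) {
    node$q <- q[node$id]
    node$t <- -log(node$q)
  }
  node$children <- lapply(node$children, set_q_node, q = q)
  node
}

#' Replace the branch proximities of a tree
#'
#' @param tree A `pssv_tree`.
#' @param q Numeric vector indexed by node id (as in `tidy(tree)$id`), with
#'   `NA` at the root position; values must lie in (0, 1].
#' @return The tree with updated `q` and `t = -log(q)` on every branch.
#' @export
set_branch_proximities <- function(tree, q) {
  if (length(q) != tree$n_nodes) {
    abort(sprintf("`q` must have length %d (one slot per node id).", tree$n_nodes))
  }
  qq <- q[!is.na(q)]
  if (any(qq <= 0 | qq > 1)) abort("All proximities must lie in (0, 1].")
  tree$root <- set_q_node(tree$root, q)
  tree
}

#' @export
print.pssv_tree <- function(x, ...) {
  cat(sprintf("<pssv_tree> %d leaves, %d nodes\n", n_leaves(x), x$n_nodes))
  cat("  leaves:", paste(x$leaf_order, collapse = ", "), "\n")
  cat(" ", write_newick(x, "time"), "\n")
  invisible(x)
}
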