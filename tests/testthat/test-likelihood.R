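bg <- subst_model("F81", c(0.3, 0.2, 0.2, 0.3))

test_that("pruning handles the degenerate closed-form cases", {
  # single leaf at q = 1: the leaf state is forced equal to the root
  tr1 <- read_newick("A:0.0;")
  expect_equal(prune_likelihood(tr1, c(A = "A"), bg), 0.3)
  # identical-by-descent contradiction: all q = 1 but differing leaves
  trf <- with_q(fig_tree(), 1)
  expect_equal(prune_likelihood(trf, c(A = "A", C = "C", T = "T"), bg), 0)
  # two-leaf star at q -> 0: leaves independent draws from pi
  tr2 <- read_newick("(A:1e-9,C:1e-9);", lengths = "proximity")
  expect_equal(prune_likelihood(tr2, c(A = "A", C = "C"), bg), 0.06,
               tolerance = 1e-6)
  expect_error(prune_likelihood(trf, c(A = "A", C = "C", X = "T"), bg),
               "leaves")
})

test_that("pruning agrees with brute-force enumeration over internal states", {
  set.seed(405)
  for (i in 1:15) {
    tr <- random_tree(sample(3:5, 1))
    pat <- random_pattern(tr)
    pi <- random_simplex()
    for (m in list(subst_model("F81", pi),
                   subst_model("HKY85", pi, kappa = runif(1, 0.5, 4)))) {
      expect_equal(prune_likelihood(tr, pat, m),
                   brute_force_likelihood(tr, pat, m), tolerance = 1e-12)
    }
  }
})

test_that("pruning agrees with phangorn's F81 likelihood", {
  skip_if_not_installed("phangorn")
  pi <- c(0.3, 0.2, 0.2, 0.3)
  nwk <- "((A:0.2,C:0.35):0.15,T:0.4);"
  ours <- prune_likelihood(read_newick(nwk), c(A = "A", C = "C", T = "T"),
                           subst_model("F81", pi))
  # phangorn normalizes the generator to one expected substitution per unit
  # time; ours has unit event rate, so edges scale by 1 - sum(pi^2)
  ap <- ape::read.tree(text = nwk)
  ap$edge.length <- ap$edge.length * (1 - sum(pi^2))
  dat <- phangorn::phyDat(matrix(c("a", "c", "t"), ncol = 1,
                                 dimnames = list(c("A", "C", "T"), NULL)),
                          type = "DNA")
  fit <- phangorn::pml(ap, dat, bf = pi, model = NULL)
  expect_equal(ours, exp(fit$logLik), tolerance = 1e-10)
})

test_that("the worked tree decomposes into the two printed terms", {
  tr <- fig_tree(q1 = 0.9, q2 = 0.85, q3 = 0.8, q4 = 0.75)
  d <- decompose_sum_of_stars(tr)
  expect_s3_class(d, "star_decomposition")
  expect_length(d$terms, 2L)
  b <- tidy(tr)
  id_beta <- b$id[b$label == "b"]
  # term with weight q4: one merged star over {A, C, T}
  t1 <- d$terms[[which(vapply(d$terms, function(t) all(t$fac_sign == 1L), TRUE))]]
  expect_identical(t1$fac_id, id_beta)
  expect_length(t1$stars, 1L)
  expect_setequal(t1$stars[[1]]$leaf_names, c("A", "C", "T"))
  # term with weight (1 - q4): star(T) times star(A, C)
  t2 <- d$terms[[which(vapply(d$terms, function(t) all(t$fac_sign == 2L), TRUE))]]
  expect_identical(t2$fac_id, id_beta)
  sizes <- sort(vapply(t2$stars, function(s) length(s$leaf_names), 1L))
  expect_identical(sizes, c(1L, 2L))
  expect_setequal(unlist(lapply(t2$stars, `[[`, "leaf_names")), c("A", "C", "T"))
})

test_that("a balanced four-leaf tree yields the four expected terms", {
  tr <- read_newick("((a:0.9,b:0.8)X:0.7,(c:0.85,d:0.95)Y:0.75);",
                    lengths = "proximity")
  d <- decompose_sum_of_stars(tr)
  expect_length(d$terms, 4L)
  b <- tidy(tr)
  idX <- b$id[b$label == "X"]; idY <- b$id[b$label == "Y"]
  signatures <- lapply(d$terms, function(t) {
    s <- setNames(t$fac_sign, t$fac_id)
    s[order(names(s))]
  })
  want <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  got <- lapply(signatures, unname)
  expect_setequal(lapply(got, paste, collapse = ""),
                  lapply(want, paste, collapse = ""))
  expect_true(all(vapply(signatures, function(s)
    setequal(names(s), as.character(c(idX, idY))), TRUE)))
  # evaluated weights partition unity for any q
  set.seed(406)
  for (i in 1:5) {
    q <- tree_q(tr); q[!is.na(q)] <- runif(sum(!is.na(q)), 0.05, 1)
    expect_equal(sum(pssver:::term_weights(d, q)), 1, tolerance = 1e-12)
  }
})

test_that("a star tree is its own decomposition and term growth is bounded", {
  d <- decompose_sum_of_stars(read_newick("(A:0.9,C:0.8,T:0.7);", lengths = "proximity"))
  expect_length(d$terms, 1L)
  expect_length(d$terms[[1]]$fac_id, 0L)
  # every processed star node at most doubles the term count
  tr8 <- read_newick(paste0("(((a:.9,b:.9):.9,(c:.9,d:.9):.9):.9,",
                            "((e:.9,f:.9):.9,(g:.9,h:.9):.9):.9);"),
                     lengths = "proximity")
  d8 <- decompose_sum_of_stars(tr8)
  expect_lte(length(d8$terms), 2^7)
  q <- tree_q(tr8)
  expect_equal(sum(pssver:::term_weights(d8, q)), 1, tolerance = 1e-12)
})

test_that("eval_star evaluates its closed form", {
  tr <- fig_tree()
  d <- decompose_sum_of_stars(tr)
  q <- tree_q(tr)
  expect_equal(eval_star(list(leaf_names = character(0), leaf_ids = integer(0)),
                         c(A = "A", C = "C", T = "T"), bg$pi, q), 1)
  q1 <- q; q1[!is.na(q1)] <- 1
  star_ac <- list(leaf_names = c("A", "C"),
                  leaf_ids = tidy(tr)$id[match(c("A", "C"), tidy(tr)$label)])
  expect_equal(eval_star(star_ac, c(A = "A", C = "A", T = "G"), bg$pi, q1), 0.3)
  expect_equal(eval_star(star_ac[c(1, 2)], c(A = "A", C = "C", T = "G"), bg$pi, q1), 0)
  star_a <- list(leaf_names = "A", leaf_ids = star_ac$leaf_ids[1])
  expect_equal(eval_star(star_a, c(A = "G", C = "C", T = "T"), bg$pi, q1), 0.2)
})

test_that("fast sum-of-stars equals pruning to machine precision", {
  set.seed(407)
  for (i in 1:120) {
    tr <- random_tree(sample(3:10, 1))
    pi <- random_simplex()
    pat <- random_pattern(tr)
    d <- decompose_sum_of_stars(tr)
    f <- fast_likelihood(d, pat, pi, tree_q(tr))
    p <- prune_likelihood(tr, pat, subst_model("F81", pi))
    expect_lt(abs(f - p) / p, 1e-12)
  }
})

test_that("site likelihoods over all patterns sum to one", {
  set.seed(408)
  for (n in 3:5) {
    tr <- random_tree(n)
    pi <- random_simplex()
    pats <- all_patterns(tr)
    m <- subst_model("F81", pi)
    expect_equal(sum(prune_likelihood(tr, pats, m)), 1, tolerance = 1e-10)
    d <- decompose_sum_of_stars(tr)
    expect_equal(sum(fast_likelihood(d, pats, pi, tree_q(tr))), 1,
                 tolerance = 1e-10)
    mh <- subst_model("HKY85", pi, kappa = 2.7)
    expect_equal(sum(prune_likelihood(tr, pats, mh)), 1, tolerance = 1e-10)
  }
})

test_that("the star engine refuses trees beyond about 12 leaves", {
  tr <- random_tree(13)
  expect_warning(decompose_sum_of_stars(tr), "12 leaves")
  pat <- random_pattern(tr)
  expect_warning(v <- site_likelihood(tr, pat, bg, engine = "star"),
                 "falling back")
  expect_equal(v, prune_likelihood(tr, pat, bg))
  expect_error(site_likelihood(fig_tree(), c(A = "A", C = "C", T = "T"),
                               subst_model("HKY85", bg$pi, kappa = 2),
                               engine = "star"),
               "F81")
})

test_that("site_likelihood dispatches engines consistently", {
  tr <- fig_tree()
  pat <- c(A = "A", C = "G", T = "T")
  expect_equal(site_likelihood(tr, pat, bg, engine = "auto"),
               site_likelihood(tr, pat, bg, engine = "prune"),
               tolerance = 1e-13)
})
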