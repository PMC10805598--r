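primate_tree <- function(q = 0.92) with_q(study_topology("primates"), q)

test_that("branch fitting hits the q = 1 boundary on substitution-free data", {
  tr <- study_topology("primates")
  groups <- tidyr::expand_grid(site_id = sprintf("s%03d", 1:120),
                               species = tr$leaf_order) |>
    dplyr::mutate(chrom = "chr1", start = 0L, end = 2L, strand = "+",
                  seq = "AC")
  expect_warning(fit <- fit_branch_proximities(groups, tr, neutral_columns = 1),
                 "boundary")
  expect_true(all(tidy(fit)$q[-1] > 0.99))
})

test_that("branch fitting collapses q on signal-free i.i.d. data", {
  tr <- study_topology("primates")
  groups <- iid_groups(tr, 400, 1, mammal_background, seed = 21)
  fit <- suppressWarnings(fit_branch_proximities(groups, tr, neutral_columns = 1))
  expect_true(all(tidy(fit)$q[-1] < 0.3))
})

test_that("branch proximities are recovered from simulated neutral sites", {
  tr <- study_topology("primates")
  b <- tidy(tr)
  qt <- rep(NA_real_, tr$n_nodes)
  withr::with_seed(99, qt[b$id[-1]] <- runif(tr$n_nodes - 1, 0.85, 0.99))
  sim <- simulate_groups(set_branch_proximities(tr, qt), mammal_background,
                         n_sites = 2500, seed = 17)
  fit <- fit_branch_proximities(sim$groups, tr, neutral_columns = 1)
  expect_true(fit$converged)
  est <- tidy(fit)
  root_kids <- est$id[!is.na(est$parent_id) & est$parent_id == tr$root$id]
  inner <- setdiff(est$id[-1], root_kids)
  expect_lt(max(abs(est$q[match(inner, est$id)] - qt[inner])), 0.03)
  # the two root-adjacent branches are identified through their product
  expect_lt(abs(prod(est$q[match(root_kids, est$id)]) - prod(qt[root_kids])), 0.03)
})

test_that("PSSV fitting at q -> 0 returns the pooled empirical frequencies", {
  tr <- primate_tree(q = 1e-6)
  pi <- c(0.55, 0.2, 0.1, 0.15)
  groups <- iid_groups(tr, 2000, 1, pi, seed = 5)
  fit <- fit_pssv(groups, tr, columns = 1)
  counts <- table(factor(substring(groups$seq, 1, 1), levels = c("A", "C", "G", "T")))
  emp <- as.numeric(counts / sum(counts))
  est <- as.numeric(profile_row(fit$pssv, 1))
  expect_lt(0.5 * sum(abs(est - emp)), 1e-3)
})

test_that("a unanimous column drives the fitted vector to the floor corner", {
  tr <- primate_tree(0.9)
  groups <- tidyr::expand_grid(site_id = sprintf("s%03d", 1:150),
                               species = tr$leaf_order) |>
    dplyr::mutate(chrom = "chr1", start = 0L, end = 1L, strand = "+", seq = "G")
  expect_warning(fit <- fit_pssv(groups, tr, columns = 1), "floor")
  est <- as.numeric(profile_row(fit$pssv, 1))
  expect_gt(est[3], 0.999)
})

test_that("fitting the same column twice is bit-identical", {
  tr <- primate_tree()
  sim <- simulate_groups(tr, c(0.6, 0.2, 0.1, 0.1), n_sites = 300, seed = 9)
  f1 <- fit_pssv(sim$groups, tr, columns = 1)
  f2 <- fit_pssv(sim$groups, tr, columns = 1)
  expect_identical(f1$pssv, f2$pssv)
  expect_true(all(abs(rowSums(as.matrix(f1$pssv[, c("A", "C", "G", "T")])) - 1) < 1e-9))
})

test_that("per-position stationary vectors are recovered from simulation", {
  tr <- primate_tree(0.92)
  pim <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
               c(0.1, 0.1, 0.7, 0.1), c(0.1, 0.1, 0.1, 0.7))
  sim <- simulate_groups(tr, pim, n_sites = 1200, seed = 23)
  fit <- fit_pssv(sim$groups, tr)
  m <- as.matrix(fit$pssv[, c("A", "C", "G", "T")])
  tv <- vapply(1:4, function(i) 0.5 * sum(abs(m[i, ] - pim[i, ])), numeric(1))
  expect_true(all(tv <= 0.05))
})

test_that("F81 and HKY85 give similar PSSVs on the same data", {
  tr <- study_topology("primates")
  b <- tidy(tr)
  qt <- rep(NA_real_, tr$n_nodes); qt[b$id[-1]] <- 0.93
  pim <- rbind(mammal_background, c(0.65, 0.15, 0.1, 0.1),
               c(0.1, 0.1, 0.15, 0.65), mammal_background)
  sim <- simulate_groups(set_branch_proximities(tr, qt), pim,
                         n_sites = 700, seed = 31)
  fit_f <- fit_branch_proximities(sim$groups, tr, neutral_columns = c(1, 4))
  fit_h <- fit_branch_proximities(sim$groups, tr, neutral_columns = c(1, 4),
                                  model = "HKY85")
  pssv_f <- fit_pssv(sim$groups, fit_f$tree, columns = 2:3)
  pssv_h <- fit_pssv(sim$groups, fit_h$tree, columns = 2:3,
                     model = "HKY85", kappa = fit_h$kappa)
  mf <- as.matrix(pssv_f$pssv[, c("A", "C", "G", "T")])
  mh <- as.matrix(pssv_h$pssv[, c("A", "C", "G", "T")])
  tv <- vapply(1:2, function(i) 0.5 * sum(abs(mf[i, ] - mh[i, ])), numeric(1))
  expect_true(all(tv <= 0.03))
  expect_gt(fit_h$kappa, 0.5)
  expect_lt(fit_h$kappa, 2.5)   # data were simulated under F81 (kappa = 1)
})

test_that("ancestral posteriors normalize and respect the q limits", {
  tr <- primate_tree(1)   # q = 1: identity transitions
  groups <- tidyr::expand_grid(site_id = sprintf("s%02d", 1:10),
                               species = tr$leaf_order) |>
    dplyr::mutate(chrom = "chr1", start = 0L, end = 1L, strand = "+", seq = "G")
  post <- ancestral_posterior(groups, tr, 1)
  expect_true(all(abs(rowSums(as.matrix(post[, c("A", "C", "G", "T")])) - 1) < 1e-12))
  expect_true(all(post$G == 1))

  tr0 <- primate_tree(1e-8)  # q -> 0: leaves carry no information
  post0 <- ancestral_posterior(groups, tr0, 1)
  expect_equal(as.numeric(post0[1, c("A", "C", "G", "T")]),
               unname(mammal_background), tolerance = 1e-6)
})

test_that("ancestral posteriors match brute-force enumeration", {
  tr <- fig_tree(0.9, 0.9, 0.9, 0.9)
  groups <- tibble::tibble(site_id = "s1", species = c("A", "C", "T"),
                           chrom = "chr1", start = 0L, end = 1L, strand = "+",
                           seq = c("A", "A", "A"))
  post <- ancestral_posterior(groups, tr, 1)
  # enumerate the internal node: P(leaves | root = a) * prior, normalized
  pi <- mammal_background
  Tq <- function(q) f81_transition(q, pi)
  lik <- vapply(1:4, function(a) {
    sum(vapply(1:4, function(b) {
      Tq(0.9)[1, a] * Tq(0.9)[b, a] * Tq(0.9)[1, b] * Tq(0.9)[1, b]
    }, numeric(1)))
  }, numeric(1))
  expected <- lik * pi / sum(lik * pi)
  expect_equal(as.numeric(post[1, c("A", "C", "G", "T")]), unname(expected),
               tolerance = 1e-12)
  expect_gt(post$A[1], 0.9)
})

test_that("conditional PSSV selection is strict and errors on empty subsets", {
  tr <- primate_tree(0.9)
  sim <- simulate_groups(tr, c(0.7, 0.1, 0.1, 0.1), n_sites = 200, seed = 13)
  # q < 1 keeps every posterior strictly below 1, so threshold 1 selects none
  expect_error(conditional_pssv(sim$groups, tr, 1, "A", threshold = 1),
               "No site group")
  # unambiguous data: conditioning selects every group, so the conditional
  # PSSV equals the unconditional one
  groups <- dplyr::mutate(sim$groups, seq = "A")
  cond <- suppressWarnings(conditional_pssv(groups, tr, 1, "A"))
  expect_equal(cond$n_selected, 200L)
  expect_identical(cond$pssv, suppressWarnings(fit_pssv(groups, tr))$pssv)
  expect_warning(conditional_pssv(sim$groups, tr, 1, "A", min_groups = 1e5),
                 "only")
})

test_that("conditional PSSVs separate a planted ancestral mixture", {
  tr <- primate_tree(0.92)
  coupling <- list(
    list(position = 1, nucleotide = "A", target = 2, pi = c(0.1, 0.7, 0.1, 0.1)),
    list(position = 1, nucleotide = "G", target = 2, pi = c(0.1, 0.1, 0.7, 0.1)))
  base <- rbind(c(0.45, 0.05, 0.45, 0.05), c(0.25, 0.25, 0.25, 0.25))
  sim <- simulate_groups(tr, base, n_sites = 1000, coupling = coupling, seed = 29)
  cond_a <- conditional_pssv(sim$groups, tr, 1, "A", columns = 2)
  cond_g <- conditional_pssv(sim$groups, tr, 1, "G", columns = 2)
  uncond <- fit_pssv(sim$groups, tr, columns = 2)
  jsd_ag <- jsd_profile(cond_a$pssv, cond_g$pssv)$jsd
  expect_gt(jsd_ag, jsd_profile(uncond$pssv, cond_a$pssv)$jsd)
  expect_gt(jsd_ag, jsd_profile(uncond$pssv, cond_g$pssv)$jsd)
  # the C-rich component goes with ancestral A, the G-rich with ancestral G
  expect_gt(cond_a$pssv$C[1], cond_a$pssv$G[1])
  expect_gt(cond_g$pssv$G[1], cond_g$pssv$C[1])
  # subset assignment accuracy against the latent roots
  root1 <- substring(sim$roots$root_seq, 1, 1)
  acc_a <- mean(root1[match(cond_a$site_ids, sim$roots$site_id)] == "A")
  acc_g <- mean(root1[match(cond_g$site_ids, sim$roots$site_id)] == "G")
  expect_gt(acc_a, 0.8)
  expect_gt(acc_g, 0.8)
})

test_that("Jensen-Shannon profile matches its closed form", {
  p <- new_profile(rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
  q <- new_profile(rbind(c(0, 1, 0, 0), c(0.5, 0, 0.5, 0), c(0.25, 0.25, 0.25, 0.25)))
  out <- jsd_profile(p, q)
  expect_equal(out$jsd, c(1, 0.5, 0))
  expect_equal(jsd_profile(p, p)$jsd, c(0, 0, 0))
  expect_error(jsd_profile(p, new_profile(matrix(0.25, 2, 4))), "length")
})

test_that("groups not covering the tree are excluded from fits", {
  tr <- primate_tree()
  sim <- simulate_groups(tr, c(0.7, 0.1, 0.1, 0.1), n_sites = 60, seed = 3)
  partial <- dplyr::filter(sim$groups, !(site_id == "site00001" & species == "human"))
  expect_message(fit <- suppressWarnings(
    fit_branch_proximities(partial, tr, neutral_columns = 1)), "Excluded 1")
  expect_equal(fit$n_groups, 59L)
})
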