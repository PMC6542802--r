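test_that("Z separation matches hand computation on the toy groups", {
  # groups {0,1} and {2,3}: means 0.5 and 2.5, grand mean 1.5
  # between = 2*(1)^2 + 2*(1)^2 = 4; pooled within SS = 4 * 0.25 = 1
  zs <- z_separation(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(zs$z, 4)
  expect_equal(zs$between, 4)
  expect_equal(zs$within, 1)

  # identical group means: Z = 0
  expect_equal(z_separation(c(0, 1, 0, 1), c("a", "a", "b", "b"))$z, 0)

  # mean-square denominator rescales Z by sum(n_k - 1)
  zm <- z_separation(c(0, 1, 2, 3), c("a", "a", "b", "b"), within = "ms")
  expect_equal(zm$z, 4 * 2)
})

test_that("Z separation is invariant to affine transforms and relabeling", {
  set.seed(9)
  x <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  z0 <- z_separation(x, g)$z
  for (case in list(c(2, 3), c(-0.5, 10), c(100, -7))) {
    expect_equal(z_separation(case[1] * x + case[2], g)$z, z0)
  }
  relabeled <- c(a = "q", b = "r", c = "s")[g]
  expect_equal(z_separation(x, relabeled)$z, z0)
})

test_that("degenerate separation inputs raise classed errors", {
  expect_error(z_separation(c(0, 0, 1, 1), c("a", "a", "b", "b")),
               class = "deathcue_degenerate")
  expect_error(z_separation(c(0, 1, 2), c("a", "a", "b")),
               class = "deathcue_insufficient_data")
})

test_that("permutation p-values respect the add-one smoothing bound", {
  m <- process_metab(simulate_metabolome(n_replicates = 2, n_metabolites = 8,
                                         planted_rank = 2, missing_fraction = 0,
                                         seed = 4))
  pt <- permutation_pc_test(m, "exposure", n_permutations = 10, seed = 1)
  expect_true(all(pt$p_value >= 1 / 11))
  expect_true(all(pt$p_value <= 1))
})

test_that("a strongly planted effect is recovered on a significant component", {
  hits <- 0
  for (i in 1:10) {
    m <- simulate_metabolome(effect_size = 3, seed = 800 + i)
    proc <- process_metab(m)
    pca <- run_pca(proc)
    pt <- permutation_pc_test(pca, n_permutations = 499, seed = 900 + i)
    sig <- which(pt$p_value < 0.05)
    planted <- attr(m, "planted")
    proj <- as.numeric(proc$abundance %*% planted$direction[colnames(proc$abundance)])
    if (length(sig) > 0 &&
        max(abs(cor(pca$scores[, sig, drop = FALSE], proj))) > 0.9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 8)
})

test_that("loading ranks order by absolute value with lexicographic ties", {
  vals <- matrix(rnorm(8 * 6), 8, 6)
  m <- make_metab(vals, scale = "log") |> standardize() |> run_pca()
  # direct check of ordering semantics on a constructed loading vector
  fake <- m
  fake$loadings[, 1] <- c(0.9, -0.95, 0.1, 0.3, -0.3, 0.05)
  rownames(fake$loadings) <- sprintf("m%02d", 1:6)
  top2 <- rank_loadings(fake, 1, top_n = 2)
  expect_equal(top2$metabolite, c("m02", "m01"))
  expect_equal(top2$abs_loading, c(0.95, 0.9))
  # |m04| == |m05|: tie broken by name, stable across calls
  top4 <- rank_loadings(fake, 1, top_n = 4)
  expect_equal(top4$metabolite[3:4], c("m04", "m05"))
  expect_identical(rank_loadings(fake, 1, top_n = 4), top4)
  expect_warning(all10 <- rank_loadings(fake, 1, top_n = 10), "exceeds")
  expect_equal(nrow(all10), 6)
})

test_that("top loadings recover the metabolites spanning a sparse shift", {
  # When the exposure shift loads on a known set of 10 metabolites, the
  # top-10 |loading| list of the shift-carrying component should be
  # dominated by that set.
  hits <- 0
  for (i in 1:10) {
    set.seed(300 + i)
    n <- 32
    p <- 60
    vals <- matrix(rnorm(n * p, 0, 1), n, p,
                   dimnames = list(NULL, sprintf("met%02d", seq_len(p))))
    genotype <- rep(c("control", "mutant"), each = 16)
    exposure <- rep(rep(c("unexposed", "exposed"), each = 8), 2)
    spanning <- sprintf("met%02d", 1:10)
    shifted <- genotype == "control" & exposure == "exposed"
    vals[shifted, spanning] <- vals[shifted, spanning] + 3
    m <- make_metab(vals, scale = "log", genotype = genotype, exposure = exposure)
    pca <- run_pca(standardize(m))
    pt <- permutation_pc_test(pca, n_permutations = 299, seed = 301 + i)
    comp <- pt$component[which.min(pt$p_value)]
    top <- rank_loadings(pca, comp, 10)
    if (length(intersect(top$metabolite, spanning)) >= 7) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("candidate screen flags perception-dependent shifts only", {
  set.seed(77)
  base <- matrix(rnorm(32 * 5, 10, 1), 32, 5,
                 dimnames = list(NULL, sprintf("met%d", 1:5)))
  genotype <- rep(c("control", "mutant"), each = 16)
  exposure <- rep(rep(c("unexposed", "exposed"), each = 8), 2)
  ctrl_exposed <- genotype == "control" & exposure == "exposed"
  mut_exposed <- genotype == "mutant" & exposure == "exposed"
  base[ctrl_exposed, "met1"] <- base[ctrl_exposed, "met1"] + 5 # control only
  base[ctrl_exposed, "met2"] <- base[ctrl_exposed, "met2"] + 5 # both genotypes
  base[mut_exposed, "met2"] <- base[mut_exposed, "met2"] + 5
  m <- make_metab(base, scale = "log", genotype = genotype, exposure = exposure)
  res <- screen_candidates(m, c("met1", "met2", "met3"))
  expect_true(res$flagged[res$metabolite == "met1"])
  expect_false(res$flagged[res$metabolite == "met2"]) # criterion (ii) fails
  expect_identical(res$flagged,
                   res$p_control < 0.05 & res$p_mutant >= 0.05)
})

test_that("candidate screen has the designed power and error rate", {
  flag_rate <- function(shift, n_runs) {
    flags <- logical(n_runs)
    for (i in seq_len(n_runs)) {
      set.seed(4000 + i + round(1000 * shift))
      vals <- matrix(rnorm(32, 0, 1), 32, 1, dimnames = list(NULL, "met"))
      genotype <- rep(c("control", "mutant"), each = 16)
      exposure <- rep(rep(c("unexposed", "exposed"), each = 8), 2)
      vals[genotype == "control" & exposure == "exposed", 1] <-
        vals[genotype == "control" & exposure == "exposed", 1] + shift
      m <- make_metab(vals, scale = "log", genotype = genotype, exposure = exposure)
      flags[i] <- screen_candidates(m, "met")$flagged
    }
    mean(flags)
  }
  # +2 SD shift in control-exposed only: one-sided t power ~0.98 at n=8/cell,
  # jointly with the ~0.95 chance of a quiet mutant arm -> ~0.93 expected
  expect_gte(flag_rate(2, 200), 0.88)
  # No shift anywhere: because the test direction is taken from the observed
  # control effect, the control-arm test is effectively two-sided at 2*alpha,
  # so the null flag rate is ~2*alpha*(1 - alpha) ~ 0.095, not alpha.
  expect_lte(flag_rate(0, 400), 0.13)
})

test_that("the within-genotype rule finds the planted perception component", {
  hits <- 0
  for (i in 1:10) {
    m <- simulate_metabolome(effect_size = 3, seed = 8800 + i)
    proc <- process_metab(m)
    pca <- run_pca(proc)
    target <- suppressWarnings(
      select_perception_pc(pca, n_permutations = 499, seed = 8900 + i)
    )
    if (is.na(target)) next
    planted <- attr(m, "planted")
    proj <- as.numeric(proc$abundance %*% planted$direction[colnames(proc$abundance)])
    if (abs(cor(pca$scores[, as.character(target)], proj)) > 0.9) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("marginal target selection requires exposure but not genotype separation", {
  m <- simulate_metabolome(seed = 21)
  proc <- process_metab(m)
  pca <- run_pca(proc)
  et <- permutation_pc_test(pca, "exposure", n_permutations = 499, seed = 22)
  gt <- permutation_pc_test(pca, "genotype", n_permutations = 499, seed = 23)
  target <- select_target_pc(et, gt)
  expect_true(is.na(target) || target %in% et$component)
  if (!is.na(target)) {
    expect_lt(et$p_value[et$component == target], 0.05)
    expect_gte(gt$p_value[gt$component == target], 0.05)
  }
})
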