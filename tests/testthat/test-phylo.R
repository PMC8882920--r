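test_that("Newick reader parses, validates, and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_error(read_newick("((A:1,A:1):1,C:2);"),
               class = "voweldisp_config_error")
  expect_error(suppressWarnings(read_newick("((A:1,B:1")),
               class = "voweldisp_config_error")
  expect_error(read_newick("((A,B),C);"), class = "voweldisp_config_error")
})

test_that("a 50-tip tree survives a write/read round-trip", {
  tr <- simulate_yule_tree(50, seed = 14)
  back <- read_newick(write_newick(tr))
  expect_setequal(back$tip.label, tr$tip.label)
  d1 <- stats::cophenetic(tr); d2 <- stats::cophenetic(back)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
})

test_that("pruning preserves patristic distances among kept tips", {
  tr3 <- read_newick("((A:1,B:2):1,C:2);")
  pruned <- prune_to_taxa(tr3, c("A", "B"))
  expect_equal(sort(pruned$tip.label), c("A", "B"))
  expect_equal(stats::cophenetic(pruned)["A", "B"], 3)
  # identity when keeping everything
  same <- prune_to_taxa(tr3, tr3$tip.label)
  expect_setequal(same$tip.label, tr3$tip.label)
  # oracle: random 20-tip tree, random 8 kept, distance matrix unchanged
  tr20 <- simulate_yule_tree(20, seed = 5)
  keep <- withr::with_seed(6, sample(tr20$tip.label, 8))
  sub <- prune_to_taxa(tr20, keep)
  expect_equal(stats::cophenetic(sub)[keep, keep],
               stats::cophenetic(tr20)[keep, keep], tolerance = 1e-10)
  expect_error(prune_to_taxa(tr3, c("A", "Z")),
               class = "voweldisp_config_error")
})

test_that("contrast recursion: base cases", {
  tr2 <- read_newick("(A:1.5,B:0.5);")
  cs <- independent_contrasts(tr2, c(A = 4, B = 1))
  expect_equal(nrow(cs), 1)
  expect_equal(cs$contrast, (4 - 1) / sqrt(2))
  expect_equal(cs$variance, 2)
  # constant trait: all contrasts zero
  fix <- pic_fixture()
  cs0 <- independent_contrasts(fix$tree, c(A = 2, B = 2, C = 2, D = 2))
  expect_equal(cs0$contrast, rep(0, 3))
})

test_that("contrasts match the hand-executed pruning pass on the 4-tip tree", {
  fix <- pic_fixture()
  cs <- independent_contrasts(fix$tree, fix$trait)
  expect_equal(nrow(cs), 3) # n_tips - 1
  expect_equal(sort(cs$contrast), sort(unname(fix$contrasts)),
               tolerance = 1e-12)
  expect_equal(sort(cs$variance), sort(unname(fix$variances)),
               tolerance = 1e-12)
})

test_that("contrasts agree with the reference implementation on random trees", {
  for (seed in c(2, 9)) {
    tr <- simulate_yule_tree(30, seed = seed)
    x <- withr::with_seed(seed, stats::setNames(rnorm(30), tr$tip.label))
    mine <- independent_contrasts(tr, x)
    ref <- ape::pic(x, tr, var.contrasts = TRUE)
    expect_equal(mine$contrast, unname(ref[, "contrasts"]),
                 tolerance = 1e-10)
    expect_equal(mine$variance, unname(ref[, "variance"]),
                 tolerance = 1e-10)
  }
})

test_that("polytomies are refused until resolved", {
  star <- ape::stree(5, "star"); star$edge.length <- rep(1, 5)
  x <- stats::setNames(1:5, star$tip.label)
  expect_error(independent_contrasts(star, x),
               class = "voweldisp_config_error")
  res <- resolve_polytomies(star)
  expect_true(ape::is.binary(res))
  expect_equal(nrow(independent_contrasts(res, x)), 4)
})

test_that("contrast correlation: exact bounds and star-tree equivalence", {
  tr <- simulate_yule_tree(20, seed = 44)
  x <- withr::with_seed(4, stats::setNames(rnorm(20), tr$tip.label))
  cx <- independent_contrasts(tr, x)
  cy <- independent_contrasts(tr, stats::setNames(2 * x, names(x)))
  expect_equal(contrast_correlation(cx, cy), 1, tolerance = 1e-12)
  cz <- independent_contrasts(tr, stats::setNames(-x, names(x)))
  expect_equal(contrast_correlation(cx, cz), -1, tolerance = 1e-12)
  # star tree with equal branch lengths: contrast correlation equals the
  # plain correlation of the centered tip values
  star <- ape::stree(9, "star"); star$edge.length <- rep(1, 9)
  star <- resolve_polytomies(star, epsilon = 0)
  a <- withr::with_seed(5, rnorm(9)); b <- withr::with_seed(6, rnorm(9))
  names(a) <- names(b) <- star$tip.label
  ca <- independent_contrasts(star, a); cb <- independent_contrasts(star, b)
  ac <- a - mean(a); bc <- b - mean(b)
  expect_equal(contrast_correlation(ca, cb),
               sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2)),
               tolerance = 1e-9)
  expect_error(contrast_correlation(ca, independent_contrasts(
    star, stats::setNames(rep(1, 9), star$tip.label))),
    class = "voweldisp_domain_error")
})

test_that("BM-simulated contrasts are properly standardized", {
  # Garland-style diagnostic: |contrast| shows no trend in its SD
  tr <- simulate_yule_tree(100, seed = 12)
  traits <- simulate_bivariate_traits(tr, "BM", seed = 13)
  cs <- independent_contrasts(tr, stats::setNames(traits$x, traits$tip))
  expect_equal(nrow(cs), 99)
  r <- stats::cor(abs(cs$contrast), sqrt(cs$variance))
  expect_lt(abs(r), 0.3)
})

test_that("tip covariance matrices have the process-implied structure", {
  # star tree of depth T under BM: T * identity
  star <- ape::stree(4, "star"); star$edge.length <- rep(2.5, 4)
  V <- phylo_vcv(star, "BM")
  expect_equal(unname(V), diag(2.5, 4), tolerance = 1e-12)
  # sister tips share their stem length
  tr <- read_newick("((A:1,B:1):3,C:4);")
  V2 <- phylo_vcv(tr, "BM")
  expect_equal(V2["A", "B"], 3)
  expect_equal(V2["A", "C"], 0)
  expect_equal(V2["A", "A"], 4)
  # OU: exp(-alpha * patristic distance), unit diagonal
  V3 <- phylo_vcv(tr, "OU", alpha = 0.3)
  expect_equal(diag(V3), stats::setNames(rep(1, 3), c("A", "B", "C")))
  expect_equal(V3["A", "B"], exp(-0.3 * 2))
  expect_error(phylo_vcv(tr, "OU"), class = "voweldisp_domain_error")
})

test_that("vanishing OU attraction reproduces BM inference", {
  tr <- simulate_yule_tree(25, seed = 3)
  tt <- simulate_bivariate_traits(tr, "BM", rho = -0.5, seed = 7)
  d <- tibble::tibble(tip = tt$tip, effective_de = tt$x, fe = tt$y)
  bm <- pgls_fit(d, tr, fe ~ effective_de, "BM")
  ou <- pgls_fit(d, tr, fe ~ effective_de, "OU", alpha = 1e-6)
  expect_equal(ou$beta, bm$beta, tolerance = 1e-4)
})
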