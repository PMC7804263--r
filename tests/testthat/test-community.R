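test_that("percent cover from points counts and conserves", {
  pts <- data.frame(
    quadrat_id = rep(c("Q1", "Q2"), each = 100),
    sample_id = "S1",
    label = c(rep("Turf", 40), rep("CCA", 60), rep("Turf", 10),
              rep("sand", 90)))
  cm <- percent_cover_from_points(pts, "quadrat_id")
  expect_equal(cm$cover["Q1", "Turf"], 40)
  expect_equal(unname(rowSums(cm$cover)), c(100, 100))
  # pooling to sample level gives 200-point denominators here
  cs <- percent_cover_from_points(pts, "sample_id")
  expect_equal(cs$cover["S1", "Turf"], 100 * 50 / 200)
  expect_error(percent_cover_from_points(pts[0, ], "quadrat_id"))
})

test_that("pruning and standardization follow the cover-algebra", {
  m <- rbind(S1 = c(Turf = 45, sand = 30, shadow = 25),
             S2 = c(Turf = 60, sand = 20, shadow = 20))
  cm <- community_matrix(m)
  out <- prepare_community_matrix(cm)
  expect_equal(unname(out$cover[, "Turf"]), c(100, 100))

  m2 <- rbind(S1 = c(Turf = 60, CCA = 20, rock = 20))
  out2 <- prepare_community_matrix(community_matrix(m2))
  expect_equal(unname(out2$cover["S1", c("Turf", "CCA")]), c(75, 25))

  sq <- transform_sqrt(out2)
  expect_equal(unname(sq$cover["S1", "CCA"]), 5)
  expect_error(transform_sqrt(sq), "already")
  zero <- community_matrix(rbind(S1 = c(Turf = 0, sand = 100)))
  expect_error(prepare_community_matrix(zero), "zero living cover")
})

test_that("Bray-Curtis matches hand computation and a brute-force oracle", {
  m <- rbind(a = c(4, 1, 0), b = c(1, 1, 2))
  s <- bray_curtis(m)
  expect_equal(s$values["a", "b"], 100 * 4 / 9, tolerance = 1e-12)
  expect_equal(diag(s$values), c(a = 100, b = 100))

  ident <- rbind(x = c(3, 2), y = c(3, 2))
  expect_equal(bray_curtis(ident)$values["x", "y"], 100)
  disj <- rbind(x = c(5, 0), y = c(0, 5))
  expect_equal(bray_curtis(disj)$values["x", "y"], 0)

  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    p <- sample(2:8, 1)
    m <- matrix(rexp(n * p), n, p)
    rownames(m) <- paste0("u", 1:n)
    expect_equal(bray_curtis(m)$values, bray_oracle(m), tolerance = 1e-12)
  }
  expect_error(bray_curtis(rbind(a = c(-1, 2), b = c(1, 1))), "negative")
  expect_warning(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("Bray-Curtis agrees with vegan as an independent cross-check", {
  set.seed(9)
  m <- matrix(rpois(60, 8), 10, 6)
  rownames(m) <- paste0("u", 1:10)
  ours <- bray_curtis(m)$values
  veg <- as.matrix(vegan::vegdist(m, "bray"))
  expect_equal(ours[lower.tri(ours)], 100 * (1 - veg[lower.tri(veg)]),
               tolerance = 1e-10)
})

test_that("SIMPROF never splits duplicated units and recovers planted groups", {
  m <- rbind(u1 = c(10, 5, 1), u2 = c(10, 5, 1), u3 = c(1, 2, 30),
             u4 = c(1, 2, 30))
  cm <- community_matrix(m, transform = "sqrt")
  gr <- cluster_simprof(cm, n_perm = 199, seed = 1)
  expect_equal(unname(gr$groups["u1"]), unname(gr$groups["u2"]))
  expect_equal(unname(gr$groups["u3"]), unname(gr$groups["u4"]))

  cm2 <- toy_community(4)
  gr2 <- cluster_simprof(cm2, n_perm = 499, seed = 2)
  expect_equal(length(unique(gr2$groups)), 2)
  expect_equal(length(unique(gr2$groups[1:4])), 1)
  expect_error(cluster_simprof(community_matrix(m[1:2, ],
                                                transform = "sqrt")),
               "at least 3")
  expect_true(all(gr2$tests$p > 0 & gr2$tests$p <= 1))
})

test_that("SIMPROF is seed-reproducible and stable in n_perm", {
  cm <- toy_community(4)
  g1 <- cluster_simprof(cm, n_perm = 299, seed = 5)
  g2 <- cluster_simprof(cm, n_perm = 299, seed = 5)
  expect_identical(g1$groups, g2$groups)
  expect_identical(g1$tests$p, g2$tests$p)
  g3 <- cluster_simprof(cm, n_perm = 599, seed = 5)
  # doubling permutations moves root p by less than 2 binomial SEs
  p1 <- g1$tests$p[1]
  se <- sqrt(p1 * (1 - p1) / 299)
  expect_lte(abs(g3$tests$p[1] - p1), max(2 * se, 2 / 299))
})

test_that("SIMPER contributions reconstruct similarities and close at 100", {
  m <- rbind(u1 = c(4, 2), u2 = c(4, 2), u3 = c(1, 9), u4 = c(1.2, 8.8))
  cm <- community_matrix(m, transform = "sqrt")
  g <- setNames(c("g1", "g1", "g2", "g2"), rownames(m))
  out <- simper(cm, g)
  t1 <- out$within$g1
  expect_equal(t1$av_sim[t1$taxon == "t1"] /
                 sum(t1$av_sim) * 100, t1$ind_contrib[t1$taxon == "t1"])
  # identical units: similarity 100, contributions 2*4/12 and 2*2/12
  colnames(m) <- c("t1", "t2")
  out <- simper(community_matrix(m, transform = "sqrt"), g)
  t1 <- out$within$g1
  expect_equal(sum(t1$av_sim), 100)
  expect_equal(sort(t1$ind_contrib), c(100 / 3, 200 / 3), tolerance = 1e-9)
  expect_equal(t1$cum_contrib[nrow(t1)], 100, tolerance = 1e-9)
  expect_equal(out$within$g2$cum_contrib[2], 100, tolerance = 1e-9)

  # additivity: per-pair taxon terms sum to the pairwise similarity
  set.seed(4)
  mm <- matrix(rexp(24), 6, 4,
               dimnames = list(paste0("u", 1:6), paste0("t", 1:4)))
  gg <- setNames(rep(c("A", "B"), each = 3), rownames(mm))
  sims <- bray_curtis(mm)$values
  outA <- simper(community_matrix(mm, transform = "sqrt"), gg)
  pairs <- utils::combn(1:3, 2)
  av_sim_A <- mean(apply(pairs, 2, function(jk) sims[jk[1], jk[2]]))
  expect_equal(sum(outA$within$A$av_sim), av_sim_A, tolerance = 1e-9)
  expect_named(outA$between, "A_vs_B")
  expect_equal(outA$between$A_vs_B$cum_contrib[4], 100, tolerance = 1e-9)
})

test_that("SIMPER singleton groups report abundance only", {
  m <- rbind(u1 = c(4, 2), u2 = c(1, 9), u3 = c(2, 8))
  g <- setNames(c("solo", "duo", "duo"), rownames(m))
  out <- simper(community_matrix(m, transform = "sqrt"), g,
                raw = community_matrix(m))
  expect_true(all(is.na(out$within$solo$av_sim)))
  expect_equal(sum(out$within$solo$av_abundance), 6)
})

test_that("ANOSIM: exact enumeration, extremes and permutation null", {
  # 2+2 perfectly separated: R = 1, exact p = 1/3
  m <- rbind(a1 = c(10, 0), a2 = c(9, 1), b1 = c(0, 10), b2 = c(1, 9))
  d <- bray_curtis(m)
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  res <- anosim(d, g, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  # all between > all within -> R = 1 in a larger design too
  cm <- toy_community(4)
  d2 <- bray_curtis(cm)
  g2 <- setNames(rep(c("A", "B"), each = 4), rownames(cm$cover))
  r2 <- anosim(d2, g2, n_perm = 499, seed = 2)
  expect_gte(r2$statistic, 0.9)
  expect_lte(r2$p_value, 0.05)
  expect_true(abs(r2$statistic) <= 1)
  expect_gt(r2$p_value, 0)
  expect_error(anosim(d2, setNames(rep("A", 8), rownames(cm$cover))),
               "two groups")
})

test_that("ANOSIM matches vegan and has a centred null", {
  set.seed(11)
  m <- matrix(rexp(9 * 5), 9, 5, dimnames = list(paste0("u", 1:9), NULL))
  g <- setNames(rep(c("A", "B", "C"), each = 3), rownames(m))
  ours <- anosim(bray_curtis(m), g, n_perm = 999, seed = 3)
  veg <- vegan::anosim(vegan::vegdist(m, "bray"), factor(g),
                       permutations = 999)
  expect_equal(ours$statistic, unname(veg$statistic), tolerance = 1e-10)

  # random labels on noise: mean R over 200 runs within +-0.05 of 0
  Rs <- vapply(1:200, function(b) {
    set.seed(1000 + b)
    mm <- matrix(rexp(8 * 4), 8, 4, dimnames = list(paste0("u", 1:8), NULL))
    gg <- setNames(sample(rep(c("A", "B"), each = 4)), rownames(mm))
    anosim(bray_curtis(mm), gg, n_perm = 19, seed = b)$statistic
  }, 0)
  expect_lte(abs(mean(Rs)), 0.05)
})

test_that("nMDS reaches near-zero stress on embeddable data", {
  set.seed(21)
  pts <- matrix(rnorm(16), 8, 2, dimnames = list(paste0("u", 1:8), NULL))
  d <- euclidean_distance(pts)
  fit <- nmds(d, n_dim = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  # stress non-increasing as dimensions grow
  s <- vapply(1:3, function(k)
    nmds(d, n_dim = k, n_restarts = 10, seed = 1)$stress, 0)
  expect_true(all(diff(s) <= 1e-6))
  # duplicated units end up coincident
  m <- rbind(u1 = c(5, 1, 2), u2 = c(5, 1, 2), u3 = c(0, 8, 1),
             u4 = c(2, 2, 9), u5 = c(7, 1, 4))
  fit2 <- nmds(bray_curtis(m), n_dim = 2, n_restarts = 10, seed = 2)
  expect_lt(sqrt(sum((fit2$points["u1", ] - fit2$points["u2", ])^2)),
            0.05 * max(dist(fit2$points)))
  expect_error(nmds(d, n_dim = 8), "n_dim")
})

test_that("DistLM reproduces classical ANOVA and its projection identity", {
  set.seed(31)
  y <- c(rnorm(6, 0), rnorm(6, 2))
  f <- rep(c("lo", "hi"), each = 6)
  d <- euclidean_distance(matrix(y, dimnames = list(paste0("u", 1:12), NULL)))
  res <- distlm_dbrda(d, data.frame(f = f), n_perm = 199, seed = 1)
  Fcl <- summary(stats::aov(y ~ f))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, Fcl, tolerance = 1e-8)

  # tr(HGH) + tr((I-H)G(I-H)) = tr(G) for every fit
  set.seed(32)
  m <- matrix(rexp(10 * 4), 10, 4, dimnames = list(paste0("u", 1:10), NULL))
  dd <- bray_curtis(m)
  preds <- data.frame(a = rnorm(10), b = factor(rep(c("x", "y"), 5)))
  G <- benthomap:::gower_center(benthomap:::as_dissimilarity(dd))
  X <- benthomap:::expand_predictors(preds)$X
  H <- benthomap:::hat_matrix(X)$H
  IH <- diag(10) - H
  expect_equal(sum(diag(H %*% G %*% H)) + sum(diag(IH %*% G %*% IH)),
               sum(diag(G)), tolerance = 1e-9)
  res2 <- distlm_dbrda(dd, preds, n_perm = 99, seed = 2)
  expect_true(res2$r2 >= 0 && res2$r2 <= 1)
  expect_equal(nrow(res2$marginal), 2)
  expect_true(res2$best_subset %in% res2$subsets$subset)
  expect_equal(dim(res2$predictor_correlations)[2], ncol(res2$axes))
})

test_that("DistLM R2 under pure-noise predictors matches m/(n-1)", {
  r2s <- vapply(1:60, function(b) {
    set.seed(2000 + b)
    y <- matrix(rnorm(12), dimnames = list(paste0("u", 1:12), NULL))
    x <- rnorm(12)
    d <- euclidean_distance(y)
    distlm_dbrda(d, data.frame(x = x), n_perm = 0, seed = b)$r2
  }, 0)
  expect_lt(abs(mean(r2s) - 1 / 11), 0.03)
})

test_that("CAP separates planted groups and respects axis counts", {
  cm <- toy_community(4, seed = 5)
  d <- bray_curtis(cm)
  g <- setNames(rep(c("A", "B"), each = 4), rownames(cm$cover))
  res <- cap_analysis(d, g, predictors = data.frame(g = unname(g)))
  expect_equal(res$allocation_success, 1)
  expect_equal(res$n_canonical, 1)           # groups - 1
  expect_equal(nrow(res$predictor_correlations), 2)

  # permuted labels allocate near chance
  set.seed(51)
  succ <- replicate(20, {
    gg <- setNames(sample(unname(g)), names(g))
    suppressWarnings(cap_analysis(d, gg)$allocation_success)
  })
  expect_lte(mean(succ), 0.5 + 2 * stats::sd(succ) / sqrt(20) + 0.15)
  expect_error(cap_analysis(d, setNames(rep("A", 8), names(g))), "two groups")
})

test_that("DistLM with Euclidean distances reproduces classical redundancy R2", {
  set.seed(61)
  n <- 15
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Y <- matrix(rnorm(n * 3), n, 3) + 0.8 * X$x1
  rownames(Y) <- paste0("u", 1:n)
  res <- distlm_dbrda(euclidean_distance(Y), X, n_perm = 0, seed = 1)
  # direct least-squares oracle
  Yc <- scale(Y, scale = FALSE)
  fit <- stats::lm(Yc ~ scale(X$x1) + scale(X$x2))
  r2_direct <- 1 - sum(stats::residuals(fit)^2) / sum(Yc^2)
  expect_equal(res$r2, r2_direct, tolerance = 1e-10)
})
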