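# distribution overlap, MSWO, phenotypic activity

dist1d <- function(mu, s2, n = 100) pheno_dist(mu, matrix(s2), n)

test_that("overlap matches its scalar closed forms", {
  # unit variances, means 2 apart: 2*sqrt(1*1)/(1+1) * exp(-1/2 * 4/2) = e^-1
  expect_equal(overlap(dist1d(0, 1), dist1d(2, 1)), exp(-1),
               tolerance = 1e-12)
  # equal means, variances 1 and 4: sqrt(4*1*4)/(1+4) = 0.8
  expect_equal(overlap(dist1d(0, 1), dist1d(0, 4)), 0.8, tolerance = 1e-12)
  # identity for arbitrary valid distributions
  set.seed(101)
  for (i in 1:20) {
    d <- random_dist(sample(1:6, 1))
    expect_equal(overlap(d, d), 1, tolerance = 1e-9)
  }
  expect_error(overlap(dist1d(0, 1), random_dist(2)), "dimension mismatch")
})

test_that("overlap agrees with a numerical Bhattacharyya-coefficient oracle", {
  # in 1-D the formula equals the integral of sqrt(f1 * f2) squared-free:
  # BC = integral sqrt(N(x;mu1,s1) N(x;mu2,s2)) dx, and O = BC^2
  set.seed(5)
  for (i in 1:10) {
    mu <- rnorm(2, 0, 2)
    s2 <- runif(2, 0.3, 3)
    bc <- integrate(function(x)
      sqrt(dnorm(x, mu[1], sqrt(s2[1])) * dnorm(x, mu[2], sqrt(s2[2]))),
      -Inf, Inf, rel.tol = 1e-12)$value
    expect_equal(overlap(dist1d(mu[1], s2[1]), dist1d(mu[2], s2[2])),
                 bc^2, tolerance = 1e-8)
  }
})

test_that("weighted overlap composes the three printed factors", {
  d0 <- dist1d(0, 1)
  d1 <- dist1d(3, 1)
  d2 <- dist1d(3.5, 1.5)
  expect_equal(weighted_overlap(d1, d2, d0),
               overlap(d1, d2) * (1 - overlap(d1, d0)) *
                 (1 - overlap(d2, d0)), tolerance = 1e-15)
  expect_equal(weighted_overlap(d1, d2, d0), weighted_overlap(d2, d1, d0))
  # a control-identical phenotype contributes nothing
  expect_equal(weighted_overlap(d0, d0, d0), 0)
  # identical phenotypes far from control approach 1
  far <- dist1d(60, 1)
  expect_equal(weighted_overlap(far, far, d0), 1, tolerance = 1e-9)
  # frozen arithmetic case: O = 0.5, O(.,d0) = 0.2 and 0.4 -> 0.24
  expect_equal(0.5 * (1 - 0.2) * (1 - 0.4), 0.24)
})

test_that("the MSWO dynamic program reproduces the worked 3-level case", {
  W <- rbind(c(0.9, 0.1, 0.0),
             c(0.1, 0.8, 0.2),
             c(0.0, 0.2, 0.7))
  n <- c(100, 100, 100)
  # diagonal matching: (200*0.9 + 200*0.8 + 200*0.7) / 600 = 0.8
  expect_equal(mswo_dp(W, n, n), 0.8, tolerance = 1e-12)
  expect_equal(phenotrack:::mswo_bruteforce_matrix(W, n, n), 0.8,
               tolerance = 1e-12)
})

test_that("DP equals the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:60) {
    Li <- sample(1:6, 1)
    Lj <- sample(1:6, 1)
    W <- matrix(runif(Li * Lj), Li, Lj)
    ni <- sample(0:200, Li, replace = TRUE)
    nj <- sample(0:200, Lj, replace = TRUE)
    if (sum(ni) + sum(nj) == 0) ni[1] <- 1
    expect_equal(mswo_dp(W, ni, nj),
                 phenotrack:::mswo_bruteforce_matrix(W, ni, nj),
                 tolerance = 1e-12)
  }
})

test_that("mswo on real trajectories: saturation, zero and symmetry", {
  set.seed(303)
  m <- 3
  d0 <- pheno_dist(rep(0, m), diag(m), 1000)
  mk_traj <- function(id, means, n = 100) {
    dists <- lapply(seq_along(means), function(l)
      pheno_dist(rep(means[l], m), diag(m), n, level = l))
    structure(list(compound_id = id, distributions = dists, control = d0),
              class = "pheno_trajectory")
  }
  far <- mk_traj("far", c(30, 40, 50))
  expect_equal(mswo(far, far), 1, tolerance = 1e-9)
  # a trajectory identical to control matches nothing
  ctrl_like <- mk_traj("ctrl", c(0, 0, 0))
  expect_equal(mswo(ctrl_like, far), 0, tolerance = 1e-12)
  expect_equal(mswo(ctrl_like, ctrl_like), 0, tolerance = 1e-12)
  # symmetry is exact
  t1 <- random_trajectory(5, m, d0, "a")
  t2 <- random_trajectory(4, m, d0, "b")
  expect_identical(mswo(t1, t2), mswo(t2, t1))
  # DP vs brute force on full trajectory objects
  expect_equal(mswo(t1, t2), mswo_bruteforce(t1, t2), tolerance = 1e-12)
  # single-level trajectories reduce to the weighted overlap itself
  s1 <- mk_traj("s1", 5)
  s2 <- mk_traj("s2", 5.5)
  expect_equal(mswo(s1, s2),
               weighted_overlap(s1$distributions[[1]], s2$distributions[[1]],
                                d0), tolerance = 1e-12)
})

test_that("potency-shifted copies of one track match via non-consecutive doses", {
  # two compounds on the same track, one 2 dose-levels less potent: the
  # optimal matching must skip levels rather than align them one-to-one
  set.seed(404)
  m <- 2
  d0 <- pheno_dist(rep(0, m), diag(m), 1000)
  track <- function(l) rep(2 * l, m)  # positions at 2,4,...,18 per dim
  potent <- lapply(1:9, function(l)
    pheno_dist(track(l), diag(m), 100, level = l))
  # the weak compound traverses the same positions at half speed
  weak <- lapply(1:9, function(l)
    pheno_dist(track(l / 2), diag(m), 100, level = l))
  ti <- structure(list(compound_id = "potent", distributions = potent,
                       control = d0), class = "pheno_trajectory")
  tj <- structure(list(compound_id = "weak", distributions = weak,
                       control = d0), class = "pheno_trajectory")
  shifted <- mswo(ti, tj)
  # far larger than the naive consecutive-alignment score
  W <- phenotrack:::overlap_matrix(ti, tj)
  diag_score <- sum((100 + 100) * diag(W)) / (9 * 200)
  expect_gt(shifted, 2 * diag_score)
  # and the optimum uses a non-consecutive subsequence: the best fixed
  # diagonal-band alignment (every offset) is also beaten
  offsets <- sapply(-8:8, function(o) {
    ks <- (1:9)[(1:9) + o >= 1 & (1:9) + o <= 9]
    sum((100 + 100) * W[cbind(ks, ks + o)]) / (9 * 200)
  })
  expect_gt(shifted, max(offsets) + 1e-6)
})

test_that("phenotypic activity matches its closed form and is monotone", {
  m <- 2
  d0 <- pheno_dist(rep(0, m), diag(m), 1000)
  mk <- function(mu1, mu2, n = c(100, 100)) {
    structure(list(compound_id = "x",
                   distributions = list(
                     pheno_dist(rep(mu1, m), diag(m), n[1], level = 1),
                     pheno_dist(rep(mu2, m), diag(m), n[2], level = 2)),
                   control = d0), class = "pheno_trajectory")
  }
  # identical-to-control at level 1 (O = 1), O = 0.2 at level 2:
  # A_P = (100*0 + 100*0.8) / 200 = 0.4
  o2 <- 0.2
  mu2 <- sqrt(-4 * log(o2) / m)  # invert the equal-covariance overlap
  t <- mk(0, mu2)
  expect_equal(overlap(t$distributions[[2]], d0), o2, tolerance = 1e-12)
  expect_equal(phenotypic_activity(t), 0.4, tolerance = 1e-12)
  # all-control trajectory has activity 0
  expect_equal(phenotypic_activity(mk(0, 0)), 0, tolerance = 1e-12)
  # pushing any level further from control strictly increases activity
  acts <- sapply(seq(0.5, 4, by = 0.5), function(s)
    phenotypic_activity(mk(s, s + 1)))
  expect_true(all(diff(acts) > 0))
})

test_that("similarity matrices are symmetric, bounded and class-structured", {
  scr <- generate_screen(small_config(seed = 17))
  res <- analyze_screen(scr$cells,
                        spec = screen_transform_spec(screen_features(10)),
                        dims = 6, drop_top_level = FALSE)
  S <- res$sim
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(S, t(S))
  expect_false(anyNA(S))
  # duplicated trajectory: off-diagonal equals the self-similarity
  ts <- res$trajectories
  ts$trajectories[["copy"]] <- ts$trajectories[[1]]
  S2 <- similarity_matrix(ts)
  expect_equal(S2[1, "copy"], S2[1, 1], tolerance = 1e-12)
  # within-class similarity exceeds between-class for active classes
  truth <- setNames(scr$truth$true_class, scr$truth$compound_id)
  expect_gt(intra_inter_ratio(S, truth), 1)
})

test_that("degenerate levels depress similarity but keep their counts", {
  m <- 2
  d0 <- pheno_dist(rep(0, m), diag(m), 1000)
  mk <- function(degenerate_top) {
    dists <- list(
      pheno_dist(rep(8, m), diag(m), 100, level = 1),
      pheno_dist(rep(10, m), diag(m), 100, level = 2,
                 degenerate = degenerate_top))
    structure(list(compound_id = "x", distributions = dists, control = d0),
              class = "pheno_trajectory")
  }
  full <- mswo(mk(FALSE), mk(FALSE))
  cut <- mswo(mk(FALSE), mk(TRUE))
  expect_lt(cut, full)
  # the degenerate level's cells still sit in the denominator: matching only
  # level 1 of each (200 * OW) over total 400 cells = OW / 2
  expect_equal(cut, weighted_overlap(mk(FALSE)$distributions[[1]],
                                     mk(FALSE)$distributions[[1]], d0) / 2,
               tolerance = 1e-12)
})
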