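# exemplar selection, class scoring, MAP threshold, LOOCV classification

toy_setup <- function() {
  # 2 strong classes of 5, one weak class of 4, 3 unclassified
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5), sprintf("w%d", 1:4),
           sprintf("u%d", 1:3))
  classes <- setNames(c(rep("alpha", 5), rep("beta", 5), rep("weak", 4),
                        rep("Unspecified", 3)), ids)
  act <- setNames(c(runif(5, 0.6, 0.9), runif(5, 0.5, 0.8),
                    runif(4, 0.05, 0.2), runif(3, 0.3, 0.6)), ids)
  n <- length(ids)
  S <- matrix(runif(n * n, 0, 0.05), n, n, dimnames = list(ids, ids))
  S <- (S + t(S)) / 2
  for (cls in c("alpha", "beta")) {
    members <- ids[classes == cls]
    S[members, members] <- S[members, members] + 0.6
  }
  diag(S) <- pmin(S[cbind(1:n, 1:n)] + 0.3, 1)
  list(ids = ids, classes = classes, act = act, sim = pmin(S, 1))
}

test_that("exemplar selection enforces the activity and size rules", {
  set.seed(1)
  s <- toy_setup()
  ex <- select_exemplars(s$act, s$classes, pa_threshold = 0.4,
                         min_members = 4)
  expect_setequal(names(ex$classes), c("alpha", "beta"))
  expect_setequal(ex$classes$alpha, sprintf("a%d", 1:5))
  # a class with only 3 qualifying members is dropped entirely
  act2 <- s$act
  act2[c("a1", "a2")] <- 0.1
  ex2 <- select_exemplars(act2, s$classes)
  expect_setequal(names(ex2$classes), "beta")
  expect_false("a3" %in% unlist(ex2$classes))
  # raising the threshold never adds classes (monotonicity)
  for (thr in seq(0.1, 0.9, by = 0.2)) {
    lo <- tryCatch(length(select_exemplars(s$act, s$classes,
                                           pa_threshold = thr)$classes),
                   error = function(e) 0)
    hi <- tryCatch(length(select_exemplars(s$act, s$classes,
                                           pa_threshold = thr + 0.1)$classes),
                   error = function(e) 0)
    expect_lte(hi, lo)
  }
  expect_error(select_exemplars(setNames(rep(0, 17), s$ids), s$classes),
               "configuration error")
})

test_that("class similarity is the mean over exemplars, honoring exclusion", {
  set.seed(2)
  s <- toy_setup()
  ex <- select_exemplars(s$act, s$classes)
  sc <- class_similarity("u1", ex, s$sim)
  expect_equal(sc[["alpha"]], mean(s$sim["u1", sprintf("a%d", 1:5)]))
  expect_equal(sc[["beta"]], mean(s$sim["u1", sprintf("b%d", 1:5)]))
  # self-exclusion removes the compound from its own class only
  sc_a1 <- class_similarity("a1", ex, s$sim, exclude_self = TRUE)
  expect_equal(sc_a1[["alpha"]], mean(s$sim["a1", sprintf("a%d", 2:5)]))
  expect_equal(sc_a1[["beta"]], mean(s$sim["a1", sprintf("b%d", 1:5)]))
  # a 1-exemplar class scores the bare pair similarity
  ex1 <- structure(list(classes = list(solo = "u2"), pa_threshold = 0.4,
                        min_members = 1L), class = "exemplar_set")
  expect_equal(class_similarity("u1", ex1, s$sim)[["solo"]],
               s$sim["u1", "u2"])
  expect_warning(class_similarity("u2", ex1, s$sim, exclude_self = TRUE),
                 "empty after self-exclusion")
})

test_that("threshold closed forms match hand algebra", {
  boundary <- phenotrack:::threshold_boundary
  # equal variances at p_c = 0.5: the midpoint
  expect_equal(boundary(-0.5, 0.25, -2, 0.25, 0.5, "printed"),
               -1.25, tolerance = 1e-12)
  # printed simple form: sigma_c = 0.5, sigma_u = 1 ->
  # (0.5 * -2 + 1 * -0.5) / 1.5 = -1
  expect_equal(boundary(-0.5, 0.25, -2, 1, 0.5, "printed"), -1,
               tolerance = 1e-12)
  # equal-variance limit with p_c != 0.5
  mu_c <- -0.5; mu_u <- -2; s2 <- 0.25; pc <- 0.68
  expect_equal(boundary(mu_c, s2, mu_u, s2, pc, "printed"),
               (mu_c + mu_u) / 2 + s2 * log(pc / (1 - pc)) / (mu_c - mu_u),
               tolerance = 1e-12)
})

test_that("the exact threshold matches a bisection oracle; the printed form's
          deviation is the predicted prior/log-variance term", {
  map_gap <- function(x, mu_c, s2_c, mu_u, s2_u, pc)
    pc * dnorm(x, mu_c, sqrt(s2_c)) - (1 - pc) * dnorm(x, mu_u, sqrt(s2_u))
  set.seed(33)
  for (i in 1:20) {
    mu_u <- rnorm(1, -2, 0.5)
    mu_c <- mu_u + runif(1, 1, 3)
    s2_c <- runif(1, 0.2, 1.5)
    s2_u <- runif(1, 0.2, 1.5)
    pc <- runif(1, 0.2, 0.8)
    root <- tryCatch(
      uniroot(map_gap, c(mu_u, mu_c), mu_c = mu_c, s2_c = s2_c,
              mu_u = mu_u, s2_u = s2_u, pc = pc, tol = 1e-13)$root,
      error = function(e) NULL)
    if (is.null(root)) next  # no boundary between the means for this draw
    exact <- phenotrack:::threshold_boundary(mu_c, s2_c, mu_u, s2_u, pc,
                                             "exact")
    expect_equal(exact, root, tolerance = 1e-9)
    # the printed general form solves the same quadratic but with the term
    # log(s2c/s2u * pc/(1-pc)) in place of the exact
    # log(s2c/s2u * ((1-pc)/pc)^2) under the radical: verify against an
    # independent evaluation of that algebra, and bound its deviation from
    # the exact boundary by the radical substitution
    printed <- phenotrack:::threshold_boundary(mu_c, s2_c, mu_u, s2_u, pc,
                                               "printed")
    d_pr <- max((mu_c - mu_u)^2 +
                  (s2_c - s2_u) * log(s2_c / s2_u * pc / (1 - pc)), 0)
    cand_pr <- (s2_c * mu_u - s2_u * mu_c +
                  c(1, -1) * sqrt(s2_c * s2_u * d_pr)) / (s2_c - s2_u)
    expect_lt(min(abs(printed - cand_pr)), 1e-9)
    d_ex <- max((mu_c - mu_u)^2 +
                  (s2_c - s2_u) * log(s2_c / s2_u * ((1 - pc) / pc)^2), 0)
    radical_gap <- sqrt(s2_c * s2_u) * (sqrt(d_pr) + sqrt(d_ex)) /
      abs(s2_c - s2_u)
    expect_lte(abs(printed - exact), radical_gap + 1e-9)
  }
})

test_that("fit_threshold validates its inputs and reports both scales", {
  set.seed(3)
  scores <- setNames(c(runif(5, 0.4, 0.8), runif(5, 0.01, 0.1)),
                     sprintf("c%d", 1:10))
  act <- setNames(rep(0.5, 10), names(scores))
  cls <- setNames(rep(c(TRUE, FALSE), each = 5), names(scores))
  m <- fit_threshold(scores, act, cls, p_c = 0.5)
  expect_equal(m$m_t, exp(m$log_m_t))
  expect_gt(m$mu_c, m$mu_u)
  expect_error(fit_threshold(scores[c(1, 6:10)], act, cls),
               "at least 2 compounds")
  same <- setNames(c(rep(0.5, 5), runif(5, 0.01, 0.1)), names(scores))
  expect_error(fit_threshold(same, act, cls), "degenerate")
})

test_that("classification respects the threshold rule and the LOOCV contract", {
  set.seed(4)
  s <- toy_setup()
  res <- classify_all(s$sim, s$act, s$classes, p_c = "auto")
  expect_true(all(res$predicted_class %in%
                    c("alpha", "beta", "Unspecified")))
  # the threshold rule is an exact iff
  expect_identical(res$predicted_class == res$best_match_class,
                   res$normalized_score >= res$m_t)
  # exemplar compounds never see themselves in their own class average
  ex <- select_exemplars(s$act, s$classes)
  for (cmpd in c("a1", "b3")) {
    row <- res[res$compound_id == cmpd, ]
    expect_equal(row$best_match_score,
                 max(class_similarity(cmpd, ex, s$sim,
                                      exclude_self = TRUE)))
  }
  # strong in-class compounds classify correctly; weak class goes nowhere
  strong <- res$expected_class %in% c("alpha", "beta")
  expect_equal(classification_accuracy(res, strong), 1)
  expect_true(all(res$predicted_class[res$expected_class == "weak"] ==
                    "Unspecified"))
})

test_that("comparison metrics are deterministic and cap perfect separation", {
  set.seed(5)
  s <- toy_setup()
  models <- list(m1 = list(sim = s$sim, activities = s$act),
                 m2 = list(sim = s$sim, activities = s$act))
  tab <- comparison_metrics(models, s$classes, p_c = "auto")
  expect_equal(tab$intra_inter_ratio[1], tab$intra_inter_ratio[2])
  expect_equal(tab$accuracy[1], tab$accuracy[2])
  # block-diagonal similarity: infinite ratio sentinel
  ids <- names(s$classes)[s$classes != "Unspecified"]
  B <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (cls in unique(s$classes[ids]))
    B[s$classes[ids] == cls, s$classes[ids] == cls] <- 1
  expect_identical(intra_inter_ratio(B, s$classes[ids]), Inf)
})
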