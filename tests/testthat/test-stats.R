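test_that("Wilcoxon exact p equals sign-assignment enumeration, ties included", {
  # independent oracle: enumerate all 2^m sign assignments directly
  enum_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    m <- length(d)
    W <- sum(r[d > 0])
    mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Wn <- as.vector(signs %*% r)
    mean(abs(Wn - mu) >= abs(W - mu) - 1e-12)
  }
  set.seed(13)
  for (m in c(3, 5, 8, 10, 12)) {
    d <- round(rnorm(m, 0.4, 1), 1)       # rounding forces occasional ties
    if (all(d == 0)) d[1] <- 0.5
    got <- wilcoxon_signed_rank(d, rep(0, m), mode = "exact")
    expect_equal(got$p_value, enum_p(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon matches wilcox.test on tie-free data and textbook cases", {
  g <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))
  expect_equal(g$p_value, 2 / 2^6)          # all positive, m = 6
  expect_equal(g$statistic, 21)

  sym <- wilcoxon_signed_rank(c(1, -1), c(0, 0))
  expect_equal(sym$p_value, 1)

  set.seed(31)
  x <- rnorm(10); y <- x + rnorm(10, 0.8)
  ours <- wilcoxon_signed_rank(y, x, mode = "exact")
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  oursn <- wilcoxon_signed_rank(y, x, mode = "normal_approx")
  refn <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(oursn$p_value, refn$p.value, tolerance = 1e-10)
  # exact and normal approximation agree closely at m = 10
  expect_lt(abs(ours$p_value - oursn$p_value), 0.03)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "all differences")
  # zeros dropped: identical to testing the nonzero pairs alone
  z <- wilcoxon_signed_rank(c(3, 3, 5, 9), c(3, 3, 1, 2))
  expect_equal(z$n_used, 2L)
})

test_that("Poisson regression with robust SEs recovers known rates", {
  # saturated: counts == exposure -> rate 1, intercept 0
  p1 <- poisson_robust(c(10, 20, 30), c(10, 20, 30))
  expect_equal(unname(p1$coefficients), 0, tolerance = 1e-10)

  # two-group simulation with rates 0.2 and 0.6 -> coefficient ~ log 3
  sim <- with_private_seed(41, {
    n <- 300
    grp <- rep(c(0, 1), each = n)
    expo <- rep(400, 2 * n)
    cnt <- stats::rpois(2 * n, expo * ifelse(grp == 1, 0.6, 0.2))
    list(cnt = cnt, expo = expo, grp = grp)
  })
  p2 <- poisson_robust(sim$cnt, sim$expo, design = data.frame(g = sim$grp))
  expect_lt(abs(p2$coefficients[["g"]] - log(3)), 2 * p2$robust_se[["g"]])

  # coefficients other than the intercept are invariant to exposure rescaling
  p3 <- poisson_robust(sim$cnt, sim$expo * 10, design = data.frame(g = sim$grp))
  expect_equal(p3$coefficients[["g"]], p2$coefficients[["g"]], tolerance = 1e-8)
  expect_equal(p3$coefficients[["(Intercept)"]],
               p2$coefficients[["(Intercept)"]] - log(10), tolerance = 1e-8)

  expect_error(poisson_robust(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(poisson_robust(c(1, 2), c(0, 1)), "positive")
})

test_that("cluster-robust sandwich SEs agree with a cluster bootstrap", {
  sim <- with_private_seed(53, {
    ns <- 40
    subj <- rep(seq_len(ns), each = 2)
    meth <- rep(c(0, 1), ns)
    re <- stats::rnorm(ns, 0, 0.3)[subj]     # shared subject effect
    expo <- rep(600, 2 * ns)
    cnt <- stats::rpois(2 * ns, expo * exp(log(0.3) + 0.9 * meth + re))
    list(cnt = cnt, expo = expo, meth = meth, subj = subj)
  })
  fit <- poisson_robust(sim$cnt, sim$expo, design = data.frame(m = sim$meth),
                        cluster = sim$subj)
  boot <- with_private_seed(54, {
    reps <- vapply(1:500, function(b) {
      ids <- sample(unique(sim$subj), replace = TRUE)
      rows <- unlist(lapply(ids, function(i) which(sim$subj == i)))
      f <- poisson_robust(sim$cnt[rows], sim$expo[rows],
                          design = data.frame(m = sim$meth[rows]))
      f$coefficients[["m"]]
    }, numeric(1))
    stats::sd(reps)
  })
  expect_lt(abs(fit$robust_se[["m"]] - boot) / boot, 0.15)
})

test_that("sign-flip permutation flags extremes and is antisymmetric", {
  set.seed(7)
  deltas <- matrix(rnorm(20 * 30, 0, 0.1), 20, 30)
  deltas[, 5] <- abs(deltas[, 5]) + 0.2        # all 20 subjects positive
  deltas[, 9] <- 0                             # degenerate column
  res <- sign_flip_null(deltas, n_perm = 1000, seed = 3)
  expect_true(res$significant_up[5])
  expect_false(res$significant_down[5])
  expect_true(res$degenerate[9])
  expect_false(res$significant_up[9] || res$significant_down[9])
  expect_equal(res$observed[5], 20)

  flipped <- sign_flip_null(-deltas, n_perm = 1000, seed = 3)
  expect_equal(flipped$significant_down, res$significant_up)
  expect_equal(flipped$significant_up, res$significant_down)
  expect_equal(flipped$observed, -res$observed)
})

test_that("sign-flip null is calibrated near the nominal tail level", {
  # at the study cohort size (n = 35 subjects) the signed-count lattice is
  # fine enough for the strict empirical-threshold rule to reject at ~4.5%
  up <- dn <- tot <- 0
  for (d in 1:150) {
    deltas <- with_private_seed(1000 + d, matrix(stats::rnorm(35 * 40), 35, 40))
    r <- sign_flip_null(deltas, n_perm = 1000, seed = d)
    up <- up + sum(r$significant_up)
    dn <- dn + sum(r$significant_down)
    tot <- tot + 40
  }
  expect_gt(up / tot, 0.03); expect_lt(up / tot, 0.07)
  expect_gt(dn / tot, 0.03); expect_lt(dn / tot, 0.07)

  # the caller's RNG state is never consumed
  deltas <- matrix(seq(-1, 1, length.out = 50), 10, 5)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sign_flip_null(deltas, seed = 1))
  expect_equal(rnorm(1), before)
})
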