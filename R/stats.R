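#' Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided test of symmetric location shift between two methods
#' measured on the same subjects. Zero differences are dropped (Wilcoxon's
#' original treatment; `zero = "pratt"` keeps them in the ranking), ties in
#' |difference| receive mid-ranks. The exact two-sided p-value enumerates
#' all 2^m sign assignments of the observed rank vector, which stays valid
#' under ties; the normal approximation uses the tie-corrected variance
#' `sum(r^2)/4` with a 0.5 continuity correction. `"auto"` uses exact
#' enumeration for m <= 12.
#'
#' @param values_a,values_b equal-length numeric vectors (e.g. percent
#'   overlap per subject under two sampling methods).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param zero `"drop"` or `"pratt"`.
#' @return list with `statistic` (W, sum of ranks of positive differences),
#'   `p_value` (two-sided), `n_used` (pairs after zero handling) and `mode`
#'   actually used.
#' @export
wilcoxon_signed_rank <- function(values_a, values_b,
                                 mode = c("auto", "exact", "normal_approx"),
                                 zero = c("drop", "pratt")) {
  mode <- match.arg(mode)
  zero <- match.arg(zero)
  if (length(values_a) != length(values_b)) stop("paired vectors differ in length")
  d <- values_a - values_b
  if (any(!is.finite(d))) stop("differences must be finite")
  if (all(d == 0)) stop("all differences are zero")
  if (zero == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]  # zeros enter the ranking, then leave the statistic
    d <- d[d != 0]
  }
  m <- length(d)
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (mode == "auto") mode <- if (m <= 12L) "exact" else "normal_approx"
  if (mode == "exact") {
    if (m > 16L) stop("exact enumeration limited to m <= 16")
    # all 2^m sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Wnull <- as.vector(signs %*% r)
    p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-12)
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  list(statistic = W, p_value = min(p, 1), n_used = m, mode = mode)
}

#' Poisson regression with robust (sandwich) standard errors
#'
#' Models overlap voxel counts with a log link and `log(exposure)` offset
#' (the reference block's voxel count), so coefficients are log rate ratios
#' of percent overlap. Standard errors come from the sandwich estimator,
#' clustered by subject by default because each subject contributes one
#' observation per method and those are dependent by design; `cluster =
#' NULL` gives plain HC0. The mean model is fit by [stats::glm()]
#' (iteratively reweighted least squares, tight convergence tolerance).
#'
#' @param counts non-negative per-observation overlap voxel counts.
#' @param exposure positive reference voxel counts (the denominator).
#' @param design data.frame of covariates (e.g. a method factor); an
#'   intercept is always included.
#' @param cluster vector of subject ids for cluster-robust SEs, or `NULL`.
#' @return list of class `bb_glm_result` with `coefficients`, `robust_se`,
#'   `z_values`, `p_values`, `n_obs`, `vcov` and the underlying `fit`.
#' @export
poisson_robust <- function(counts, exposure, design = NULL, cluster = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(exposure <= 0)) stop("exposure must be positive")
  dat <- if (is.null(design) || ncol(as.data.frame(design)) == 0)
    data.frame(.counts = counts) else cbind(.counts = counts,
                                            as.data.frame(design))
  form <- if (ncol(dat) == 1L) .counts ~ 1 else
    stats::as.formula(paste(".counts ~", paste(names(dat)[-1], collapse = "+")))
  fit <- stats::glm(form, family = stats::poisson(), data = dat,
                    offset = log(exposure),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) stop("Poisson IRLS did not converge")
  if (fit$rank < length(stats::coef(fit))) stop("rank-deficient design")
  V <- if (is.null(cluster)) sandwich::vcovHC(fit, type = "HC0")
       else sandwich::vcovCL(fit, cluster = cluster, type = "HC0")
  se <- sqrt(diag(V))
  b <- stats::coef(fit)
  z <- b / se
  structure(list(coefficients = b, robust_se = se, z_values = z,
                 p_values = 2 * stats::pnorm(-abs(z)),
                 n_obs = length(counts), vcov = V, fit = fit),
            class = "bb_glm_result")
}

#' @export
print.bb_glm_result <- function(x, ...) {
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                   z = x$z_values, p = x$p_values), digits = 4)
  invisible(x)
}

#' Sign-flip permutation test for paired connectivity differences
#'
#' For an n-subjects x R-regions matrix of within-subject differences
#' (e.g. subject-specific minus reference correlation), tests each region
#' against an empirical null built by randomly negating whole subject rows —
#' the exchangeability implied by swapping the two method labels within a
#' subject, which preserves the dependence across regions. The default
#' per-region statistic is the signed subject count, `#(delta > 0) -
#' #(delta < 0)`; the mean difference is available as an alternative.
#' Thresholds are the empirical `alpha` and `1 - alpha` quantiles of each
#' region's null; a region is flagged up (down) when its observed statistic
#' exceeds (falls below) them strictly. All-zero regions are flagged
#' degenerate and never significant.
#'
#' @param deltas n x R numeric matrix of per-subject differences.
#' @param n_perm number of sign-flip samples (>= 100; 1000 by default).
#' @param alpha per-tail level (default 0.05: top and bottom 5%).
#' @param seed integer seed for the flips (a private RNG stream; the
#'   caller's `.Random.seed` is untouched).
#' @param statistic `"signed_count"` or `"mean"`.
#' @return data.frame with one row per region: `observed`, `lower`, `upper`,
#'   `significant_up`, `significant_down`, `degenerate`.
#' @export
sign_flip_null <- function(deltas, n_perm = 1000L, alpha = 0.05, seed = 1L,
                           statistic = c("signed_count", "mean")) {
  statistic <- match.arg(statistic)
  deltas <- as.matrix(deltas)
  if (any(!is.finite(deltas))) stop("deltas must be finite")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  n <- nrow(deltas); R <- ncol(deltas)
  X <- if (statistic == "signed_count") sign(deltas) else deltas / n
  observed <- colSums(X)
  rng <- local_rng(seed)
  flips <- matrix(ifelse(rng(n_perm * n) < 0.5, -1, 1), n_perm, n)
  null <- flips %*% X  # n_perm x R
  lower <- apply(null, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(null, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  degenerate <- colSums(deltas != 0) == 0L
  data.frame(region = seq_len(R), observed = observed,
             lower = lower, upper = upper,
             significant_up = !degenerate & observed > upper,
             significant_down = !degenerate & observed < lower,
             degenerate = degenerate)
}
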