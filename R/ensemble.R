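#' Analytic least-squares scale between two profiles
#'
#' The scale c minimising sum((I_exp - c I_calc) / sigma)^2 in closed form:
#' c = sum(I_exp I_calc / sigma^2) / sum(I_calc^2 / sigma^2). The calculated
#' profile is first interpolated (linearly in q) onto the experimental grid.
#'
#' @param exp a [saxs_profile] with uncertainties.
#' @param calc a calculated [saxs_profile] covering the experimental range.
#' @return The scale factor.
#' @export
optimal_scale <- function(exp, calc) {
  require_sigma(exp, "optimal_scale")
  ip <- interp_profile(calc, exp)
  Ie <- exp$intensity[ip$idx]; s <- exp$sigma[ip$idx]; Ic <- ip$calc
  den <- sum(Ic^2 / s^2)
  if (den == 0) stop("calculated intensity is identically zero")
  sum(Ie * Ic / s^2) / den
}

#' Reduced chi-square between experimental and calculated profiles
#'
#' chi^2 = 1/(N - 1) * sum((I_exp - c I_calc)^2 / sigma^2) with the analytic
#' scale c from [optimal_scale]; the single fitted scale accounts for the
#' lost degree of freedom. Optionally a constant background is co-fitted
#' (N - 2 degrees of freedom then).
#'
#' @param exp experimental [saxs_profile] with uncertainties.
#' @param calc calculated [saxs_profile].
#' @param fit_constant also fit an additive constant background.
#' @return The reduced chi-square (attributes `scale` and, when fitted,
#'   `constant`).
#' @export
chi2 <- function(exp, calc, fit_constant = FALSE) {
  require_sigma(exp, "chi2")
  ip <- interp_profile(calc, exp)
  Ie <- exp$intensity[ip$idx]; s <- exp$sigma[ip$idx]; Ic <- ip$calc
  N <- length(Ie)
  if (N < 2) stop("need at least 2 overlapping points")
  if (fit_constant) {
    fm <- stats::lm(Ie ~ Ic, weights = 1 / s^2)
    cf <- stats::coef(fm)
    resid <- (Ie - cf[[1]] - cf[[2]] * Ic) / s
    structure(sum(resid^2) / (N - 2), scale = cf[[2]], constant = cf[[1]])
  } else {
    den <- sum(Ic^2 / s^2)
    if (den == 0) stop("calculated intensity is identically zero")
    cc <- sum(Ie * Ic / s^2) / den
    structure(sum(((Ie - cc * Ic) / s)^2) / (N - 1), scale = cc)
  }
}

#' Best single-state model from a pool
#'
#' Scores every pool member by [chi2] against the experimental profile and
#' returns the minimum; ties are broken by the lexicographically lowest
#' identifier so the result is independent of pool ordering.
#'
#' @param exp experimental [saxs_profile] with uncertainties.
#' @param pool named list of calculated [saxs_profile]s (names are the
#'   conformation identifiers).
#' @param fit_constant passed to [chi2].
#' @return A `fit_result` with one member of weight 1, plus a `chi2_table`
#'   element giving every member's score.
#' @export
best_single_state <- function(exp, pool, fit_constant = FALSE) {
  stopifnot(length(pool) >= 1)
  ids <- names(pool)
  if (is.null(ids)) ids <- as.character(seq_along(pool))
  scores <- vapply(pool, function(p) as.numeric(chi2(exp, p, fit_constant)),
                   numeric(1))
  ord <- order(scores, ids)
  best <- ord[1]
  x2 <- chi2(exp, pool[[best]], fit_constant)
  fit_result(member_ids = ids[best], weights = 1,
             scale = attr(x2, "scale"), chi2 = as.numeric(x2),
             n_points = nrow(exp),
             chi2_table = data.frame(id = ids, chi2 = unname(scores)))
}

#' Minimal multi-state ensemble fit
#'
#' Finds the best k-state mixture explaining the experimental curve: for
#' each candidate subset the non-negative weights minimising chi^2 of the
#' weighted intensity sum are solved by non-negative least squares, then
#' normalised to sum to 1 with the overall scale refit analytically. All
#' size-k subsets are enumerated for k <= 2; for k > 2 a greedy forward
#' selection grows the best pair.
#'
#' @param exp experimental [saxs_profile] with uncertainties.
#' @param pool named list of calculated [saxs_profile]s.
#' @param k number of states (default 2).
#' @return A `fit_result` with `k` members, weights summing to 1.
#' @export
multi_state_fit <- function(exp, pool, k = 2) {
  stopifnot(k >= 1, length(pool) >= k)
  ids <- names(pool)
  if (is.null(ids)) ids <- as.character(seq_along(pool))
  require_sigma(exp, "multi_state_fit")
  # interpolate every member once
  mats <- lapply(pool, function(p) {
    ip <- interp_profile(p, exp)
    out <- rep(NA_real_, nrow(exp)); out[ip$idx] <- ip$calc; out
  })
  common <- which(Reduce(`&`, lapply(mats, function(v) !is.na(v))))
  Ie <- exp$intensity[common]; s <- exp$sigma[common]
  B <- vapply(mats, function(v) v[common], numeric(length(common)))
  N <- length(common)

  score_subset <- function(sub) {
    A <- B[, sub, drop = FALSE] / s
    w <- pracma::lsqnonneg(A, Ie / s)$x
    if (sum(w) <= 0) return(list(chi2 = Inf))
    resid <- (Ie / s) - as.numeric(A %*% w)
    list(chi2 = sum(resid^2) / max(1, N - 1), w = w)
  }

  if (k == 1) {
    subsets <- lapply(seq_along(pool), function(i) i)
  } else {
    pairs <- utils::combn(seq_along(pool), 2, simplify = FALSE)
    if (k == 2) subsets <- pairs
    else {
      best_pair <- pairs[[which.min(vapply(pairs,
        function(sb) score_subset(sb)$chi2, numeric(1)))]]
      sub <- best_pair
      while (length(sub) < k) {        # greedy forward growth
        cand <- setdiff(seq_along(pool), sub)
        sc <- vapply(cand, function(j) score_subset(c(sub, j))$chi2,
                     numeric(1))
        sub <- c(sub, cand[which.min(sc)])
      }
      subsets <- list(sub)
    }
  }
  scored <- lapply(subsets, score_subset)
  best <- which.min(vapply(scored, `[[`, numeric(1), "chi2"))
  sub <- subsets[[best]]; sc <- scored[[best]]
  scale <- sum(sc$w)
  fit_result(member_ids = ids[sub], weights = sc$w / scale, scale = scale,
             chi2 = sc$chi2, n_points = N)
}

#' Ensemble fit result
#'
#' @param member_ids conformation identifiers.
#' @param weights non-negative fractions summing to 1.
#' @param scale overall intensity scale.
#' @param chi2 reduced chi-square of the fit.
#' @param n_points number of experimental points used.
#' @param ... further elements stored verbatim (e.g. `chi2_table`).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(member_ids, weights, scale, chi2, n_points, ...) {
  weights <- as.numeric(weights)
  if (any(weights < -1e-9) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (chi2 < 0) stop("chi2 must be non-negative")
  structure(list(member_ids = member_ids, weights = weights, scale = scale,
                 chi2 = chi2, n_points = n_points, ...),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%d-state fit: chi2 = %.3f over %d points (scale %.4g)\n",
              length(x$member_ids), x$chi2, x$n_points, x$scale))
  for (i in seq_along(x$member_ids))
    cat(sprintf("  %s  weight %.3f\n", x$member_ids[i], x$weights[i]))
  invisible(x)
}
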