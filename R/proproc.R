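# Proper binormal (PROPROC) ROC model.
#
# The model takes the conventional binormal latent pair -- nondiseased
# N(0,1), diseased N(a/b, 1/b^2) -- and thresholds its likelihood ratio
# instead of the raw latent score. The resulting ROC curve is "proper":
# its slope is monotone non-increasing and it never hooks below the chance
# line. Parameters follow the (c, d_a) convention:
#   b = (1 + c) / (1 - c),   a = d_a * sqrt(1 + b^2) / sqrt(2),
# with c in (-1, 1) indexing the variance asymmetry and d_a >= 0 the
# separation (c = 0 recovers the equal-variance binormal curve with
# AUC = pnorm(d_a / sqrt(2))).
#
# log LR(x) = log(b) + (1 - b^2) x^2 / 2 + a b x - a^2 / 2 is quadratic in
# x, so every LR threshold v maps to an interval (b > 1) or a pair of tails
# (b < 1) of the latent axis; FPF(v) and TPF(v) are normal-CDF expressions
# of the quadratic's roots, and the curve is traced by sweeping v.

ab_from_cda <- function(cpar, d_a) {
  b <- (1 + cpar) / (1 - cpar)
  list(a = d_a * sqrt(1 + b^2) / sqrt(2), b = b)
}

# FPF and TPF at log-likelihood-ratio threshold v (scalar v).
pp_point <- function(v, cpar, d_a) {
  if (d_a < 1e-12 && abs(cpar) < 1e-12) {
    # chance line: LR constant; convention FPF = TPF swept directly
    p <- pnorm(-v)
    return(c(fpf = p, tpf = p))
  }
  ab <- ab_from_cda(cpar, d_a); a <- ab$a; b <- ab$b
  if (abs(cpar) < 1e-8) { # equal-variance: log LR linear in x
    x0 <- (v + a^2 / 2) / a
    return(c(fpf = pnorm(-x0), tpf = pnorm(a - x0)))
  }
  A <- (1 - b^2) / 2
  C <- log(b) - a^2 / 2 - v
  disc <- (a * b)^2 - 4 * A * C
  if (b > 1) {                      # concave logLR: region between roots
    if (disc <= 0) return(c(fpf = 0, tpf = 0))
    r <- sqrt(disc)
    x1 <- (-a * b + r) / (2 * A)    # A < 0: this is the smaller root
    x2 <- (-a * b - r) / (2 * A)
    lo <- min(x1, x2); hi <- max(x1, x2)
    c(fpf = pnorm(hi) - pnorm(lo),
      tpf = pnorm(b * hi - a) - pnorm(b * lo - a))
  } else {                          # convex logLR: region outside roots
    if (disc <= 0) return(c(fpf = 1, tpf = 1))
    r <- sqrt(disc)
    x1 <- (-a * b - r) / (2 * A)
    x2 <- (-a * b + r) / (2 * A)
    lo <- min(x1, x2); hi <- max(x1, x2)
    c(fpf = pnorm(lo) + pnorm(-hi),
      tpf = pnorm(b * lo - a) + pnorm(-(b * hi - a)))
  }
}

# threshold range over which the curve is swept (outside it FPF saturates)
pp_v_bound <- function(cpar, d_a) {
  ab <- ab_from_cda(cpar, d_a); a <- ab$a; b <- ab$b
  if (abs(cpar) < 1e-8) return(c(-Inf, Inf))
  A <- (1 - b^2) / 2
  v_star <- log(b) - a^2 / 2 - (a * b)^2 / (4 * A)  # logLR at the vertex
  if (b > 1) c(-Inf, v_star) else c(v_star, Inf)
}

# invert FPF(v) = f for the threshold v (FPF is decreasing in v)
pp_v_for_fpf <- function(f, cpar, d_a) {
  if (d_a < 1e-12 && abs(cpar) < 1e-12) return(-qnorm(f))
  ab <- ab_from_cda(cpar, d_a); a <- ab$a; b <- ab$b
  if (abs(cpar) < 1e-8) return(a * (-qnorm(f)) - a^2 / 2)
  bounds <- pp_v_bound(cpar, d_a)
  g <- function(v) pp_point(v, cpar, d_a)[["fpf"]] - f
  if (b > 1) {
    hi <- bounds[2]
    lo <- hi - 1
    step <- 1
    while (g(lo) < 0 && step < 1e7) { step <- step * 2; lo <- hi - step }
  } else {
    lo <- bounds[1]
    hi <- lo + 1
    step <- 1
    while (g(hi) > 0 && step < 1e7) { step <- step * 2; hi <- lo + step }
  }
  uniroot(g, c(lo, hi), tol = 1e-12)$root
}

# vectorized curve evaluation: FPF and TPF at a vector of thresholds v
pp_point_vec <- function(v, cpar, d_a) {
  if (d_a < 1e-12 && abs(cpar) < 1e-12) {
    p <- pnorm(-v)
    return(list(fpf = p, tpf = p))
  }
  ab <- ab_from_cda(cpar, d_a); a <- ab$a; b <- ab$b
  if (abs(cpar) < 1e-8) {
    x0 <- (v + a^2 / 2) / a
    return(list(fpf = pnorm(-x0), tpf = pnorm(a - x0)))
  }
  A <- (1 - b^2) / 2
  C <- log(b) - a^2 / 2 - v
  disc <- (a * b)^2 - 4 * A * C
  r <- sqrt(pmax(disc, 0))
  x1 <- (-a * b + r) / (2 * A)
  x2 <- (-a * b - r) / (2 * A)
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  if (b > 1) {
    fpf <- ifelse(disc <= 0, 0, pnorm(hi) - pnorm(lo))
    tpf <- ifelse(disc <= 0, 0, pnorm(b * hi - a) - pnorm(b * lo - a))
  } else {
    fpf <- ifelse(disc <= 0, 1, pnorm(lo) + pnorm(-hi))
    tpf <- ifelse(disc <= 0, 1, pnorm(b * lo - a) + pnorm(-(b * hi - a)))
  }
  list(fpf = fpf, tpf = tpf)
}

# d FPF / d v along the curve (negative everywhere); used by the Newton
# inversion. Root slopes follow from implicit differentiation of the
# threshold quadratic: dx/dv = 1 / (2 A x + a b).
pp_fpf_deriv <- function(v, cpar, d_a) {
  ab <- ab_from_cda(cpar, d_a); a <- ab$a; b <- ab$b
  A <- (1 - b^2) / 2
  C <- log(b) - a^2 / 2 - v
  disc <- (a * b)^2 - 4 * A * C
  r <- sqrt(pmax(disc, 1e-300))
  x1 <- (-a * b + r) / (2 * A)
  x2 <- (-a * b - r) / (2 * A)
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  s_lo <- 1 / (2 * A * lo + a * b)
  s_hi <- 1 / (2 * A * hi + a * b)
  d <- if (b > 1) dnorm(hi) * s_hi - dnorm(lo) * s_lo
       else dnorm(lo) * s_lo - dnorm(hi) * s_hi
  ifelse(disc <= 0, 0, d)
}

# invert FPF(v) = f for a vector of targets: warm-started Newton with a
# ladder-bracketed bisection fallback
pp_invert <- function(f, cpar, d_a, tol = 1e-12, v0 = NULL) {
  bounds <- pp_v_bound(cpar, d_a)
  ab <- ab_from_cda(cpar, d_a)
  clamp <- function(v) {
    if (ab$b > 1) pmin(v, bounds[2] - 1e-9 * (1 + abs(bounds[2])))
    else pmax(v, bounds[1] + 1e-9 * (1 + abs(bounds[1])))
  }
  if (!is.null(v0) && length(v0) == length(f) && all(is.finite(v0))) {
    v <- clamp(v0)
    for (it in 1:30) {
      g <- pp_point_vec(v, cpar, d_a)$fpf - f
      if (max(abs(g)) < 1e-13) return(v)
      d <- pp_fpf_deriv(v, cpar, d_a)
      if (any(!is.finite(d)) || any(d >= 0)) break
      vn <- clamp(v - g / d)
      if (any(!is.finite(vn))) break
      if (max(abs(vn - v)) < tol * (1 + max(abs(v)))) {
        v <- vn
        g <- pp_point_vec(v, cpar, d_a)$fpf - f
        if (max(abs(g)) < 1e-10) return(v)
        break
      }
      v <- vn
    }
  }
  # bracketed bisection from a geometric threshold ladder
  steps <- 2^seq(-4, 25)
  if (ab$b < 1) {
    v_grid <- c(bounds[1], bounds[1] + steps)  # FPF = 1 at the bound
  } else {
    v_grid <- c(rev(bounds[2] - steps), bounds[2])  # FPF = 0 at the bound
  }
  f_grid <- pp_point_vec(v_grid, cpar, d_a)$fpf
  j <- findInterval(-f, -f_grid)               # last index with f_grid >= f
  j <- pmin(pmax(j, 1L), length(v_grid) - 1L)
  lo <- v_grid[j]; hi <- v_grid[j + 1]
  for (it in 1:100) {
    if (max(hi - lo) <= tol * (1 + max(abs(hi)))) break
    mid <- (lo + hi) / 2
    up <- pp_point_vec(mid, cpar, d_a)$fpf >= f   # root lies above mid
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

# TPF on the proper curve at the given FPF values
pp_tpf_at <- function(fpf, cpar, d_a, tol = 1e-12, v0 = NULL,
                      with_v = FALSE) {
  out <- numeric(length(fpf))
  out[fpf >= 1] <- 1
  inner <- which(fpf > 0 & fpf < 1)
  if (!length(inner)) {
    return(if (with_v) list(tpf = out, v = NULL) else out)
  }
  if (d_a < 1e-12 && abs(cpar) < 1e-12) {      # chance line
    out[inner] <- fpf[inner]
    return(if (with_v) list(tpf = out, v = NULL) else out)
  }
  ab <- ab_from_cda(cpar, d_a)
  if (abs(cpar) < 1e-8) {                      # equal-variance closed form
    out[inner] <- pnorm(ab$a + qnorm(fpf[inner]))
    return(if (with_v) list(tpf = out, v = NULL) else out)
  }
  v <- pp_invert(fpf[inner], cpar, d_a, tol = tol,
                 v0 = if (!is.null(v0) && length(v0) == length(inner)) v0)
  out[inner] <- pp_point_vec(v, cpar, d_a)$tpf
  if (with_v) list(tpf = out, v = v) else out
}

#' Bin case scores into rating categories
#'
#' Bins the continuous LOS case scores at the BI-RADS anchor cutpoints for
#' categorical maximum-likelihood curve fitting. Intervals are half-open,
#' closed on the left (`[21, 41)` etc.); the bottom category additionally
#' absorbs the `-Inf` sentinel of unmarked cases.
#'
#' @param scores A `case_scores` tibble for a single reader, or a numeric
#'   vector of diseased scores (then supply `nondiseased_scores`).
#' @param boundaries Strictly increasing cut values inside (0, 100);
#'   default the BI-RADS anchors `c(21, 41, 61, 81)`.
#' @param nondiseased_scores Numeric vector when `scores` is a vector.
#' @return An object of class `rating_counts`: a tibble with `category`
#'   (1 = least suspicious), `n_diseased`, `n_nondiseased`; attribute
#'   `boundaries`.
#' @export
bin_scores <- function(scores, boundaries = c(21, 41, 61, 81),
                       nondiseased_scores = NULL) {
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0 | boundaries >= 100)) {
    stop_input("`boundaries` must be strictly increasing inside (0, 100).")
  }
  if (is.numeric(scores)) {
    d <- scores; n <- nondiseased_scores
  } else {
    s <- split_scores(scores); d <- s$d; n <- s$n
  }
  if (!length(d) || !length(n)) stop_input("empty score class.")
  K <- length(boundaries) + 1L
  cat_of <- function(x) findInterval(x, boundaries) + 1L  # -Inf -> 1
  out <- tibble(
    category = seq_len(K),
    n_diseased = tabulate(cat_of(d), nbins = K),
    n_nondiseased = tabulate(cat_of(n), nbins = K)
  )
  structure(out, class = c("rating_counts", class(out)),
            boundaries = boundaries)
}

#' Fit the proper binormal ROC model by maximum likelihood
#'
#' Maximizes the multinomial likelihood of categorical rating counts under
#' the proper binormal model. The parameters are optimized on an
#' unconstrained scale (`atanh` for `c`, `log` for `d_a`, ordered softplus
#' increments on the probit-FPF scale for the category cutpoints) with five
#' deterministic starts, since small-sample proper-binormal likelihoods can
#' be multimodal.
#'
#' @param counts A `rating_counts` object from [bin_scores()].
#' @return An object of class `proproc_fit` with elements `c`, `d_a`,
#'   `cutpoints` (tibble: cumulative `fpf` and `tpf` at each fitted
#'   cutpoint, plus the latent log-likelihood-ratio threshold `v`),
#'   `loglik`, `converged`, `reason`, and the input `counts`. Degenerate
#'   data (perfect separation) return a boundary fit flagged
#'   `converged = FALSE` with `reason = "degenerate"`.
#' @export
fit_proproc <- function(counts) {
  n1 <- counts$n_diseased; n0 <- counts$n_nondiseased
  K <- nrow(counts)
  if (sum(n1) == 0 || sum(n0) == 0) stop_input("empty score class.")
  nonempty <- (n1 + n0) > 0
  if (sum(nonempty) < 2) {
    stop_input("need at least 2 non-degenerate rating categories.")
  }
  # perfect separation: every nondiseased case below every diseased case
  hi0 <- max(which(n0 > 0)); lo1 <- min(which(n1 > 0))
  if (hi0 < lo1) {
    emp_f <- rev(cumsum(rev(n0)))[-1] / sum(n0)
    fit <- structure(list(
      c = 0, d_a = PP_DA_MAX,
      cutpoints = cutpoint_table(pmin(pmax(emp_f, 1e-6), 1 - 1e-6), 0, PP_DA_MAX),
      loglik = NA_real_, converged = FALSE, reason = "degenerate",
      counts = counts), class = "proproc_fit")
    return(fit)
  }

  N0 <- sum(n0); N1 <- sum(n1)
  # empirical AUC from the binned data for initialization
  emp_auc <- {
    r <- rank(c(rep(seq_len(K), n1), rep(seq_len(K), n0)), ties.method = "average")
    (sum(r[seq_len(N1)]) - N1 * (N1 + 1) / 2) / (N1 * N0)
  }
  da0 <- max(0.05, sqrt(2) * qnorm(min(max(emp_auc, 0.5 + 1e-4), 0.999)))
  # cumulative FPF above cut k: f_k = P0(category > k), already decreasing
  emp_f <- (rev(cumsum(rev(n0)))[-1]) / N0
  emp_f <- pmin(pmax(emp_f, 1e-4), 1 - 1e-4)
  # enforce strict decrease for the softplus parameterization
  for (k in seq_along(emp_f)[-1]) {
    emp_f[k] <- min(emp_f[k], emp_f[k - 1] - 1e-5)
  }
  emp_f <- pmax(emp_f, 1e-6)
  z0 <- qnorm(1 - emp_f)                          # increasing
  t0 <- c(z0[1], log(pmax(exp(diff(z0)) - 1, 1e-6)))  # inverse softplus

  starts <- list(
    c(atanh(0.0), log(da0), t0),
    c(atanh(0.35), log(da0), t0),
    c(atanh(-0.35), log(da0), t0),
    c(atanh(0.0), log(max(da0 * 1.6, 0.1)), t0),
    c(atanh(0.0), log(max(da0 * 0.6, 0.05)), t0)
  )

  v_cache <- NULL                                 # warm start for inversion
  nll <- function(theta) {
    cpar <- tanh(theta[1])
    d_a <- exp(theta[2])
    # |c| -> 1 is a degenerate (one-class-collapsed) curve; treat as
    # out-of-bounds rather than chasing it through overflow territory
    if (!is.finite(cpar) || !is.finite(d_a) || d_a > PP_DA_MAX ||
        abs(cpar) > 0.995) return(1e10)
    z <- cumsum(c(theta[3], log1p(exp(theta[-(1:2)][-1]))))
    f <- pnorm(-z)                                # decreasing cutpoint FPFs
    res <- pp_tpf_at(f, cpar, d_a, tol = 1e-11, v0 = v_cache, with_v = TRUE)
    R <- res$tpf
    if (!is.null(res$v)) v_cache <<- res$v
    p0 <- -diff(c(1, f, 0))
    p1 <- -diff(c(1, R, 0))
    if (any(!is.finite(p0)) || any(!is.finite(p1))) return(1e10)
    -sum(n0 * log(pmax(p0, 1e-300))) - sum(n1 * log(pmax(p1, 1e-300)))
  }

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, nll, method = "BFGS",
            control = list(maxit = 150, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop_input("proper binormal fit failed from every start.")

  theta <- best$par
  cpar <- tanh(theta[1]); d_a <- exp(theta[2])
  z <- cumsum(c(theta[3], log1p(exp(theta[-(1:2)][-1]))))
  f <- pnorm(-z)
  # finite-difference gradient at the optimum for an honest convergence flag
  g <- vapply(seq_along(theta), function(i) {
    h <- 1e-5 * (1 + abs(theta[i]))
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (nll(tp) - nll(tm)) / (2 * h)
  }, numeric(1))
  gnorm <- sqrt(sum(g^2))
  at_bound <- d_a > PP_DA_MAX * 0.99
  # relative criterion: finite-difference gradient small against the
  # magnitude of the objective
  converged <- best$convergence == 0 &&
    gnorm < 1e-4 * (1 + abs(best$value)) && !at_bound
  structure(list(
    c = cpar, d_a = d_a,
    cutpoints = cutpoint_table(f, cpar, d_a),
    loglik = -best$value, converged = converged,
    reason = if (at_bound) "degenerate" else if (converged) "ok"
             else "no convergence",
    gradient_norm = gnorm,
    counts = counts), class = "proproc_fit")
}

PP_DA_MAX <- 6

cutpoint_table <- function(f, cpar, d_a) {
  tibble(
    cutpoint = seq_along(f),
    fpf = f,
    tpf = pp_tpf_at(f, cpar, d_a),
    v = vapply(f, pp_v_for_fpf, numeric(1), cpar = cpar, d_a = d_a)
  )
}

as_pp_params <- function(fit) {
  if (inherits(fit, "proproc_fit")) {
    list(cpar = fit$c, d_a = fit$d_a)
  } else if (is.list(fit) && all(c("c", "d_a") %in% names(fit))) {
    list(cpar = fit$c, d_a = fit$d_a)
  } else {
    stop_input("`fit` must be a proproc_fit or a list with elements c and d_a.")
  }
}

#' Proper binormal ROC curve
#'
#' Evaluates the fitted curve's TPF at the requested FPF values.
#'
#' @param fit A `proproc_fit`, or a list with elements `c` and `d_a`.
#' @param fpf_grid Numeric vector of FPF values in \[0, 1\].
#' @return A tibble with columns `fpf`, `tpf`.
#' @export
proproc_curve <- function(fit, fpf_grid = seq(0, 1, by = 0.01)) {
  if (any(fpf_grid < 0 | fpf_grid > 1)) stop_input("`fpf_grid` must lie in [0, 1].")
  p <- as_pp_params(fit)
  tibble(fpf = fpf_grid, tpf = pp_tpf_at(fpf_grid, p$cpar, p$d_a))
}

#' Partial area under the fitted ROC curve
#'
#' Integrates the fitted TPF over a false-positive-fraction interval,
#' by default FPF 0-0.2 (specificity 80-100%), the operating range of
#' supplemental ultrasound screening.
#'
#' @param fit A `proproc_fit` (or list with `c`, `d_a`), or -- with
#'   `type = "empirical"` -- a `case_scores` tibble / `afroc_curve`.
#' @param interval FPF interval, default `c(0, 0.2)`.
#' @param type `"fitted"` (integrate the proper binormal curve) or
#'   `"empirical"` (trapezoidal partial area under the empirical curve).
#' @return The partial area, between 0 and `diff(interval)`.
#' @export
pauc <- function(fit, interval = c(0, 0.2), type = c("fitted", "empirical")) {
  type <- match.arg(type)
  if (interval[1] < 0 || interval[2] > 1 || interval[1] >= interval[2]) {
    stop_input("`interval` must be an increasing sub-interval of [0, 1].")
  }
  if (type == "empirical") {
    crv <- if (inherits(fit, "afroc_curve")) fit else afroc_curve(fit)
    return(trapezoid_area(crv$fpf, crv$tpf, interval))
  }
  p <- as_pp_params(fit)
  if (p$d_a < 1e-12 && abs(p$cpar) < 1e-12) {
    return((interval[2]^2 - interval[1]^2) / 2)   # chance line, exactly
  }
  integrate(function(f) pp_tpf_at(f, p$cpar, p$d_a),
            interval[1], interval[2], rel.tol = 1e-10,
            subdivisions = 200L)$value
}

#' Sensitivity at fixed specificity on the fitted curve
#'
#' @param fit A `proproc_fit` or list with `c`, `d_a`.
#' @param specificity Fixed specificity in (0, 1); default 0.90, the
#'   screening operating point.
#' @return TPF at FPF = 1 - specificity.
#' @export
sens_at_spec <- function(fit, specificity = 0.90) {
  if (!is_number(specificity) || specificity <= 0 || specificity >= 1) {
    stop_input("`specificity` must lie strictly between 0 and 1.")
  }
  p <- as_pp_params(fit)
  pp_tpf_at(1 - specificity, p$cpar, p$d_a)
}

#' Analytic area under the proper binormal curve
#'
#' Closed form in terms of the standard bivariate normal CDF:
#' `AUC = pnorm(d_a/sqrt(2)) + 2 * F(-d_a/sqrt(2), 0; rho)` with
#' `rho = -(1 - c^2)/(1 + c^2)`; at `c = 0` this reduces to the
#' equal-variance binormal `pnorm(d_a/sqrt(2))`.
#'
#' @param fit A `proproc_fit` or list with `c`, `d_a`.
#' @return The full AUC in \[0.5, 1\].
#' @export
full_auc <- function(fit) {
  p <- as_pp_params(fit)
  rho <- -(1 - p$cpar^2) / (1 + p$cpar^2)
  pnorm(p$d_a / sqrt(2)) + 2 * bvn_cdf(-p$d_a / sqrt(2), 0, rho)
}

# standard bivariate normal CDF P(Z1 <= h, Z2 <= k), correlation rho,
# via a single numerically quadratured conditioning integral
bvn_cdf <- function(h, k, rho) {
  if (rho <= -1 + 1e-14) return(max(0, pnorm(h) + pnorm(k) - 1))
  if (rho >= 1 - 1e-14) return(pnorm(min(h, k)))
  s <- sqrt(1 - rho^2)
  integrate(function(z) dnorm(z) * pnorm((k - rho * z) / s),
            -Inf, h, rel.tol = 1e-12)$value
}

#' @export
print.proproc_fit <- function(x, ...) {
  cat("Proper binormal ROC fit\n")
  cat(sprintf("  c = %.4f, d_a = %.4f  (loglik %.3f, %s)\n",
              x$c, x$d_a, x$loglik, x$reason))
  cat(sprintf("  AUC = %.4f | pAUC(0-0.2) = %.4f | sens@90%% spec = %.4f\n",
              full_auc(x), pauc(x), sens_at_spec(x)))
  invisible(x)
}

#' @rdname fit_proproc
#' @param x A `proproc_fit`.
#' @param ... Unused.
#' @export
tidy.proproc_fit <- function(x, ...) {
  tibble(term = c("c", "d_a"), estimate = c(x$c, x$d_a))
}

#' @rdname fit_proproc
#' @export
glance.proproc_fit <- function(x, ...) {
  tibble(auc = full_auc(x), pauc = pauc(x), sens_at_spec90 = sens_at_spec(x),
         logLik = x$loglik, converged = x$converged, reason = x$reason)
}
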