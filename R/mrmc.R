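# Multi-reader multi-case significance testing: Dorfman-Berbaum-Metz
# jackknife pseudovalue ANOVA with the Hillis denominator and degrees of
# freedom, comparing the unaided and CAD-validated reading conditions.

#' Jackknife pseudovalues of a figure of merit
#'
#' For a figure of merit `theta` computed on `n` cases, the pseudovalue of
#' case `k` is `n * theta - (n - 1) * theta_minus_k`, where `theta_minus_k`
#' omits case `k`. For the rank-statistic AFROC figure of merit the mean of
#' the pseudovalues equals the full-sample figure of merit exactly.
#'
#' @param scores A `case_scores` tibble for one reader.
#' @param fom_fn Figure-of-merit function taking a `case_scores` tibble and
#'   returning a scalar. The default `NULL` uses a fast closed-form
#'   leave-one-out path for the empirical AFROC figure of merit
#'   ([afroc_fom()]); pass a function (e.g. an empirical partial-area) to
#'   jackknife any other figure of merit.
#' @return A tibble with columns `case_id`, `class`, `pseudovalue`.
#' @export
jackknife_pseudovalues <- function(scores, fom_fn = NULL) {
  d_idx <- which(scores$class == "diseased")
  n_idx <- which(scores$class == "nondiseased")
  if (length(d_idx) < 2 || length(n_idx) < 2) {
    stop_input("jackknife needs at least 2 cases per truth class.")
  }
  n <- nrow(scores)
  if (is.null(fom_fn)) {
    d <- scores$score[d_idx]; nd <- scores$score[n_idx]
    psi <- outer(d, nd, function(a, b) (a > b) + 0.5 * (a == b))
    S <- sum(psi)
    nD <- length(d); nN <- length(nd)
    theta <- S / (nD * nN)
    th_minus <- numeric(n)
    th_minus[d_idx] <- (S - rowSums(psi)) / ((nD - 1) * nN)
    th_minus[n_idx] <- (S - colSums(psi)) / (nD * (nN - 1))
  } else {
    theta <- fom_fn(scores)
    th_minus <- vapply(seq_len(n), function(k) fom_fn(scores[-k, , drop = FALSE]),
                       numeric(1))
  }
  tibble(case_id = scores$case_id, class = scores$class,
         pseudovalue = n * theta - (n - 1) * th_minus)
}

#' DBM jackknife-pseudovalue ANOVA for two reading conditions
#'
#' Three-way mixed-model ANOVA of the case pseudovalues with modality fixed
#' and reader and case random, one observation per
#' modality x reader x case cell. The modality F test uses the Hillis
#' denominator `MS(TR) + max(MS(TC) - MS(TRC), 0)` and the Hillis
#' denominator degrees of freedom; `classic = TRUE` restores the original
#' uncorrected DBM denominator `MS(TR) + MS(TC) - MS(TRC)`. With a single
#' reader the test reduces to a paired jackknife t test on that reader's
#' pseudovalue differences.
#'
#' Confidence intervals are Wald-type on the figure-of-merit scale,
#' truncated to \[0, 1\]; single-modality intervals use the analogous
#' `MS(R) + max(MS(C) - MS(RC), 0)` variance with its Satterthwaite-style
#' degrees of freedom. Negative variance-component estimates are truncated
#' at zero and reported via a message.
#'
#' @param pseudovalues Long tibble with columns `modality` (two levels),
#'   `reader_id`, `case_id`, `pseudovalue`; every cell present exactly once.
#' @param alpha Significance level (default 0.05).
#' @param classic Use the uncorrected DBM denominator (default `FALSE`).
#' @return An object of class `mrmc_result`: list with `pooled` (per-modality
#'   estimate and CI), `readers` (per-reader per-modality estimate and CI),
#'   `difference` (estimate, `se`, CI, `F`, `ndf`, `ddf`, `p`,
#'   `significant`), `reader_tests` (per-reader paired jackknife t tests),
#'   `mean_squares` and `variance_components`.
#' @export
dbm_anova <- function(pseudovalues, alpha = 0.05, classic = FALSE) {
  pv <- as_tibble(pseudovalues)
  mods <- sort(unique(pv$modality))
  if (length(mods) != 2) stop_input("exactly two modalities are required.")
  readers <- sort(unique(pv$reader_id))
  cases <- sort(unique(pv$case_id))
  r <- length(readers); nc <- length(cases)
  if (nc < 3) stop_input("need at least 3 cases.")
  Y <- array(NA_real_, dim = c(2, r, nc))
  idx <- cbind(match(pv$modality, mods), match(pv$reader_id, readers),
               match(pv$case_id, cases))
  Y[idx] <- pv$pseudovalue
  if (anyNA(Y)) stop_input("pseudovalue table is incomplete (missing cells).")

  m_t <- apply(Y, 1, mean); m_r <- apply(Y, 2, mean); m_c <- apply(Y, 3, mean)
  m_tr <- apply(Y, c(1, 2), mean); m_tc <- apply(Y, c(1, 3), mean)
  m_rc <- apply(Y, c(2, 3), mean)
  g <- mean(Y)

  est_tr <- m_tr                      # jackknife FOM estimates per cell
  pooled_est <- rowMeans(est_tr)
  diff_est <- pooled_est[1] - pooled_est[2]

  # per-reader paired jackknife t tests
  reader_tests <- purrr::map_dfr(seq_len(r), function(j) {
    dk <- Y[1, j, ] - Y[2, j, ]
    se <- sd(dk) / sqrt(nc)
    tt <- if (se > 0) mean(dk) / se else 0
    p <- if (se > 0) 2 * pt(-abs(tt), df = nc - 1) else 1
    tibble(reader_id = readers[j], difference = mean(dk), se = se,
           statistic = tt, df = nc - 1, p_value = p)
  })

  per_reader <- purrr::map_dfr(seq_len(2), function(i) {
    purrr::map_dfr(seq_len(r), function(j) {
      se <- sd(Y[i, j, ]) / sqrt(nc)
      hw <- qt(1 - alpha / 2, nc - 1) * se
      tibble(modality = mods[i], reader_id = readers[j],
             estimate = est_tr[i, j],
             ci_lo = max(0, est_tr[i, j] - hw),
             ci_hi = min(1, est_tr[i, j] + hw))
    })
  })

  if (r == 1) {
    tt <- reader_tests
    Fst <- tt$statistic^2; ddf <- nc - 1
    se_diff <- tt$se
    p <- tt$p_value
    ms <- NULL; vc <- NULL
    pooled <- single_modality_ci(Y, mods, r, nc, alpha)
  } else {
    # mean squares of the fully crossed three-way layout
    MS_T <- r * nc * sum((m_t - g)^2) / (2 - 1)
    MS_R <- 2 * nc * sum((m_r - g)^2) / (r - 1)
    MS_C <- 2 * r * sum((m_c - g)^2) / (nc - 1)
    dev_tr <- m_tr - outer(m_t, rep(1, r)) - outer(rep(1, 2), m_r) + g
    MS_TR <- nc * sum(dev_tr^2) / ((2 - 1) * (r - 1))
    dev_tc <- m_tc - outer(m_t, rep(1, nc)) - outer(rep(1, 2), m_c) + g
    MS_TC <- r * sum(dev_tc^2) / ((2 - 1) * (nc - 1))
    dev_rc <- m_rc - outer(m_r, rep(1, nc)) - outer(rep(1, r), m_c) + g
    MS_RC <- 2 * sum(dev_rc^2) / ((r - 1) * (nc - 1))
    resid <- Y
    for (i in 1:2) for (j in 1:r) {
      resid[i, j, ] <- Y[i, j, ] - m_tr[i, j] - m_tc[i, ] - m_rc[j, ] +
        m_t[i] + m_r[j] + m_c - g
    }
    MS_TRC <- sum(resid^2) / ((2 - 1) * (r - 1) * (nc - 1))
    ms <- tibble(term = c("T", "R", "C", "TR", "TC", "RC", "TRC"),
                 mean_square = c(MS_T, MS_R, MS_C, MS_TR, MS_TC, MS_RC, MS_TRC))
    vc <- variance_components(ms, r, nc)

    denom <- if (classic) MS_TR + MS_TC - MS_TRC
             else MS_TR + max(MS_TC - MS_TRC, 0)
    if (denom <= 0) {
      Fst <- if (MS_T <= 0) 0 else Inf
      ddf <- (r - 1)
      p <- if (MS_T <= 0) 1 else 0
      se_diff <- 0
    } else {
      Fst <- MS_T / denom
      ddf <- denom^2 / (MS_TR^2 / ((2 - 1) * (r - 1)))
      p <- stats::pf(Fst, 1, ddf, lower.tail = FALSE)
      se_diff <- sqrt(2 * denom / (r * nc))
    }
    pooled <- single_modality_ci(Y, mods, r, nc, alpha)
  }

  hw <- qt(1 - alpha / 2, ddf) * se_diff
  difference <- tibble(
    estimate = diff_est, se = se_diff,
    ci_lo = diff_est - hw, ci_hi = diff_est + hw,
    F = Fst, ndf = 1, ddf = ddf, p_value = p,
    significant = p < alpha
  )
  structure(list(modalities = mods, pooled = pooled, readers = per_reader,
                 difference = difference, reader_tests = reader_tests,
                 mean_squares = ms, variance_components = vc,
                 alpha = alpha, classic = classic),
            class = "mrmc_result")
}

# per-modality pooled estimate and Wald CI from that modality's own
# reader/case mean squares
single_modality_ci <- function(Y, mods, r, nc, alpha) {
  purrr::map_dfr(1:2, function(i) {
    Yi <- matrix(Y[i, , ], nrow = r)
    est <- mean(Yi)
    if (r == 1) {
      v <- var(Yi[1, ]) / nc
      df <- nc - 1
    } else {
      m_r <- rowMeans(Yi); m_c <- colMeans(Yi); g <- mean(Yi)
      MS_R <- nc * sum((m_r - g)^2) / (r - 1)
      MS_C <- r * sum((m_c - g)^2) / (nc - 1)
      MS_RC <- sum((Yi - outer(m_r, rep(1, nc)) - outer(rep(1, r), m_c) + g)^2) /
        ((r - 1) * (nc - 1))
      num <- MS_R + max(MS_C - MS_RC, 0)
      v <- num / (r * nc)
      df <- num^2 / (MS_R^2 / (r - 1))
    }
    hw <- qt(1 - alpha / 2, df) * sqrt(v)
    tibble(modality = mods[i], estimate = est,
           ci_lo = max(0, est - hw), ci_hi = min(1, est + hw), df = df)
  })
}

variance_components <- function(ms, r, nc) {
  get <- function(tm) ms$mean_square[ms$term == tm]
  raw <- c(
    reader = (get("R") - get("TR") - get("RC") + get("TRC")) / (2 * nc),
    case = (get("C") - get("TC") - get("RC") + get("TRC")) / (2 * r),
    treatment_reader = (get("TR") - get("TRC")) / nc,
    treatment_case = (get("TC") - get("TRC")) / r,
    reader_case = (get("RC") - get("TRC")) / 2,
    error = get("TRC")
  )
  if (any(raw < 0)) {
    inform(sprintf("dbm_anova: variance component(s) %s truncated at zero.",
                   paste(names(raw)[raw < 0], collapse = ", ")))
  }
  tibble(component = names(raw), estimate = pmax(raw, 0), raw = unname(raw))
}

#' @export
print.mrmc_result <- function(x, ...) {
  cat("DBM jackknife-pseudovalue ANOVA (modality fixed; readers, cases random)\n")
  cat(sprintf("  %s vs %s\n", x$modalities[1], x$modalities[2]))
  print(x$pooled)
  d <- x$difference
  cat(sprintf("  difference %.4f (SE %.4f), F(1, %.1f) = %.3f, P = %.4f%s\n",
              d$estimate, d$se, d$ddf, d$F, d$p_value,
              if (d$significant) " *" else ""))
  invisible(x)
}

#' @rdname dbm_anova
#' @param x An `mrmc_result`.
#' @param ... Unused.
#' @export
tidy.mrmc_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pooled, reader_id = "pooled", .before = 1),
    dplyr::mutate(x$readers, reader_id = .data$reader_id)
  ) |>
    dplyr::select("modality", "reader_id", "estimate", "ci_lo", "ci_hi")
}

#' @rdname dbm_anova
#' @export
glance.mrmc_result <- function(x, ...) {
  d <- x$difference
  tibble(difference = d$estimate, se = d$se, F = d$F, ndf = d$ndf,
         ddf = d$ddf, p_value = d$p_value, significant = d$significant)
}

#' Compare unaided and CAD-validated reading across readers and cases
#'
#' Runs the complete study analysis: validates every reader's findings
#' against the CAD marks, builds the two reading conditions (unaided = all
#' findings; CAD-validated = retained findings only), computes per-reader
#' and pooled figures of merit (empirical AFROC AUC; partial AUC over the
#' FPF interval; sensitivity at the fixed specificity -- each with proper
#' binormal fitted counterparts), and tests the modality effect per figure
#' of merit with [dbm_anova()].
#'
#' Point estimates labelled `fitted` come from the proper binormal fit of
#' the anchor-binned scores (NA when a reader's data are degenerate);
#' jackknifing and the DBM test operate on the empirical figures of merit,
#' which are well-defined for every leave-one-out subset.
#'
#' @param study An `abus_study` with findings from two or more readers.
#' @param criterion A [match_criterion()].
#' @param pauc_interval FPF interval for the partial AUC (default
#'   `c(0, 0.2)`).
#' @param specificity Fixed specificity for the sensitivity figure
#'   (default 0.90).
#' @param alpha Significance level (default 0.05).
#' @param boundaries Rating-bin boundaries for curve fitting (default the
#'   BI-RADS anchors).
#' @param nondiseased Nondiseased pool passed to [build_case_scores()].
#' @param positive_birads Positivity threshold for the rejection summary.
#' @return An object of class `study_report`: list with elements
#'   `validation` (the `cad_validation` tibble), `rejections` (the
#'   [summarize_rejections()] output), `workload`
#'   ([double_read_workload()]), `foms` (per-reader per-modality tibble of
#'   empirical and fitted figures of merit), `mrmc` (named list of
#'   `mrmc_result`, one per figure of merit), and `table1` (the
#'   Table-1-style layout: pooled and per-reader estimates, delta SE and P
#'   per figure of merit).
#' @export
analyze_study <- function(study, criterion = match_criterion(),
                          pauc_interval = c(0, 0.2), specificity = 0.90,
                          alpha = 0.05, boundaries = c(21, 41, 61, 81),
                          nondiseased = "non_malignant",
                          positive_birads = 3) {
  readers <- sort(unique(study$findings$reader_id))
  if (length(readers) < 2) stop_input("analyze_study needs at least 2 readers.")
  validation <- validate_findings(study, criterion)
  retained <- dplyr::filter(validation, .data$retained)
  arms <- list(
    unaided = study$findings,
    cad_validated = as_tibble(retained)[names(study$findings)]
  )
  scores <- purrr::map(arms, function(f) {
    build_case_scores(study, findings = f, criterion = criterion,
                      nondiseased = nondiseased)
  })

  emp_pauc <- function(sc) pauc(afroc_curve(sc), interval = pauc_interval,
                                type = "empirical")
  emp_sens <- function(sc) {
    crv <- afroc_curve(sc)
    stats::approx(crv$fpf, crv$tpf, xout = 1 - specificity, ties = max)$y
  }

  foms <- purrr::map_dfr(names(arms), function(arm) {
    purrr::map_dfr(readers, function(rd) {
      sc <- dplyr::filter(scores[[arm]], .data$reader_id == rd)
      fit <- tryCatch(fit_proproc(bin_scores(sc, boundaries)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        fit <- list(c = NA_real_, d_a = NA_real_, converged = FALSE)
      }
      ok <- fit$converged
      tibble(
        modality = arm, reader_id = rd,
        auc_empirical = afroc_fom(sc),
        pauc_empirical = emp_pauc(sc),
        sens_empirical = emp_sens(sc),
        auc_fitted = if (ok) full_auc(fit) else NA_real_,
        pauc_fitted = if (ok) pauc(fit, pauc_interval) else NA_real_,
        sens_fitted = if (ok) sens_at_spec(fit, specificity) else NA_real_,
        fit_c = fit$c, fit_d_a = fit$d_a, fit_converged = ok
      )
    })
  })

  fom_fns <- list(
    auc = NULL,                                   # fast AFROC path
    pauc = emp_pauc,
    sens_at_spec = emp_sens
  )
  mrmc <- purrr::imap(fom_fns, function(fn, kind) {
    pv <- purrr::map_dfr(names(arms), function(arm) {
      purrr::map_dfr(readers, function(rd) {
        sc <- dplyr::filter(scores[[arm]], .data$reader_id == rd)
        dplyr::mutate(jackknife_pseudovalues(sc, fn),
                      modality = arm, reader_id = rd)
      })
    })
    dbm_anova(pv, alpha = alpha)
  })

  table1 <- purrr::imap_dfr(mrmc, function(m, kind) {
    wide <- tidy(m) |>
      tidyr::pivot_wider(names_from = "modality",
                         values_from = c("estimate", "ci_lo", "ci_hi"))
    rp <- dplyr::bind_rows(
      tibble(reader_id = "pooled",
             delta_se = m$difference$se, p_value = m$difference$p_value),
      dplyr::select(m$reader_tests, "reader_id", delta_se = "se",
                    p_value = "p_value")
    )
    dplyr::left_join(wide, rp, by = "reader_id") |>
      dplyr::mutate(fom = kind, .before = 1)
  })

  structure(list(validation = validation,
                 rejections = summarize_rejections(validation, positive_birads),
                 workload = double_read_workload(validation, study,
                                                 positive_birads),
                 scores = scores, foms = foms, mrmc = mrmc, table1 = table1,
                 settings = list(criterion = criterion,
                                 pauc_interval = pauc_interval,
                                 specificity = specificity, alpha = alpha,
                                 boundaries = boundaries,
                                 nondiseased = nondiseased,
                                 positive_birads = positive_birads)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("ABUS CAD-validation study report\n")
  cat(sprintf("  readers: %d | positive findings rejected (mean %%): %.1f\n",
              length(unique(x$validation$reader_id)),
              attr(x$rejections, "summary")$pct_rejected[1]))
  for (kind in names(x$mrmc)) {
    d <- x$mrmc[[kind]]$difference
    po <- x$mrmc[[kind]]$pooled
    cat(sprintf("  %-13s %s %.3f vs %s %.3f | P = %.3f\n", kind,
                po$modality[1], po$estimate[1], po$modality[2], po$estimate[2],
                d$p_value))
  }
  invisible(x)
}

#' @rdname analyze_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) x$table1

#' @rdname analyze_study
#' @export
glance.study_report <- function(x, ...) {
  purrr::imap_dfr(x$mrmc, function(m, kind) {
    dplyr::mutate(glance(m), fom = kind, .before = 1)
  })
}
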