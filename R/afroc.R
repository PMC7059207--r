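# Empirical AFROC figure of merit and curve.
#
# Case-level scoring follows the highest-rated-lesion rule: a malignant
# (diseased) case is scored by the highest LOS among findings that localize
# a malignant lesion -- false-positive findings in malignant cases are
# omitted so that neither reader nor CAD is rewarded while the cancer itself
# is missed or rejected. A non-malignant case is scored by the highest LOS
# among all of its findings. Unmarked cases carry a sentinel (-Inf) ranking
# strictly below every real score; sentinel-sentinel comparisons count as
# ties (0.5).

#' Build case-level score sets from findings
#'
#' Reduces a set of findings (typically one reader's, either all findings or
#' the CAD-retained subset) to one score per case, per reader.
#'
#' @param study An `abus_study` (case truth, lesions, geometry).
#' @param findings A findings tibble (e.g. `study$findings`, or a
#'   `cad_validation` tibble filtered to retained rows). Must contain
#'   `reader_id`, `case_id`, `volume_id`, coordinates and `los`.
#' @param criterion A [match_criterion()]; sets the lesion-localization
#'   radius, kept identical to the CAD-validation radius.
#' @param nondiseased One of `"non_malignant"` (benign and normal cases
#'   pooled, the 90-case pool over which specificity is defined) or
#'   `"normal_only"`.
#' @return A tibble of class `case_scores` with columns `reader_id`,
#'   `case_id`, `class` (`"diseased"`/`"nondiseased"`) and `score` (LOS, or
#'   `-Inf` for unmarked cases); exactly one row per case per reader.
#' @export
build_case_scores <- function(study, findings = study$findings,
                              criterion = match_criterion(),
                              nondiseased = c("non_malignant", "normal_only")) {
  nondiseased <- match.arg(nondiseased)
  f <- as_tibble(findings)
  if (nrow(f) && any(!f$case_id %in% study$cases$case_id)) {
    stop_input("findings reference unknown case(s).")
  }
  cases <- study$cases
  keep_case <- if (nondiseased == "normal_only") {
    cases$label %in% c("malignant", "normal")
  } else rep(TRUE, nrow(cases))
  cases <- cases[keep_case, , drop = FALSE]
  readers <- unique(f$reader_id)
  if (!length(readers)) stop_input("no findings (no readers) supplied.")

  grid <- tidyr::expand_grid(reader_id = readers, case_id = cases$case_id)
  grid <- dplyr::left_join(grid, cases, by = "case_id")

  f <- f[f$case_id %in% cases$case_id, , drop = FALSE]
  lab <- cases$label[match(f$case_id, cases$case_id)]
  # in malignant cases only lesion-localizing findings may score the case
  if (nrow(f)) {
    mal <- which(lab == "malignant")
    if (length(mal)) {
      ids <- localize_findings(f[mal, , drop = FALSE], study, criterion)
      truth <- study$lesions$truth[match(ids, study$lesions$lesion_id)]
      drop_idx <- mal[is.na(ids) | truth != "malignant"]
      if (length(drop_idx)) f <- f[-drop_idx, , drop = FALSE]
    }
  }
  sc <- f |>
    dplyr::group_by(.data$reader_id, .data$case_id) |>
    dplyr::summarise(score = max(.data$los), .groups = "drop")
  out <- grid |>
    dplyr::left_join(sc, by = c("reader_id", "case_id")) |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, -Inf),
                  class = ifelse(.data$label == "malignant",
                                 "diseased", "nondiseased")) |>
    dplyr::select("reader_id", "case_id", "class", "score")
  structure(out, class = c("case_scores", class(out)))
}

split_scores <- function(scores) {
  if (is.data.frame(scores)) {
    list(d = scores$score[scores$class == "diseased"],
         n = scores$score[scores$class == "nondiseased"])
  } else {
    stop_input("`scores` must be a case_scores tibble; use afroc_fom(d, n) for raw vectors.")
  }
}

#' AFROC figure of merit (two-sample rank statistic)
#'
#' The probability that a randomly chosen diseased case outranks a randomly
#' chosen nondiseased case, with ties (including mutual sentinel `-Inf`)
#' counting one half: the Wilcoxon-Mann-Whitney statistic over all
#' (diseased, nondiseased) case pairs, equal to the trapezoidal area under
#' the empirical AFROC curve.
#'
#' @param scores A `case_scores` tibble for a single reader (see
#'   [build_case_scores()]), or a numeric vector of diseased-case scores.
#' @param nondiseased_scores Numeric vector of nondiseased-case scores when
#'   `scores` is a vector.
#' @return The figure of merit in \[0, 1\].
#' @export
#' @examples
#' afroc_fom(c(81, 41, -Inf), c(41, -Inf))
afroc_fom <- function(scores, nondiseased_scores = NULL) {
  if (is.numeric(scores)) {
    d <- scores; n <- nondiseased_scores
  } else {
    s <- split_scores(scores); d <- s$d; n <- s$n
  }
  if (!length(d) || !length(n)) {
    stop_input("need at least one diseased and one nondiseased case score.")
  }
  # midrank formulation: identical to pairwise 1/0.5/0 scoring, O(n log n)
  r <- rank(c(d, n), ties.method = "average")
  (sum(r[seq_along(d)]) - length(d) * (length(d) + 1) / 2) /
    (length(d) * length(n))
}

#' Empirical AFROC curve
#'
#' Sweeps a threshold over the union of observed case scores: each
#' threshold `t` contributes the point (FPF(t), TPF(t)) with
#' FPF = fraction of nondiseased cases scoring `>= t` and TPF = fraction of
#' diseased cases scoring `>= t`; the curve is prepended with (0,0) and
#' appended with (1,1) (the jump to (1,1) absorbs unmarked, sentinel-scored
#' cases). Its trapezoidal area equals [afroc_fom()] exactly.
#'
#' @inheritParams afroc_fom
#' @return An object of class `afroc_curve`: a tibble with columns
#'   `threshold`, `fpf`, `tpf`, plus attribute `fom`.
#' @export
afroc_curve <- function(scores, nondiseased_scores = NULL) {
  if (is.numeric(scores)) {
    d <- scores; n <- nondiseased_scores
  } else {
    s <- split_scores(scores); d <- s$d; n <- s$n
  }
  if (!length(d) || !length(n)) {
    stop_input("need at least one diseased and one nondiseased case score.")
  }
  th <- sort(unique(c(d, n)[is.finite(c(d, n))]), decreasing = TRUE)
  fpf <- vapply(th, function(t) mean(n >= t), numeric(1))
  tpf <- vapply(th, function(t) mean(d >= t), numeric(1))
  curve <- tibble(threshold = c(Inf, th, -Inf),
                  fpf = c(0, fpf, 1), tpf = c(0, tpf, 1))
  structure(curve, class = c("afroc_curve", class(curve)),
            fom = afroc_fom(d, n))
}

#' Trapezoidal area under a curve
#'
#' @param fpf,tpf Coordinates of an operating-point curve, ordered by `fpf`.
#' @param interval Optional FPF sub-interval `c(lo, hi)`; the curve is
#'   linearly interpolated at the interval ends (partial area).
#' @return The (partial) area.
#' @export
trapezoid_area <- function(fpf, tpf, interval = c(0, 1)) {
  if (interval[1] > 0 || interval[2] < 1) {
    lo <- stats::approx(fpf, tpf, xout = interval[1], ties = max)$y
    hi <- stats::approx(fpf, tpf, xout = interval[2], ties = max)$y
    keep <- fpf > interval[1] & fpf < interval[2]
    fpf <- c(interval[1], fpf[keep], interval[2])
    tpf <- c(lo, tpf[keep], hi)
  }
  sum(diff(fpf) * (head(tpf, -1) + tail(tpf, -1)) / 2)
}

#' Per-reader AFROC figures of merit
#'
#' Groups a multi-reader `case_scores` tibble and computes the empirical
#' figure of merit for each reader.
#'
#' @param scores A `case_scores` tibble covering one or more readers.
#' @return A tibble with columns `reader_id`, `fom`.
#' @export
reader_foms <- function(scores) {
  scores |>
    dplyr::group_by(.data$reader_id) |>
    dplyr::summarise(fom = afroc_fom(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
}
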