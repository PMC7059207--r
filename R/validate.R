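# CAD validation of reader findings: matching, rejection causes,
# truth classification and Table-2-style summaries.

#' Matching criterion for reader-marker / CAD-region correspondence
#'
#' A reader finding is validated when a CAD region lies within
#' `max_distance` mm spherical (Euclidean) distance of the marker, by
#' default within the same ABUS volume. The boundary is inclusive: a pair at
#' exactly `max_distance` matches.
#'
#' @param max_distance Maximum marker-to-region distance in mm (default 10).
#' @param same_volume_required Must the CAD region lie in the same volume as
#'   the marker (default `TRUE`)? When `FALSE`, coordinates are compared
#'   across the per-volume frames as-is, which is only meaningful for
#'   sensitivity analyses.
#' @return An object of class `match_criterion`.
#' @export
match_criterion <- function(max_distance = 10, same_volume_required = TRUE) {
  if (!is_number(max_distance) || max_distance <= 0) {
    stop_input("`max_distance` must be a positive number (mm).")
  }
  structure(list(max_distance = max_distance,
                 same_volume_required = isTRUE(same_volume_required)),
            class = "match_criterion")
}

# localization radius used to decide whether a marker "points at" a lesion:
# half the lesion diameter, but never tighter than the match distance, so
# markers inside large tumors still localize them.
localization_radius <- function(diameter_mm, criterion = match_criterion()) {
  pmax(diameter_mm / 2, criterion$max_distance)
}

#' Match one reader finding against a set of CAD marks
#'
#' @param finding One-row data frame (or list) with `case_id`, `volume_id`,
#'   `x_mm`, `y_mm`, `z_mm`.
#' @param cad_marks Tibble of CAD marks (may be empty).
#' @param criterion A [match_criterion()].
#' @return A list with `matched` (logical), `best_mark` (one-row tibble or
#'   `NULL`) and `distance` (mm to the nearest qualifying mark, `NA` if
#'   unmatched). Ties between equidistant qualifying marks break to the
#'   lowest `volume_id`, then lowest row index.
#' @export
#' @examples
#' m <- tibble::tibble(case_id = "c1", volume_id = "v1",
#'                     x_mm = 6, y_mm = 8, z_mm = 0)
#' f <- list(case_id = "c1", volume_id = "v1", x_mm = 0, y_mm = 0, z_mm = 0)
#' match_finding(f, m)$distance # exactly 10: matched (inclusive boundary)
match_finding <- function(finding, cad_marks, criterion = match_criterion()) {
  cand <- cad_marks[cad_marks$case_id == finding$case_id, , drop = FALSE]
  if (criterion$same_volume_required) {
    cand <- cand[cand$volume_id == finding$volume_id, , drop = FALSE]
  }
  if (!nrow(cand)) {
    return(list(matched = FALSE, best_mark = NULL, distance = NA_real_))
  }
  d <- spherical_distance(
    c(finding$x_mm, finding$y_mm, finding$z_mm),
    cand[, c("x_mm", "y_mm", "z_mm")]
  )
  ok <- d <= criterion$max_distance
  if (!any(ok)) {
    return(list(matched = FALSE, best_mark = NULL, distance = NA_real_))
  }
  qual <- which(ok)
  best <- qual[order(d[qual], cand$volume_id[qual], qual)][1]
  list(matched = TRUE, best_mark = cand[best, , drop = FALSE],
       distance = d[best])
}

#' Classify a rejected finding against case truth
#'
#' A rejected finding pointing at (within the localization radius of) a
#' malignant lesion is a missed cancer (`malignant_FN`); one pointing at a
#' benign lesion is a correctly discarded benign (`benign_TN`); anything
#' else is normal tissue or artefact (`normal_tissue_artefact_TN`).
#'
#' @param finding One-row data frame or list with `case_id`, `volume_id` and
#'   coordinates.
#' @param study An `abus_study` (supplies lesions and their per-volume
#'   centers).
#' @param criterion A [match_criterion()] (sets the localization radius
#'   floor).
#' @return One of `"malignant_FN"`, `"benign_TN"`,
#'   `"normal_tissue_artefact_TN"`.
#' @export
classify_rejection <- function(finding, study, criterion = match_criterion()) {
  les <- localized_lesion(finding, study, criterion)
  if (is.null(les)) return("normal_tissue_artefact_TN")
  if (les$truth == "malignant") "malignant_FN" else "benign_TN"
}

# Vectorized localization: for each finding row, the lesion_id of the
# lesion it points at (center in the same volume within the localization
# radius), or NA. Malignant lesions take precedence, then distance.
localize_findings <- function(f, study, criterion = match_criterion()) {
  if (!nrow(f)) return(character(0))
  f2 <- dplyr::mutate(
    as_tibble(f)[, c("case_id", "volume_id", "x_mm", "y_mm", "z_mm")],
    .row = dplyr::row_number())
  locs <- dplyr::inner_join(
    study$lesion_locations,
    study$lesions[, c("lesion_id", "case_id", "truth", "diameter_mm")],
    by = "lesion_id")
  j <- dplyr::inner_join(f2, locs, by = "volume_id", suffix = c("", ".les"),
                         relationship = "many-to-many")
  j <- j[j$case_id == j$case_id.les, , drop = FALSE]
  if (nrow(j)) {
    d <- sqrt((j$x_mm - j$x_mm.les)^2 + (j$y_mm - j$y_mm.les)^2 +
                (j$z_mm - j$z_mm.les)^2)
    keep <- d <= localization_radius(j$diameter_mm, criterion)
    j <- j[keep, , drop = FALSE]; j$d <- d[keep]
  }
  out <- rep(NA_character_, nrow(f))
  if (nrow(j)) {
    j <- j[order(j$.row, j$truth != "malignant", j$d), , drop = FALSE]
    j <- j[!duplicated(j$.row), , drop = FALSE]
    out[j$.row] <- j$lesion_id
  }
  out
}

# nearest lesion (by center distance relative to localization radius) whose
# center in the finding's volume lies within the localization radius;
# malignant lesions take precedence over benign at equal eligibility.
localized_lesion <- function(finding, study, criterion = match_criterion()) {
  locs <- study$lesion_locations
  locs <- locs[locs$volume_id == finding$volume_id, , drop = FALSE]
  if (!nrow(locs)) return(NULL)
  les <- study$lesions[match(locs$lesion_id, study$lesions$lesion_id), ,
                       drop = FALSE]
  keep <- les$case_id == finding$case_id
  locs <- locs[keep, , drop = FALSE]; les <- les[keep, , drop = FALSE]
  if (!nrow(locs)) return(NULL)
  d <- spherical_distance(c(finding$x_mm, finding$y_mm, finding$z_mm),
                          locs[, c("x_mm", "y_mm", "z_mm")])
  r <- localization_radius(les$diameter_mm, criterion)
  ok <- d <= r
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  cand <- cand[order(les$truth[cand] != "malignant", d[cand])]
  les[cand[1], , drop = FALSE]
}

#' Diagnose why a rejected finding failed CAD validation
#'
#' Reproduces the rejection taxonomy observed for missed cancers:
#' * `no_cad_in_case`: the case carries no CAD marks at all.
#' * `distance_exceeded`: CAD marked the lesion in the finding's volume, but
#'   the mark lies beyond the match distance from the reader marker (large
#'   tumors whose extent exceeds the criterion).
#' * `wrong_volume`: the lesion is visible in several volumes and CAD marked
#'   it only in a volume other than the one the reader annotated.
#' * `cad_total_miss`: no CAD mark lies near the lesion in any volume.
#'
#' For findings that do not localize any lesion, a same-volume mark beyond
#' the match distance is reported as `distance_exceeded`, otherwise
#' `cad_total_miss`.
#'
#' @param finding One-row data frame or list with identifiers and
#'   coordinates.
#' @param study An `abus_study`.
#' @param criterion A [match_criterion()].
#' @return One of `"no_cad_in_case"`, `"distance_exceeded"`,
#'   `"wrong_volume"`, `"cad_total_miss"`.
#' @export
diagnose_cause <- function(finding, study, criterion = match_criterion()) {
  diagnose_cause_impl(finding, study, criterion,
                      localized_lesion(finding, study, criterion))
}

diagnose_cause_impl <- function(finding, study, criterion, les) {
  marks <- study$cad_marks[study$cad_marks$case_id == finding$case_id, ,
                           drop = FALSE]
  if (!nrow(marks)) return("no_cad_in_case")
  if (is.null(les)) {
    same_vol <- marks$volume_id == finding$volume_id
    return(if (any(same_vol)) "distance_exceeded" else "cad_total_miss")
  }
  # marks near the lesion center in each volume where the lesion is visible
  locs <- study$lesion_locations
  locs <- locs[locs$lesion_id == les$lesion_id, , drop = FALSE]
  r <- localization_radius(les$diameter_mm, criterion)
  near <- purrr::map_lgl(seq_len(nrow(marks)), function(i) {
    l <- locs[locs$volume_id == marks$volume_id[i], , drop = FALSE]
    nrow(l) > 0 &&
      spherical_distance(as.numeric(marks[i, c("x_mm", "y_mm", "z_mm")]),
                         l[1, c("x_mm", "y_mm", "z_mm")]) <= r
  })
  if (any(near & marks$volume_id == finding$volume_id)) return("distance_exceeded")
  if (any(near & marks$volume_id != finding$volume_id)) return("wrong_volume")
  "cad_total_miss"
}

#' Validate every reader finding against the CAD marks
#'
#' The central operation of the CAD-validation reading paradigm: a reader
#' finding is retained (considered positive) only when a CAD region matches
#' it under the criterion; every other finding is rejected and annotated
#' with a rejection cause and a truth classification. Retained and rejected
#' rows partition the input exactly.
#'
#' @param study An `abus_study` whose `findings` and `cad_marks` tables are
#'   used. Alternatively pass a findings tibble via `findings` to validate a
#'   subset.
#' @param criterion A [match_criterion()].
#' @param findings Optional findings tibble overriding `study$findings`.
#' @param classify Annotate rejected rows with `cause` and `truth_class`
#'   (default `TRUE`); disable when only the retained/rejected split is
#'   needed, e.g. in large replicate loops.
#' @return A tibble of class `cad_validation`: the findings with added
#'   columns `retained` (logical), `match_distance` (mm, `NA` when
#'   rejected), `cause` and `truth_class` (`NA` for retained rows).
#' @export
validate_findings <- function(study, criterion = match_criterion(),
                              findings = NULL, classify = TRUE) {
  f <- if (is.null(findings)) study$findings else as_tibble(findings)
  if (nrow(f) && any(!f$case_id %in% study$cases$case_id)) {
    stop_input(sprintf("findings reference unknown case(s): %s",
                       paste(head(setdiff(f$case_id, study$cases$case_id), 3),
                             collapse = ", ")))
  }
  out <- dplyr::mutate(f, retained = FALSE, match_distance = NA_real_,
                       cause = NA_character_, truth_class = NA_character_)
  if (!nrow(f)) return(structure(out, class = c("cad_validation", class(out))))

  marks <- study$cad_marks
  # vectorized matching: join findings to same-case (and same-volume) marks
  key <- if (criterion$same_volume_required) c("case_id", "volume_id") else "case_id"
  mk <- dplyr::mutate(marks, .mark = dplyr::row_number())
  j <- dplyr::inner_join(
    dplyr::mutate(out[, c(key, "x_mm", "y_mm", "z_mm")], .finding = dplyr::row_number()),
    mk, by = key, suffix = c("", ".mark"), relationship = "many-to-many"
  )
  if (nrow(j)) {
    j$d <- sqrt((j$x_mm - j$x_mm.mark)^2 + (j$y_mm - j$y_mm.mark)^2 +
                  (j$z_mm - j$z_mm.mark)^2)
    j <- j[j$d <= criterion$max_distance, , drop = FALSE]
  }
  if (nrow(j)) {
    vol_col <- if (criterion$same_volume_required) j$volume_id else j$volume_id.mark
    best <- j[order(j$.finding, j$d, vol_col, j$.mark), , drop = FALSE]
    best <- best[!duplicated(best$.finding), , drop = FALSE]
    out$retained[best$.finding] <- TRUE
    out$match_distance[best$.finding] <- best$d
  }
  rej <- which(!out$retained)
  if (length(rej) && classify) {
    loc_ids <- localize_findings(out[rej, , drop = FALSE], study, criterion)
    les_rows <- match(loc_ids, study$lesions$lesion_id)
    truth <- study$lesions$truth[les_rows]
    out$truth_class[rej] <- dplyr::case_when(
      is.na(loc_ids) ~ "normal_tissue_artefact_TN",
      truth == "malignant" ~ "malignant_FN",
      TRUE ~ "benign_TN"
    )
    for (k in seq_along(rej)) {
      i <- rej[k]
      les <- if (is.na(loc_ids[k])) NULL
             else study$lesions[les_rows[k], , drop = FALSE]
      out$cause[i] <- diagnose_cause_impl(out[i, , drop = FALSE], study,
                                          criterion, les)
    }
  }
  structure(out, class = c("cad_validation", class(out)))
}

#' Validate a single reader's session
#'
#' Convenience wrapper around [validate_findings()] for one reader.
#'
#' @param study An `abus_study`.
#' @param reader_id Reader identifier present in `study$findings`.
#' @param criterion A [match_criterion()].
#' @return A `cad_validation` tibble for that reader's findings.
#' @export
validate_session <- function(study, reader_id, criterion = match_criterion()) {
  f <- study$findings[study$findings$reader_id == reader_id, , drop = FALSE]
  validate_findings(study, criterion, findings = f)
}

#' Summarize CAD-rejected findings per reader
#'
#' Builds the per-reader rejection summary of the study report: among each
#' reader's positive findings (BI-RADS at or above `positive_birads`), the
#' number and percentage rejected by CAD validation; among the rejections,
#' the percentage breakdown by consensus truth class (normal
#' tissue/artefact, benign lesion, malignant lesion) and by BI-RADS
#' category. Percentages are averaged across readers with an unweighted
#' arithmetic mean; readers with an undefined percentage (zero denominator)
#' are excluded from that mean and flagged in the `excluded` attribute.
#'
#' @param validation A `cad_validation` tibble from [validate_findings()]
#'   covering one or more readers.
#' @param positive_birads Threshold defining a positive finding
#'   (default 3).
#' @return A tibble of class `rejection_summary`, one row per reader, with
#'   count and percentage columns; attribute `summary` holds the
#'   across-reader mean / min / max of each percentage (rounded to one
#'   decimal, half away from zero, in the printed columns; full precision in
#'   the `*_raw` columns).
#' @export
summarize_rejections <- function(validation, positive_birads = 3) {
  pos <- dplyr::filter(validation, .data$birads >= positive_birads)
  per <- pos |>
    dplyr::group_by(.data$reader_id) |>
    dplyr::summarise(
      n_positive = dplyr::n(),
      n_rejected = sum(!.data$retained),
      n_normal = sum(!.data$retained &
                       .data$truth_class == "normal_tissue_artefact_TN"),
      n_benign = sum(!.data$retained & .data$truth_class == "benign_TN"),
      n_malignant = sum(!.data$retained & .data$truth_class == "malignant_FN"),
      n_birads3 = sum(!.data$retained & .data$birads == 3L),
      n_birads4 = sum(!.data$retained & .data$birads == 4L),
      n_birads5 = sum(!.data$retained & .data$birads == 5L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_rejected = pct_of(.data$n_rejected, .data$n_positive),
      pct_normal = pct_of(.data$n_normal, .data$n_rejected),
      pct_benign = pct_of(.data$n_benign, .data$n_rejected),
      pct_malignant = pct_of(.data$n_malignant, .data$n_rejected),
      pct_birads3 = pct_of(.data$n_birads3, .data$n_rejected),
      pct_birads4 = pct_of(.data$n_birads4, .data$n_rejected),
      pct_birads5 = pct_of(.data$n_birads5, .data$n_rejected)
    )
  pct_cols <- grep("^pct_", names(per), value = TRUE)
  excluded <- per$reader_id[rowSums(is.na(per[pct_cols])) > 0]
  if (length(excluded)) {
    inform(sprintf(
      "summarize_rejections: reader(s) %s have undefined percentages (zero denominator); excluded from the across-reader means.",
      paste(excluded, collapse = ", ")))
  }
  summ <- purrr::map_dfr(c(mean = "mean", min = "min", max = "max"),
    function(fn) {
      vapply(per[pct_cols], function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_real_)
        switch(fn, mean = mean(v), min = min(v), max = max(v))
      }, numeric(1))
    }, .id = "statistic")
  summ <- dplyr::bind_cols(
    summ["statistic"],
    setNames(as.data.frame(round_half_up(as.matrix(summ[pct_cols]), 1)), pct_cols),
    setNames(as.data.frame(as.matrix(summ[pct_cols])), paste0(pct_cols, "_raw"))
  )
  structure(per, class = c("rejection_summary", class(per)),
            summary = as_tibble(summ), excluded = excluded,
            positive_birads = positive_birads)
}

#' @export
print.rejection_summary <- function(x, ...) {
  cat(sprintf("CAD-rejected findings (BI-RADS >= %d) per reader\n",
              attr(x, "positive_birads")))
  NextMethod()
  cat("\nAcross-reader percentages (mean / min / max):\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' Fraction of cases needing a second read under CAD-validated double reading
#'
#' In the double-reading workflow, the second reader only reviews
#' discordant cases: those in which the first reader reported at least one
#' positive finding that CAD did not validate. Cases whose positive findings
#' are all validated, and cases without positive findings, skip the second
#' read.
#'
#' @param validation A `cad_validation` tibble (one or more readers).
#' @param study The `abus_study` supplying the case list.
#' @param positive_birads Positivity threshold (default 3).
#' @return A tibble with one row per reader: `n_cases`, `n_discordant` and
#'   `fraction` (of all study cases needing a second read); attribute
#'   `mean_fraction` averages over readers.
#' @export
double_read_workload <- function(validation, study, positive_birads = 3) {
  n_cases <- nrow(study$cases)
  readers <- unique(validation$reader_id)
  out <- validation |>
    dplyr::filter(.data$birads >= positive_birads, !.data$retained) |>
    dplyr::distinct(.data$reader_id, .data$case_id) |>
    dplyr::count(.data$reader_id, name = "n_discordant") |>
    dplyr::right_join(tibble(reader_id = readers), by = "reader_id") |>
    dplyr::mutate(n_discordant = dplyr::coalesce(.data$n_discordant, 0L),
                  n_cases = n_cases,
                  fraction = .data$n_discordant / n_cases) |>
    dplyr::select("reader_id", "n_cases", "n_discordant", "fraction") |>
    dplyr::arrange(.data$reader_id)
  structure(out, mean_fraction = mean(out$fraction))
}
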