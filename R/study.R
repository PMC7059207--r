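# Study container: cases, volumes, lesions, reader findings, CAD marks.
#
# All coordinates are physical millimetres in a per-volume frame with the
# origin at one corner of the volume bounding box. Matching and localization
# are only defined within a volume, so no cross-volume registration exists.

SCHEMA_VERSION <- 1L

#' BI-RADS anchor scale for level-of-suspiciousness scores
#'
#' Readers rate findings on a continuous level-of-suspiciousness (LOS) scale
#' of 0-100 anchored to BI-RADS assessment categories: 21, 41, 61 and 81 for
#' BI-RADS 2, 3, 4 and 5. The anchors partition the LOS range into
#' half-open intervals `[0,21) -> 1`, `[21,41) -> 2`, `[41,61) -> 3`,
#' `[61,81) -> 4`, `[81,100] -> 5` used to derive a BI-RADS category from a
#' LOS score.
#'
#' @param anchors Named numeric vector mapping BI-RADS category (names
#'   `"2"`..`"5"`) to the anchor LOS value. Must be strictly increasing and
#'   inside (0, 100).
#' @return An object of class `anchor_scale`.
#' @export
#' @examples
#' sc <- anchor_scale()
#' los_to_birads(c(0, 21, 40.9, 41, 81, 100), sc)
anchor_scale <- function(anchors = c(`2` = 21, `3` = 41, `4` = 61, `5` = 81)) {
  if (length(anchors) != 4L || is.null(names(anchors)) ||
      !identical(names(anchors), as.character(2:5))) {
    stop_input("`anchors` must be a numeric vector named \"2\"..\"5\".")
  }
  if (any(diff(anchors) <= 0) || any(anchors <= 0) || any(anchors >= 100)) {
    stop_input("anchor values must be strictly increasing and inside (0, 100).")
  }
  structure(list(anchors = anchors), class = "anchor_scale")
}

#' Map LOS scores to BI-RADS categories
#'
#' @param los Numeric vector of LOS scores in \[0, 100\].
#' @param scale An [anchor_scale()].
#' @return Integer vector of BI-RADS categories in 1..5.
#' @export
los_to_birads <- function(los, scale = anchor_scale()) {
  if (any(!is.finite(los)) || any(los < 0 | los > 100)) {
    stop_input("`los` must be finite and within [0, 100].")
  }
  findInterval(los, scale$anchors) + 1L
}

#' Euclidean distance between 3D marker positions
#'
#' The spherical-distance criterion used to match reader markers to CAD
#' regions: the Euclidean norm of the coordinate difference, in mm.
#' Vectorized over rows when given matrices or data frames with columns
#' `x_mm`, `y_mm`, `z_mm`.
#'
#' @param a,b Length-3 numeric vectors, or matrices / data frames with three
#'   coordinate columns (recycled row-wise).
#' @return Numeric vector of distances in mm.
#' @export
#' @examples
#' spherical_distance(c(0, 0, 0), c(6, 8, 0)) # 10
spherical_distance <- function(a, b) {
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_input("coordinates must be finite.")
  }
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("x_mm", "y_mm", "z_mm"), names(x))
    if (length(cols) != 3L) stop_input("data frame needs x_mm, y_mm, z_mm columns.")
    return(as.matrix(x[, c("x_mm", "y_mm", "z_mm")]))
  }
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop_input("coordinate matrix must have 3 columns.")
    return(x)
  }
  if (is.numeric(x) && length(x) == 3L) return(matrix(x, nrow = 1L))
  stop_input("coordinates must be a length-3 vector, 3-column matrix or data frame.")
}

#' Assemble and validate an ABUS observer study
#'
#' Bundles the truth tables (cases, volumes, lesions and per-volume lesion
#' centers), the reader findings and the CAD region marks of one observer
#' study, enforcing every structural invariant: unique volume ids, strictly
#' positive extents and diameters, case labels consistent with their lesion
#' content, LOS scores in \[0, 100\], BI-RADS in 1..5, and every marker
#' position inside its volume's bounding box.
#'
#' @param cases Tibble with columns `case_id`, `label`
#'   (`"malignant"`, `"benign"` or `"normal"`).
#' @param volumes Tibble with `volume_id`, `case_id`, `extent_x_mm`,
#'   `extent_y_mm`, `extent_z_mm`.
#' @param lesions Tibble with `lesion_id`, `case_id`, `truth`
#'   (`"malignant"`/`"benign"`), `diameter_mm`.
#' @param lesion_locations Tibble with `lesion_id`, `volume_id`, `x_mm`,
#'   `y_mm`, `z_mm`: the lesion center in every volume in which it is
#'   visible (one or more rows per lesion).
#' @param findings Tibble with `reader_id`, `case_id`, `volume_id`, `x_mm`,
#'   `y_mm`, `z_mm`, `birads`, `los`.
#' @param cad_marks Tibble with `case_id`, `volume_id`, `x_mm`, `y_mm`,
#'   `z_mm`.
#' @param anchors An [anchor_scale()].
#' @return An object of class `abus_study`: a named list of the validated
#'   tibbles plus the anchor scale.
#' @export
new_study <- function(cases, volumes, lesions = NULL, lesion_locations = NULL,
                      findings = NULL, cad_marks = NULL,
                      anchors = anchor_scale()) {
  empty <- function(...) tibble(...)
  study <- structure(list(
    cases = as_tibble(cases),
    volumes = as_tibble(volumes),
    lesions = if (is.null(lesions))
      empty(lesion_id = character(), case_id = character(),
            truth = character(), diameter_mm = numeric()) else as_tibble(lesions),
    lesion_locations = if (is.null(lesion_locations))
      empty(lesion_id = character(), volume_id = character(),
            x_mm = numeric(), y_mm = numeric(), z_mm = numeric())
      else as_tibble(lesion_locations),
    findings = if (is.null(findings))
      empty(reader_id = character(), case_id = character(),
            volume_id = character(), x_mm = numeric(), y_mm = numeric(),
            z_mm = numeric(), birads = integer(), los = numeric())
      else as_tibble(findings),
    cad_marks = if (is.null(cad_marks))
      empty(case_id = character(), volume_id = character(),
            x_mm = numeric(), y_mm = numeric(), z_mm = numeric())
      else as_tibble(cad_marks),
    anchors = anchors
  ), class = "abus_study")
  validate_study(study)
}

required_columns <- list(
  cases = c("case_id", "label"),
  volumes = c("volume_id", "case_id", "extent_x_mm", "extent_y_mm", "extent_z_mm"),
  lesions = c("lesion_id", "case_id", "truth", "diameter_mm"),
  lesion_locations = c("lesion_id", "volume_id", "x_mm", "y_mm", "z_mm"),
  findings = c("reader_id", "case_id", "volume_id", "x_mm", "y_mm", "z_mm",
               "birads", "los"),
  cad_marks = c("case_id", "volume_id", "x_mm", "y_mm", "z_mm")
)

#' Validate study invariants
#'
#' Checks every structural invariant of an `abus_study`; errors name the
#' offending table and rows. Called by [new_study()] and [load_study()].
#'
#' @param study An `abus_study`.
#' @return The study, invisibly classed, if valid.
#' @export
validate_study <- function(study) {
  for (tb in names(required_columns)) {
    missing <- setdiff(required_columns[[tb]], names(study[[tb]]))
    if (length(missing)) {
      stop_schema(sprintf("%s: missing column(s) %s", tb,
                          paste(missing, collapse = ", ")))
    }
  }
  cases <- study$cases; volumes <- study$volumes; lesions <- study$lesions
  locs <- study$lesion_locations; findings <- study$findings
  marks <- study$cad_marks

  bad_rows <- function(tb, idx, what) {
    stop_schema(sprintf("%s: %s (row%s %s)", tb, what,
                        if (length(idx) > 1) "s" else "",
                        paste(head(idx, 5), collapse = ", ")))
  }
  if (anyDuplicated(cases$case_id)) {
    bad_rows("cases", which(duplicated(cases$case_id)), "duplicate case_id")
  }
  if (!all(cases$label %in% c("malignant", "benign", "normal"))) {
    bad_rows("cases", which(!cases$label %in% c("malignant", "benign", "normal")),
             "label must be malignant/benign/normal")
  }
  if (anyDuplicated(volumes$volume_id)) {
    bad_rows("volumes", which(duplicated(volumes$volume_id)), "duplicate volume_id")
  }
  ext <- as.matrix(volumes[, c("extent_x_mm", "extent_y_mm", "extent_z_mm")])
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    bad_rows("volumes", which(apply(ext, 1, function(r) any(!is.finite(r) | r <= 0))),
             "extents must be strictly positive")
  }
  if (any(!volumes$case_id %in% cases$case_id)) {
    bad_rows("volumes", which(!volumes$case_id %in% cases$case_id),
             "orphan case_id")
  }
  if (nrow(lesions)) {
    if (anyDuplicated(lesions$lesion_id)) {
      bad_rows("lesions", which(duplicated(lesions$lesion_id)), "duplicate lesion_id")
    }
    if (any(!lesions$truth %in% c("malignant", "benign"))) {
      bad_rows("lesions", which(!lesions$truth %in% c("malignant", "benign")),
               "truth must be malignant/benign")
    }
    if (any(!is.finite(lesions$diameter_mm) | lesions$diameter_mm <= 0)) {
      bad_rows("lesions", which(!is.finite(lesions$diameter_mm) |
                                  lesions$diameter_mm <= 0),
               "diameter_mm must be > 0")
    }
    if (any(!lesions$case_id %in% cases$case_id)) {
      bad_rows("lesions", which(!lesions$case_id %in% cases$case_id),
               "orphan case_id")
    }
    if (any(!lesions$lesion_id %in% locs$lesion_id)) {
      bad_rows("lesions", which(!lesions$lesion_id %in% locs$lesion_id),
               "lesion has no center in any volume")
    }
  }
  if (nrow(locs)) {
    if (any(!locs$lesion_id %in% lesions$lesion_id)) {
      bad_rows("lesion_locations", which(!locs$lesion_id %in% lesions$lesion_id),
               "orphan lesion_id")
    }
    if (any(!locs$volume_id %in% volumes$volume_id)) {
      bad_rows("lesion_locations", which(!locs$volume_id %in% volumes$volume_id),
               "orphan volume_id")
    }
    # lesion volume must belong to the lesion's case
    lj <- dplyr::left_join(locs, lesions[, c("lesion_id", "case_id")], by = "lesion_id")
    lj <- dplyr::left_join(lj, volumes[, c("volume_id", "case_id")],
                           by = "volume_id", suffix = c("", "_vol"))
    if (any(lj$case_id != lj$case_id_vol)) {
      bad_rows("lesion_locations", which(lj$case_id != lj$case_id_vol),
               "volume does not belong to the lesion's case")
    }
    check_inside("lesion_locations", locs, volumes)
  }
  # case label vs lesion content
  n_mal <- table(factor(lesions$case_id[lesions$truth == "malignant"],
                        levels = cases$case_id))
  n_ben <- table(factor(lesions$case_id[lesions$truth == "benign"],
                        levels = cases$case_id))
  bad <- (cases$label == "normal" & (n_mal + n_ben) > 0) |
    (cases$label == "malignant" & n_mal == 0) |
    (cases$label == "benign" & (n_ben == 0 | n_mal > 0))
  if (any(bad)) bad_rows("cases", which(bad), "label inconsistent with lesion content")

  for (tb in c("findings", "cad_marks")) {
    t <- study[[tb]]
    if (!nrow(t)) next
    if (any(!t$case_id %in% cases$case_id)) {
      bad_rows(tb, which(!t$case_id %in% cases$case_id), "orphan case_id")
    }
    if (any(!t$volume_id %in% volumes$volume_id)) {
      bad_rows(tb, which(!t$volume_id %in% volumes$volume_id), "orphan volume_id")
    }
    vj <- dplyr::left_join(t[, c("case_id", "volume_id")],
                           volumes[, c("volume_id", "case_id")],
                           by = "volume_id", suffix = c("", "_vol"))
    if (any(vj$case_id != vj$case_id_vol)) {
      bad_rows(tb, which(vj$case_id != vj$case_id_vol),
               "volume does not belong to case")
    }
    check_inside(tb, t, volumes)
  }
  if (nrow(findings)) {
    if (any(!is.finite(findings$los) | findings$los < 0 | findings$los > 100)) {
      bad_rows("findings", which(!is.finite(findings$los) | findings$los < 0 |
                                   findings$los > 100),
               "los outside [0, 100]")
    }
    if (any(!findings$birads %in% 1:5)) {
      bad_rows("findings", which(!findings$birads %in% 1:5),
               "birads outside 1..5")
    }
  }
  invisible(study)
}

check_inside <- function(tb, t, volumes) {
  j <- dplyr::left_join(
    t[, c("volume_id", "x_mm", "y_mm", "z_mm")],
    volumes[, c("volume_id", "extent_x_mm", "extent_y_mm", "extent_z_mm")],
    by = "volume_id"
  )
  out <- !is.finite(j$x_mm) | !is.finite(j$y_mm) | !is.finite(j$z_mm) |
    j$x_mm < 0 | j$y_mm < 0 | j$z_mm < 0 |
    j$x_mm > j$extent_x_mm | j$y_mm > j$extent_y_mm | j$z_mm > j$extent_z_mm
  out[is.na(out)] <- FALSE
  if (any(out)) {
    stop_schema(sprintf("%s: position outside volume extent (rows %s)", tb,
                        paste(head(which(out), 5), collapse = ", ")))
  }
  invisible(NULL)
}

#' @export
print.abus_study <- function(x, ...) {
  cat("<abus_study>\n")
  cat(sprintf("  cases: %d (%s)\n", nrow(x$cases),
              paste(sprintf("%d %s", table(x$cases$label)[c("malignant", "benign", "normal")],
                            c("malignant", "benign", "normal")), collapse = ", ")))
  cat(sprintf("  volumes: %d | lesions: %d | CAD marks: %d\n",
              nrow(x$volumes), nrow(x$lesions), nrow(x$cad_marks)))
  cat(sprintf("  findings: %d from %d reader(s)\n", nrow(x$findings),
              length(unique(x$findings$reader_id))))
  invisible(x)
}

study_tables <- c("cases", "volumes", "lesions", "lesion_locations",
                  "findings", "cad_marks")

#' Write a study to CSV files
#'
#' Writes one CSV per table (`cases.csv`, `volumes.csv`, `lesions.csv`,
#' `lesion_locations.csv`, `findings.csv`, `cad_marks.csv`) into `dir`. The
#' first line of every file is a comment header carrying the schema version.
#'
#' @param study An `abus_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [load_study()], [write_study_json()]
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in study_tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    writeLines(sprintf("# cadmrmc_schema: %d", SCHEMA_VERSION), path)
    suppressMessages(readr::write_csv(study[[tb]], path, append = TRUE,
                                      col_names = TRUE))
  }
  invisible(dir)
}

#' Load a study from CSV files
#'
#' Reads the table bundle written by [write_study()] and validates every
#' invariant; malformed files raise a schema error naming the offending
#' table, column or row.
#'
#' @param dir Directory containing the CSV bundle.
#' @param anchors An [anchor_scale()].
#' @return An `abus_study`.
#' @export
load_study <- function(dir, anchors = anchor_scale()) {
  tabs <- list()
  col_specs <- list(
    cases = readr::cols(case_id = "c", label = "c"),
    volumes = readr::cols(volume_id = "c", case_id = "c", .default = "d"),
    lesions = readr::cols(lesion_id = "c", case_id = "c", truth = "c",
                          diameter_mm = "d"),
    lesion_locations = readr::cols(lesion_id = "c", volume_id = "c",
                                   .default = "d"),
    findings = readr::cols(reader_id = "c", case_id = "c", volume_id = "c",
                           birads = "i", .default = "d"),
    cad_marks = readr::cols(case_id = "c", volume_id = "c", .default = "d")
  )
  for (tb in study_tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      if (tb %in% c("cases", "volumes")) {
        stop_schema(sprintf("required file not found: %s", path))
      }
      tabs[[tb]] <- NULL
      next
    }
    tabs[[tb]] <- suppressWarnings(
      readr::read_csv(path, comment = "#", col_types = col_specs[[tb]],
                      progress = FALSE)
    )
    prob <- readr::problems(tabs[[tb]])
    if (nrow(prob)) {
      stop_schema(sprintf("%s: could not parse row %d (%s)", basename(path),
                          prob$row[1], prob$expected[1]))
    }
  }
  new_study(cases = tabs$cases, volumes = tabs$volumes, lesions = tabs$lesions,
            lesion_locations = tabs$lesion_locations, findings = tabs$findings,
            cad_marks = tabs$cad_marks, anchors = anchors)
}

#' Write a study to a single JSON file
#'
#' @param study An `abus_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(study, path) {
  payload <- c(list(schema_version = SCHEMA_VERSION),
               lapply(study[study_tables], as.data.frame))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a study from a single JSON file
#'
#' @param path JSON file written by [write_study_json()].
#' @param anchors An [anchor_scale()].
#' @return An `abus_study`.
#' @export
load_study_json <- function(path, anchors = anchor_scale()) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version)) {
    stop_schema("JSON study bundle lacks a schema_version field.")
  }
  tabs <- lapply(payload[intersect(study_tables, names(payload))], function(t) {
    t <- as_tibble(t)
    if (!ncol(t)) NULL else t    # empty tables serialize without columns
  })
  fix_int <- function(t, col) {
    if (!is.null(t) && col %in% names(t)) t[[col]] <- as.integer(t[[col]])
    t
  }
  tabs$findings <- fix_int(tabs$findings, "birads")
  new_study(cases = tabs$cases, volumes = tabs$volumes, lesions = tabs$lesions,
            lesion_locations = tabs$lesion_locations, findings = tabs$findings,
            cad_marks = tabs$cad_marks, anchors = anchors)
}
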