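# Worked-example construction: a geometric study that realizes a given
# per-reader table of positive/rejected finding counts, so the summary
# tables can be reproduced through the full matching pipeline.

#' Reference per-reader rejection counts for the worked example
#'
#' Per-reader counts of positive (BI-RADS >= 3) findings, CAD rejections,
#' and the rejection breakdown by consensus truth class and BI-RADS
#' category for an eight-reader, 120-case ABUS reading study; bundled as
#' the input of the worked example in the package documentation.
#'
#' @return A tibble with one row per reader: `reader_id`, `n_positive`,
#'   `n_rejected`, `n_normal`, `n_benign`, `n_malignant`, `n_birads3`,
#'   `n_birads4`, `n_birads5`.
#' @export
example_rejection_counts <- function() {
  path <- system.file("extdata", "table2_counts.csv", package = "cadmrmc")
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Build a study realizing a per-reader rejection count table
#'
#' Constructs a geometric `abus_study` (cases, lesions, CAD marks and
#' reader findings) such that running [validate_findings()] reproduces, for
#' every reader, exactly the given number of positive findings, CAD
#' rejections, and rejection breakdown by truth class and BI-RADS category.
#' Retained findings sit on shared marker slots carrying a co-located CAD
#' mark; rejected findings sit on malignant lesions, benign lesions or
#' normal tissue in cases without nearby CAD marks. Marker slots are spaced
#' far apart (40 mm) so matches are unambiguous.
#'
#' @param counts A tibble like [example_rejection_counts()]: the truth-class
#'   and BI-RADS columns must each sum to `n_rejected`, and
#'   `n_rejected <= n_positive`.
#' @return An `abus_study`.
#' @export
#' @examples
#' study <- study_from_rejection_counts(example_rejection_counts())
#' summarize_rejections(validate_findings(study))
study_from_rejection_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("reader_id", "n_positive", "n_rejected", "n_normal", "n_benign",
            "n_malignant", "n_birads3", "n_birads4", "n_birads5")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop_input(sprintf("counts: missing column(s) %s",
                       paste(missing, collapse = ", ")))
  }
  if (any(counts$n_normal + counts$n_benign + counts$n_malignant !=
            counts$n_rejected) ||
      any(counts$n_birads3 + counts$n_birads4 + counts$n_birads5 !=
            counts$n_rejected) ||
      any(counts$n_rejected > counts$n_positive)) {
    stop_input("counts: breakdown columns must sum to n_rejected <= n_positive.")
  }
  n_mal <- max(counts$n_malignant)
  n_ben <- max(counts$n_benign)
  n_norm <- max(counts$n_normal)
  n_ret <- max(counts$n_positive - counts$n_rejected)

  ext <- c(200, 200, 50)
  slot <- function(i) {           # 40 mm grid, 25 slots per volume
    c(20 + 40 * ((i - 1) %% 5), 20 + 40 * (((i - 1) %/% 5) %% 5), 25)
  }
  case_block <- function(prefix, n, label) {
    tibble(case_id = sprintf("%s%02d", prefix, seq_len(n)), label = label)
  }
  cases <- dplyr::bind_rows(
    case_block("mal", n_mal, "malignant"),
    case_block("ben", n_ben, "benign"),
    case_block("nrm", n_norm, "normal"),
    case_block("ret", max(n_ret, 1), "normal")
  )
  volumes <- tibble(case_id = cases$case_id,
                    volume_id = paste0(cases$case_id, "_v1"),
                    extent_x_mm = ext[1], extent_y_mm = ext[2],
                    extent_z_mm = ext[3])
  les_cases <- cases[cases$label != "normal", , drop = FALSE]
  pos1 <- slot(1)
  lesions <- tibble(lesion_id = paste0("les_", les_cases$case_id),
                    case_id = les_cases$case_id,
                    truth = ifelse(grepl("^mal", les_cases$case_id),
                                   "malignant", "benign"),
                    diameter_mm = ifelse(grepl("^mal", les_cases$case_id),
                                         14, 12))
  locs <- tibble(lesion_id = lesions$lesion_id,
                 volume_id = paste0(lesions$case_id, "_v1"),
                 x_mm = pos1[1], y_mm = pos1[2], z_mm = pos1[3])
  # one CAD mark on every retained slot (slot 1 of each "ret" case)
  ret_cases <- cases$case_id[grepl("^ret", cases$case_id)]
  cad_marks <- tibble(case_id = ret_cases,
                      volume_id = paste0(ret_cases, "_v1"),
                      x_mm = pos1[1], y_mm = pos1[2], z_mm = pos1[3])

  anchor_los <- c(`3` = 45, `4` = 65, `5` = 85)
  findings <- purrr::map_dfr(seq_len(nrow(counts)), function(r) {
    cw <- counts[r, ]
    target_cases <- c(
      cases$case_id[grepl("^mal", cases$case_id)][seq_len(cw$n_malignant)],
      cases$case_id[grepl("^ben", cases$case_id)][seq_len(cw$n_benign)],
      cases$case_id[grepl("^nrm", cases$case_id)][seq_len(cw$n_normal)],
      ret_cases[seq_len(cw$n_positive - cw$n_rejected)]
    )
    birads <- c(rep(3L, cw$n_birads3), rep(4L, cw$n_birads4),
                rep(5L, cw$n_birads5),
                rep(3L, cw$n_positive - cw$n_rejected))
    tibble(reader_id = cw$reader_id, case_id = target_cases,
           volume_id = paste0(target_cases, "_v1"),
           x_mm = pos1[1], y_mm = pos1[2], z_mm = pos1[3],
           birads = birads, los = unname(anchor_los[as.character(birads)]))
  })
  new_study(cases = cases, volumes = volumes, lesions = lesions,
            lesion_locations = locs, findings = findings,
            cad_marks = cad_marks)
}
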