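mk_marks <- function(...) tibble::tibble(...)

test_that("matching is inclusive at the 10 mm boundary and volume-specific", {
  f <- list(case_id = "c1", volume_id = "c1_v1", x_mm = 60, y_mm = 60, z_mm = 10)
  # exact co-location
  m0 <- mk_marks(case_id = "c1", volume_id = "c1_v1", x_mm = 60, y_mm = 60, z_mm = 10)
  r <- match_finding(f, m0)
  expect_true(r$matched); expect_identical(r$distance, 0)
  # 3-4-5 triangle: exactly 10.0 mm away still matches
  m1 <- mk_marks(case_id = "c1", volume_id = "c1_v1", x_mm = 66, y_mm = 68, z_mm = 10)
  r <- match_finding(f, m1)
  expect_true(r$matched); expect_identical(r$distance, 10)
  # same coordinates, different volume: no match
  m2 <- mk_marks(case_id = "c1", volume_id = "c1_v2", x_mm = 60, y_mm = 60, z_mm = 10)
  expect_false(match_finding(f, m2)$matched)
  expect_true(match_finding(f, m2, match_criterion(same_volume_required = FALSE))$matched)
  # empty marks
  expect_false(match_finding(f, m0[0, ])$matched)
})

test_that("the nearest qualifying mark wins, verified by brute force", {
  f <- list(case_id = "c1", volume_id = "c1_v1", x_mm = 60, y_mm = 60, z_mm = 25)
  m <- mk_marks(case_id = "c1", volume_id = "c1_v1",
                x_mm = 60, y_mm = 60, z_mm = c(36, 34))  # 11 mm and 9 mm
  r <- match_finding(f, m)
  expect_true(r$matched)
  expect_equal(r$distance, 9)
  set.seed(7)
  for (i in 1:20) {
    m <- mk_marks(case_id = "c1", volume_id = "c1_v1",
                  x_mm = runif(6, 40, 80), y_mm = runif(6, 40, 80),
                  z_mm = runif(6, 5, 45))
    d <- sqrt((m$x_mm - f$x_mm)^2 + (m$y_mm - f$y_mm)^2 + (m$z_mm - f$z_mm)^2)
    r <- match_finding(f, m)
    if (any(d <= 10)) {
      expect_true(r$matched)
      expect_equal(r$distance, min(d[d <= 10]))
    } else {
      expect_false(r$matched)
    }
  }
})

test_that("validation partitions findings and behaves at the extremes", {
  st <- tiny_study()
  # no CAD marks: everything rejected with cause no_cad_in_case
  v <- validate_findings(st)
  expect_identical(nrow(v), nrow(st$findings))
  expect_true(all(!v$retained))
  expect_true(all(v$cause == "no_cad_in_case"))
  # marks exactly on every finding: everything retained
  st2 <- tiny_study(cad_marks = st$findings[, c("case_id", "volume_id",
                                                "x_mm", "y_mm", "z_mm")])
  v2 <- validate_findings(st2)
  expect_true(all(v2$retained))
  expect_true(all(is.na(v2$cause)))
  expect_identical(sum(v2$retained) + sum(!v2$retained), nrow(st2$findings))
  expect_error(
    validate_findings(st, findings = dplyr::mutate(st$findings, case_id = "zz")),
    "unknown case", class = "cadmrmc_input_error")
})

test_that("retained set only grows with looser distance or more marks", {
  st <- simulate_study(small_config(), seed = 5)
  dists <- c(5, 10, 15)
  retained <- lapply(dists, function(d) {
    v <- validate_findings(st, match_criterion(max_distance = d))
    which(v$retained)
  })
  expect_true(all(retained[[1]] %in% retained[[2]]))
  expect_true(all(retained[[2]] %in% retained[[3]]))
  # enlarging the mark set never un-retains a finding
  v_full <- validate_findings(st)
  st_half <- st
  st_half$cad_marks <- st$cad_marks[seq_len(nrow(st$cad_marks) %/% 2), ]
  v_half <- validate_findings(st_half)
  expect_true(all(which(v_half$retained) %in% which(v_full$retained)))
})

test_that("an oracle CAD never rejects a finding that localizes a cancer", {
  cfg <- small_config(reader_jitter_sd = 1.0)
  st <- simulate_study(cfg, seed = 11)
  # place a mark exactly on every lesion center in every volume
  st$cad_marks <- dplyr::inner_join(
    st$lesion_locations, st$lesions[, c("lesion_id", "case_id")],
    by = "lesion_id")[, c("case_id", "volume_id", "x_mm", "y_mm", "z_mm")]
  v <- validate_findings(st)
  expect_false(any(!v$retained & v$truth_class == "malignant_FN"))
})

test_that("rejected findings are classified against lesion truth", {
  st <- tiny_study(findings = tibble::tibble(
    reader_id = "r1",
    case_id = c("c1", "c1", "c2"),
    volume_id = c("c1_v1", "c1_v1", "c2_v1"),
    x_mm = c(82, 140, 30), y_mm = c(70, 100, 40), z_mm = c(25, 25, 25),
    birads = c(5L, 4L, 3L), los = c(85, 65, 45)))
  v <- validate_findings(st)
  # 2 mm from the malignant lesion center (diameter 14): a missed cancer
  expect_identical(v$truth_class[1], "malignant_FN")
  # far field in the malignant case: normal tissue
  expect_identical(v$truth_class[2], "normal_tissue_artefact_TN")
  # normal case
  expect_identical(v$truth_class[3], "normal_tissue_artefact_TN")
})

test_that("a finding near a benign lesion classifies as benign_TN", {
  cases <- tibble::tibble(case_id = "b1", label = "benign")
  volumes <- tibble::tibble(volume_id = "b1_v1", case_id = "b1",
                            extent_x_mm = 170, extent_y_mm = 150,
                            extent_z_mm = 50)
  lesions <- tibble::tibble(lesion_id = "L1", case_id = "b1",
                            truth = "benign", diameter_mm = 12)
  locs <- tibble::tibble(lesion_id = "L1", volume_id = "b1_v1",
                         x_mm = 80, y_mm = 70, z_mm = 25)
  f <- tibble::tibble(reader_id = "r1", case_id = "b1", volume_id = "b1_v1",
                      x_mm = 82, y_mm = 70, z_mm = 25, birads = 4L, los = 65)
  st <- new_study(cases, volumes, lesions, locs, findings = f)
  expect_identical(validate_findings(st)$truth_class[1], "benign_TN")
})

test_that("rejection causes follow the lesion-centred taxonomy", {
  # lesion at (80,70,25), diameter 30 -> localization radius 15
  mk_st <- function(marks) {
    cases <- tibble::tibble(case_id = "c1", label = "malignant")
    volumes <- tibble::tibble(volume_id = c("c1_v1", "c1_v2"), case_id = "c1",
                              extent_x_mm = 170, extent_y_mm = 150,
                              extent_z_mm = 50)
    lesions <- tibble::tibble(lesion_id = "L1", case_id = "c1",
                              truth = "malignant", diameter_mm = 30)
    locs <- tibble::tibble(lesion_id = "L1", volume_id = c("c1_v1", "c1_v2"),
                           x_mm = 80, y_mm = 70, z_mm = 25)
    f <- tibble::tibble(reader_id = "r1", case_id = "c1", volume_id = "c1_v2",
                        x_mm = 80, y_mm = 70, z_mm = 25, birads = 5L, los = 90)
    new_study(cases, volumes, lesions, locs, findings = f, cad_marks = marks)
  }
  f1 <- list(case_id = "c1", volume_id = "c1_v2", x_mm = 80, y_mm = 70, z_mm = 25)

  # same-volume mark on the tumor but 12 mm from the marker
  st <- mk_st(mk_marks(case_id = "c1", volume_id = "c1_v2",
                       x_mm = 92, y_mm = 70, z_mm = 25))
  expect_identical(diagnose_cause(f1, st), "distance_exceeded")
  # CAD marked the lesion only in the other volume
  st <- mk_st(mk_marks(case_id = "c1", volume_id = "c1_v1",
                       x_mm = 80, y_mm = 70, z_mm = 25))
  expect_identical(diagnose_cause(f1, st), "wrong_volume")
  # marks exist in the case but none near the lesion
  st <- mk_st(mk_marks(case_id = "c1", volume_id = "c1_v2",
                       x_mm = 20, y_mm = 20, z_mm = 10))
  expect_identical(diagnose_cause(f1, st), "cad_total_miss")
  # no marks at all
  st <- mk_st(NULL)
  expect_identical(diagnose_cause(f1, st), "no_cad_in_case")
})

test_that("rejection summary handles a reader with no rejections", {
  st <- tiny_study(cad_marks = tiny_study()$findings[, c("case_id", "volume_id",
                                                         "x_mm", "y_mm", "z_mm")])
  v <- validate_findings(st)
  expect_message(rs <- summarize_rejections(v), "undefined percentages")
  expect_identical(rs$n_rejected, 0L)
  expect_true(is.na(rs$pct_normal))
  expect_true(is.na(attr(rs, "summary")$pct_normal[1]))
})

test_that("summary percentages use round-half-away-from-zero", {
  expect_identical(round_half_up(0.05, 1), 0.1)
  expect_identical(round_half_up(42.65, 1), 42.7)
  expect_identical(round_half_up(-0.05, 1), -0.1)
})

test_that("double-reading workload counts discordant cases exactly", {
  st <- simulate_study(small_config(), seed = 3)
  v <- validate_findings(st)
  w <- double_read_workload(v, st)
  # brute force per reader
  for (r in unique(v$reader_id)) {
    vr <- v[v$reader_id == r, ]
    disc <- unique(vr$case_id[vr$birads >= 3 & !vr$retained])
    expect_identical(w$n_discordant[w$reader_id == r], length(disc))
    expect_equal(w$fraction[w$reader_id == r], length(disc) / nrow(st$cases))
  }
  # all findings validated -> zero workload
  st2 <- st
  st2$cad_marks <- st$findings[, c("case_id", "volume_id", "x_mm", "y_mm", "z_mm")]
  w2 <- double_read_workload(validate_findings(st2), st2)
  expect_true(all(w2$fraction == 0))
  # no marks at all -> fraction of cases with a positive finding
  st3 <- st
  st3$cad_marks <- st$cad_marks[0, ]
  v3 <- validate_findings(st3)
  w3 <- double_read_workload(v3, st3)
  for (r in unique(v3$reader_id)) {
    pos_cases <- unique(v3$case_id[v3$reader_id == r & v3$birads >= 3])
    expect_equal(w3$fraction[w3$reader_id == r],
                 length(pos_cases) / nrow(st3$cases))
  }
})
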