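# Fixtures built in code: a hand-laid two-case study and random score sets.

# Two cases (one malignant with a 14 mm lesion, one normal), two volumes
# each, one reader, three findings; geometry chosen so one finding sits on
# the lesion, one is a boundary match candidate, one is free tissue.
tiny_study <- function(findings = NULL, cad_marks = NULL) {
  cases <- tibble::tibble(case_id = c("c1", "c2"),
                          label = c("malignant", "normal"))
  volumes <- tibble::tibble(
    volume_id = c("c1_v1", "c1_v2", "c2_v1", "c2_v2"),
    case_id = c("c1", "c1", "c2", "c2"),
    extent_x_mm = 170, extent_y_mm = 150, extent_z_mm = 50)
  lesions <- tibble::tibble(lesion_id = "L1", case_id = "c1",
                            truth = "malignant", diameter_mm = 14)
  locs <- tibble::tibble(lesion_id = "L1", volume_id = "c1_v1",
                         x_mm = 80, y_mm = 70, z_mm = 25)
  if (is.null(findings)) {
    findings <- tibble::tibble(
      reader_id = "r1",
      case_id = c("c1", "c2", "c2"),
      volume_id = c("c1_v1", "c2_v1", "c2_v2"),
      x_mm = c(80, 30, 100), y_mm = c(70, 40, 90), z_mm = c(25, 25, 25),
      birads = c(5L, 3L, 2L), los = c(85, 45, 30))
  }
  new_study(cases = cases, volumes = volumes, lesions = lesions,
            lesion_locations = locs, findings = findings,
            cad_marks = cad_marks)
}

# random case-score set (with sentinel mass and ties) as a case_scores tibble
random_score_set <- function(n_d = 8, n_n = 12, p_sentinel = 0.25,
                             reader = "r1") {
  mk <- function(n, shift) {
    s <- round(runif(n, 0, 100 - shift) + shift, 1)  # rounding induces ties
    s[runif(n) < p_sentinel] <- -Inf
    s
  }
  tibble::tibble(
    reader_id = reader,
    case_id = sprintf("k%03d", seq_len(n_d + n_n)),
    class = rep(c("diseased", "nondiseased"), c(n_d, n_n)),
    score = c(mk(n_d, 20), mk(n_n, 0)))
}

# brute-force pairwise AFROC figure of merit (independent oracle)
brute_fom <- function(d, n) {
  s <- 0
  for (x in d) for (y in n) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(d) * length(n))
}

# small fast simulation config for structural tests
small_config <- function(...) {
  args <- list(...)
  base <- list(n_malignant = 8, n_benign = 8, n_normal = 16, n_readers = 3)
  do.call(sim_config, utils::modifyList(base, args))
}
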