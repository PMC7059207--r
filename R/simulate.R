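# Synthetic ABUS observer-study generator.
#
# Emulates the study design the analysis assumes: 120 unilateral exams
# (30 malignant / 30 benign / 60 normal) spread over ~375 ABUS volumes,
# 8 readers rating on the BI-RADS-anchored 0-100 LOS scale, and a CAD
# system operating at ~82% lesion sensitivity with on average one
# false-positive region per volume. Ratings follow a Roe-Metz-style latent
# model (shared case effects + reader effects + residual noise, pushed
# through a probit link onto the LOS scale) so that MRMC variance
# components are non-trivial.
#
# Random streams are split hierarchically (truth / CAD / per-reader) from
# the user seed, so e.g. changing the number of readers never perturbs the
# generated truth.

#' Simulation configuration
#'
#' All tunable parameters of the synthetic study generator, with defaults
#' reproducing the study design: class counts 30/30/60, 2-5 volumes per
#' case (mean 3.125, about 375 volumes over 120 cases), malignant diameters
#' lognormal with median 14 mm, benign with median 12.4 mm, CAD lesion
#' sensitivity 0.82 and false-positive rate 1 per volume, and eight readers
#' of graded ability.
#'
#' @param n_malignant,n_benign,n_normal Case class counts.
#' @param n_readers Number of readers.
#' @param volumes_per_case Integer candidates for volumes per case.
#' @param volume_probs Sampling probabilities for `volumes_per_case`
#'   (defaults give a mean of 3.125).
#' @param extent_mm Volume bounding box (x, y, z) in mm.
#' @param mal_diameter,ben_diameter Lognormal diameter parameters
#'   `list(meanlog, sdlog, min, max)` in mm.
#' @param multi_volume_fraction Fraction of malignant lesions visible in two
#'   volumes of the case.
#' @param cad_sensitivity Marginal probability that CAD marks a malignant
#'   lesion (the CAD operating point).
#' @param cad_benign_sensitivity Marginal probability that CAD marks a
#'   benign lesion.
#' @param cad_conspicuity_wt Weight coupling CAD lesion detection to the
#'   lesion conspicuity effect shared with the readers (probit scale).
#'   Subtle lesions rated lower by readers are then also missed more often
#'   by CAD, while the marginal sensitivities stay at their configured
#'   values.
#' @param cad_fp_rate Poisson rate of CAD false-positive regions per volume.
#' @param cad_jitter_sd SD (mm) of the CAD mark offset from the lesion
#'   center.
#' @param cad_offset_prob Probability that a marked large lesion (diameter
#'   above `2.2 * match_distance`) receives its mark offset beyond the match
#'   distance while remaining within the lesion (the "extent of the tumor
#'   exceeds the criterion" failure mode).
#' @param cad_single_volume_prob Probability that a marked multi-volume
#'   lesion is marked in only one of its volumes.
#' @param match_distance Match criterion distance (mm) referenced by the
#'   offset failure mode.
#' @param detect_malignant,detect_benign Reader lesion-detection
#'   probabilities: scalar, `c(lo, hi)` range spread evenly over readers, or
#'   one value per reader.
#' @param reader_fp_rate Reader false-mark Poisson rate per volume (same
#'   forms as above).
#' @param reader_jitter_sd SD (mm) of reader marker placement around the
#'   lesion center.
#' @param mal_mean,benign_mean,fp_mean Latent class means (probit scale).
#' @param var_case,var_reader,var_resid Latent variance components: lesion
#'   conspicuity / case effects (shared across readers -- the source of
#'   inter-reader correlation), reader effects, residual noise.
#' @param anchors An [anchor_scale()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_malignant = 30, n_benign = 30, n_normal = 60,
                       n_readers = 8,
                       volumes_per_case = 2:5,
                       volume_probs = c(0.30, 0.35, 0.275, 0.075),
                       extent_mm = c(170, 150, 50),
                       mal_diameter = list(meanlog = log(14), sdlog = 0.50,
                                           min = 6, max = 45),
                       ben_diameter = list(meanlog = log(12.4), sdlog = 0.37,
                                           min = 5, max = 30),
                       multi_volume_fraction = 0.15,
                       cad_sensitivity = 0.82,
                       cad_benign_sensitivity = 0.45,
                       cad_conspicuity_wt = 2.2,
                       cad_fp_rate = 1.0,
                       cad_jitter_sd = 2,
                       cad_offset_prob = 0.30,
                       cad_single_volume_prob = 0.5,
                       match_distance = 10,
                       detect_malignant = c(0.75, 0.92),
                       detect_benign = c(0.60, 0.80),
                       reader_fp_rate = c(0.04, 0.18),
                       reader_jitter_sd = 2,
                       mal_mean = 1.0, benign_mean = 0.25, fp_mean = -0.2,
                       var_case = 0.30, var_reader = 0.04, var_resid = 0.28,
                       anchors = anchor_scale()) {
  cfg <- as.list(environment())
  probs <- c(cad_sensitivity, cad_benign_sensitivity, cad_offset_prob,
             cad_single_volume_prob, multi_volume_fraction)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must lie in [0, 1].")
  if (any(c(n_malignant, n_benign, n_normal, n_readers) < 0)) {
    stop_input("counts must be non-negative.")
  }
  if (cad_fp_rate < 0 || any(reader_fp_rate < 0)) {
    stop_input("rates must be non-negative.")
  }
  if (any(c(var_case, var_reader, var_resid) < 0)) {
    stop_input("variances must be non-negative.")
  }
  if (length(volume_probs) != length(volumes_per_case)) {
    stop_input("volume_probs must match volumes_per_case in length.")
  }
  if (min(extent_mm) <= 2 * max(mal_diameter$max, ben_diameter$max) / 2) {
    # lesion (half-diameter margin on both sides) must fit in every axis
    stop_input("volume extent too small for the configured lesion diameters.")
  }
  structure(cfg, class = "sim_config")
}

# spread a scalar / range / per-reader vector over n readers
reader_seq <- function(x, n) {
  if (length(x) == 1) rep(x, n)
  else if (length(x) == 2) seq(x[1], x[2], length.out = n)
  else if (length(x) == n) x
  else stop_input("reader parameter must have length 1, 2 or n_readers.")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

# uniform point inside the volume, at least `margin` from every face
runif_inside <- function(n, extent, margin = 0) {
  m <- pmin(margin, extent / 2 - 1e-6)
  cbind(runif(n, m[1], extent[1] - m[1]),
        runif(n, m[2], extent[2] - m[2]),
        runif(n, m[3], extent[3] - m[3]))
}

clip_inside <- function(xyz, extent) {
  pmin(pmax(xyz, 0), matrix(extent, nrow(xyz), 3, byrow = TRUE))
}

#' Generate case, volume and lesion truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory; all streams derive from it).
#' @return An `abus_study` containing cases, volumes, lesions and lesion
#'   centers (no findings, no CAD marks).
#' @export
generate_truth <- function(config = sim_config(), seed) {
  if (missing(seed)) stop_input("`seed` is mandatory.")
  set.seed(derive_seed(seed, 1))
  n_cases <- config$n_malignant + config$n_benign + config$n_normal
  labels <- rep(c("malignant", "benign", "normal"),
                c(config$n_malignant, config$n_benign, config$n_normal))
  cases <- tibble(case_id = sprintf("case%03d", seq_len(n_cases)),
                  label = labels)
  nv <- if (length(config$volumes_per_case) == 1L) {
    rep(config$volumes_per_case, n_cases)
  } else {
    sample(config$volumes_per_case, n_cases, replace = TRUE,
           prob = config$volume_probs)
  }
  volumes <- tibble(
    case_id = rep(cases$case_id, nv),
    volume_id = paste0(rep(cases$case_id, nv), "_v",
                       unlist(lapply(nv, seq_len))),
    extent_x_mm = config$extent_mm[1],
    extent_y_mm = config$extent_mm[2],
    extent_z_mm = config$extent_mm[3]
  )
  les_cases <- cases[cases$label != "normal", , drop = FALSE]
  if (nrow(les_cases)) {
    dm <- config$mal_diameter; db <- config$ben_diameter
    mal <- les_cases$label == "malignant"
    diam <- numeric(nrow(les_cases))
    diam[mal] <- rlnorm_trunc(sum(mal), dm$meanlog, dm$sdlog, dm$min, dm$max)
    diam[!mal] <- rlnorm_trunc(sum(!mal), db$meanlog, db$sdlog, db$min, db$max)
    lesions <- tibble(
      lesion_id = paste0("les_", les_cases$case_id),
      case_id = les_cases$case_id,
      truth = ifelse(mal, "malignant", "benign"),
      diameter_mm = diam,
      # latent conspicuity shared by readers and CAD (probit scale)
      conspicuity = rnorm(nrow(les_cases), sd = sqrt(config$var_case))
    )
    # a fraction of malignant lesions is visible in two volumes
    two_vol <- mal & runif(nrow(lesions)) < config$multi_volume_fraction
    locs <- purrr::map_dfr(seq_len(nrow(lesions)), function(i) {
      vids <- volumes$volume_id[volumes$case_id == lesions$case_id[i]]
      vids <- vids[seq_len(if (two_vol[i] && length(vids) >= 2) 2 else 1)]
      xyz <- runif_inside(length(vids), config$extent_mm,
                          margin = rep(lesions$diameter_mm[i] / 2, 3))
      tibble(lesion_id = lesions$lesion_id[i], volume_id = vids,
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
    })
  } else {
    lesions <- NULL; locs <- NULL
  }
  new_study(cases = cases, volumes = volumes, lesions = lesions,
            lesion_locations = locs, anchors = config$anchors)
}

#' Generate CAD region marks for a truth set
#'
#' Each malignant lesion is marked with probability `cad_sensitivity`
#' (benign: `cad_benign_sensitivity`). Marked lesions receive a mark at the
#' lesion center plus Gaussian jitter, except for the two failure modes:
#' large lesions may get their mark offset beyond the match distance (but
#' within the lesion), and multi-volume lesions may be marked in only one
#' of their volumes. False-positive regions are added per volume as a
#' Poisson stream at uniform positions.
#'
#' @param truth An `abus_study` from [generate_truth()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A CAD-mark tibble (`case_id`, `volume_id`, `x_mm`, `y_mm`,
#'   `z_mm`).
#' @export
generate_cad_marks <- function(truth, config = sim_config(), seed) {
  if (missing(seed)) stop_input("`seed` is mandatory.")
  set.seed(derive_seed(seed, 2))
  ext <- config$extent_mm
  lesions <- truth$lesions
  marks_list <- list()
  if (nrow(lesions)) {
    # probit-normal detection: P(mark | conspicuity z) = pnorm(a + w z) with
    # a chosen so the marginal sensitivity equals the configured value
    w <- config$cad_conspicuity_wt
    s <- sqrt(1 + w^2 * config$var_case)
    z <- if ("conspicuity" %in% names(lesions)) lesions$conspicuity else 0
    p_mark <- pnorm(qnorm(ifelse(lesions$truth == "malignant",
                                 config$cad_sensitivity,
                                 config$cad_benign_sensitivity)) * s + w * z)
    marked <- runif(nrow(lesions)) < p_mark
    for (i in which(marked)) {
      locs <- truth$lesion_locations[
        truth$lesion_locations$lesion_id == lesions$lesion_id[i], , drop = FALSE]
      if (nrow(locs) > 1 && runif(1) < config$cad_single_volume_prob) {
        locs <- locs[sample(nrow(locs), 1), , drop = FALSE]
      }
      d <- lesions$diameter_mm[i]
      offset_mode <- d > 2.2 * config$match_distance &&
        runif(1) < config$cad_offset_prob
      ctr <- as.matrix(locs[, c("x_mm", "y_mm", "z_mm")])
      if (offset_mode) {
        # mark inside the lesion but beyond the match distance from center
        dir <- matrix(rnorm(3 * nrow(ctr)), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        rad <- runif(nrow(ctr), 1.05 * config$match_distance, d / 2)
        xyz <- ctr + dir * rad
      } else {
        xyz <- ctr + matrix(rnorm(3 * nrow(ctr), sd = config$cad_jitter_sd),
                            ncol = 3)
      }
      xyz <- clip_inside(xyz, ext)
      marks_list[[length(marks_list) + 1]] <- tibble(
        case_id = lesions$case_id[i], volume_id = locs$volume_id,
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
    }
  }
  n_fp <- rpois(nrow(truth$volumes), config$cad_fp_rate)
  if (sum(n_fp)) {
    xyz <- runif_inside(sum(n_fp), ext)
    marks_list[[length(marks_list) + 1]] <- tibble(
      case_id = rep(truth$volumes$case_id, n_fp),
      volume_id = rep(truth$volumes$volume_id, n_fp),
      x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
  }
  if (!length(marks_list)) {
    return(tibble(case_id = character(), volume_id = character(),
                  x_mm = numeric(), y_mm = numeric(), z_mm = numeric()))
  }
  dplyr::bind_rows(marks_list)
}

#' Generate reader sessions for a truth set
#'
#' Each reader detects each lesion independently with a per-reader
#' detection probability, marks detected lesions at the center plus jitter
#' (for multi-volume lesions, in one randomly chosen volume), and adds
#' false marks per volume as a Poisson stream. LOS scores arise from a
#' latent Gaussian model -- class mean + case effect (shared across
#' readers) + reader effect + residual -- mapped through the probit link
#' onto 0-100; BI-RADS follows from the anchor intervals
#' ([los_to_birads()]).
#'
#' @param truth An `abus_study` from [generate_truth()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A findings tibble covering all `n_readers` readers.
#' @export
generate_reader_sessions <- function(truth, config = sim_config(), seed) {
  if (missing(seed)) stop_input("`seed` is mandatory.")
  n_cases <- nrow(truth$cases)
  set.seed(derive_seed(seed, 3))
  case_eff <- setNames(rnorm(n_cases, sd = sqrt(config$var_case)),
                       truth$cases$case_id)
  p_mal <- reader_seq(config$detect_malignant, config$n_readers)
  p_ben <- reader_seq(config$detect_benign, config$n_readers)
  fp_rate <- reader_seq(config$reader_fp_rate, config$n_readers)
  ext <- config$extent_mm
  lesions <- truth$lesions
  locs <- truth$lesion_locations
  sessions <- purrr::map_dfr(seq_len(config$n_readers), function(r) {
    set.seed(derive_seed(seed, 1000 + r))
    reader_eff <- rnorm(1, sd = sqrt(config$var_reader))
    rid <- sprintf("reader%02d", r)
    rows <- list()
    if (nrow(lesions)) {
      p_det <- ifelse(lesions$truth == "malignant", p_mal[r], p_ben[r])
      det <- runif(nrow(lesions)) < p_det
      for (i in which(det)) {
        li <- locs[locs$lesion_id == lesions$lesion_id[i], , drop = FALSE]
        li <- li[sample(nrow(li), 1), , drop = FALSE]
        xyz <- clip_inside(
          as.matrix(li[, c("x_mm", "y_mm", "z_mm")]) +
            matrix(rnorm(3, sd = config$reader_jitter_sd), ncol = 3), ext)
        mu <- if (lesions$truth[i] == "malignant") config$mal_mean
              else config$benign_mean
        shared <- if ("conspicuity" %in% names(lesions)) lesions$conspicuity[i]
                  else case_eff[[lesions$case_id[i]]]
        latent <- mu + shared + reader_eff +
          rnorm(1, sd = sqrt(config$var_resid))
        rows[[length(rows) + 1]] <- tibble(
          reader_id = rid, case_id = lesions$case_id[i],
          volume_id = li$volume_id,
          x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
          los = 100 * pnorm(latent))
      }
    }
    n_fp <- rpois(nrow(truth$volumes), fp_rate[r])
    if (sum(n_fp)) {
      xyz <- runif_inside(sum(n_fp), ext)
      cid <- rep(truth$volumes$case_id, n_fp)
      latent <- config$fp_mean + case_eff[cid] + reader_eff +
        rnorm(sum(n_fp), sd = sqrt(config$var_resid))
      rows[[length(rows) + 1]] <- tibble(
        reader_id = rid, case_id = cid,
        volume_id = rep(truth$volumes$volume_id, n_fp),
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        los = 100 * pnorm(latent))
    }
    if (!length(rows)) return(tibble())
    dplyr::bind_rows(rows)
  })
  if (!nrow(sessions)) {
    return(tibble(reader_id = character(), case_id = character(),
                  volume_id = character(), x_mm = numeric(), y_mm = numeric(),
                  z_mm = numeric(), birads = integer(), los = numeric()))
  }
  sessions$birads <- los_to_birads(sessions$los, config$anchors)
  dplyr::relocate(sessions, "birads", .before = "los")
}

#' Simulate a complete synthetic observer study
#'
#' Composes [generate_truth()], [generate_cad_marks()] and
#' [generate_reader_sessions()] into a validated `abus_study`. Fully
#' deterministic given `seed`; the component streams are split so that
#' e.g. changing `n_readers` leaves the truth and CAD marks untouched.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory).
#' @return An `abus_study`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_readers = 2), seed = 7)
#' study
simulate_study <- function(config = sim_config(), seed) {
  if (missing(seed)) stop_input("`seed` is mandatory.")
  truth <- generate_truth(config, seed)
  truth$cad_marks <- generate_cad_marks(truth, config, seed)
  truth$findings <- generate_reader_sessions(truth, config, seed)
  validate_study(truth)
  truth
}
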