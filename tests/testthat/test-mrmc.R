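# direct pseudovalue construction used as an oracle in several tests
manual_pseudovalues <- function(scores) {
  n <- nrow(scores)
  fom <- function(s) afroc_fom(s)
  th <- fom(scores)
  vapply(seq_len(n), function(k) n * th - (n - 1) * fom(scores[-k, ]),
         numeric(1))
}

test_that("pseudovalues match hand enumeration on a 4-case toy set", {
  s <- tibble::tibble(reader_id = "r1",
                      case_id = c("d1", "d2", "n1", "n2"),
                      class = c("diseased", "diseased", "nondiseased", "nondiseased"),
                      score = c(80, 30, 50, 10))
  pv <- jackknife_pseudovalues(s)
  expect_equal(pv$pseudovalue, manual_pseudovalues(s))
  # the fast rank path and the generic fom_fn path agree
  pv2 <- jackknife_pseudovalues(s, fom_fn = afroc_fom)
  expect_equal(pv$pseudovalue, pv2$pseudovalue)
  # mean of pseudovalues equals the jackknife estimate (algebraic identity)
  th <- afroc_fom(s)
  th_minus <- vapply(1:4, function(k) afroc_fom(s[-k, ]), numeric(1))
  expect_equal(mean(pv$pseudovalue), 4 * th - 3 * mean(th_minus))
  # ... which for the rank FOM equals the full-sample FOM
  expect_equal(mean(pv$pseudovalue), th)
})

test_that("fast and generic pseudovalue paths agree on random sets", {
  set.seed(14)
  for (i in 1:10) {
    s <- random_score_set(n_d = sample(3:8, 1), n_n = sample(3:10, 1))
    expect_equal(jackknife_pseudovalues(s)$pseudovalue,
                 manual_pseudovalues(s), tolerance = 1e-12)
  }
})

test_that("a FOM insensitive to every case yields constant pseudovalues", {
  s <- tibble::tibble(reader_id = "r1",
                      case_id = sprintf("k%02d", 1:10),
                      class = rep(c("diseased", "nondiseased"), 5),
                      score = rep(50, 10))  # constant scores: FOM 0.5 always
  pv <- jackknife_pseudovalues(s)
  expect_true(all(pv$pseudovalue == 0.5))
  expect_error(jackknife_pseudovalues(s[c(1, 2, 3), ]),
               class = "cadmrmc_input_error")
})

null_pv_tibble <- function(seed, r = 3, nd = 8, nn = 12, delta = 0) {
  set.seed(seed)
  cases <- sprintf("k%03d", seq_len(nd + nn))
  cls <- rep(c("diseased", "nondiseased"), c(nd, nn))
  mu <- ifelse(cls == "diseased", 1, 0)
  ce <- rnorm(nd + nn, sd = 0.5)
  purrr::map_dfr(c("m1", "m2"), function(m) {
    purrr::map_dfr(seq_len(r), function(j) {
      sc <- tibble::tibble(
        reader_id = paste0("r", j), case_id = cases, class = cls,
        score = mu + (m == "m1") * delta + ce + rnorm(nd + nn, sd = 0.6))
      dplyr::mutate(jackknife_pseudovalues(sc), modality = m,
                    reader_id = paste0("r", j))
    })
  })
}

test_that("identical modalities give zero difference and P of one", {
  pv1 <- null_pv_tibble(1)
  pv_dup <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(pv1, modality == "m1"), modality = "mA"),
    dplyr::mutate(dplyr::filter(pv1, modality == "m1"), modality = "mB"))
  res <- dbm_anova(pv_dup)
  expect_equal(res$difference$estimate, 0)
  expect_equal(res$difference$p_value, 1)
  expect_false(res$difference$significant)
  expect_true(all(res$reader_tests$p_value == 1))
})

test_that("with a single reader the test is a paired jackknife t test", {
  pv <- dplyr::filter(null_pv_tibble(3, r = 1), reader_id == "r1")
  res <- dbm_anova(pv)
  wide <- tidyr::pivot_wider(pv, id_cols = "case_id",
                             names_from = "modality",
                             values_from = "pseudovalue")
  tt <- t.test(wide$m1, wide$m2, paired = TRUE)
  expect_equal(res$difference$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$difference$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(res$difference$ddf, unname(tt$parameter))
})

test_that("the mrmc result is structurally sound", {
  pv <- null_pv_tibble(5, r = 4, nd = 10, nn = 14, delta = 0.4)
  res <- dbm_anova(pv)
  expect_s3_class(res, "mrmc_result")
  expect_true(res$difference$p_value >= 0 && res$difference$p_value <= 1)
  expect_true(all(res$pooled$ci_lo <= res$pooled$estimate + 1e-12))
  expect_true(all(res$pooled$ci_hi >= res$pooled$estimate - 1e-12))
  # pooled estimate is the mean of the per-reader estimates
  for (m in res$modalities) {
    expect_equal(res$pooled$estimate[res$pooled$modality == m],
                 mean(res$readers$estimate[res$readers$modality == m]))
  }
  expect_identical(res$difference$significant,
                   res$difference$p_value < 0.05)
  # variance components reported with truncation bookkeeping
  expect_true(all(res$variance_components$estimate >= 0))
  td <- tidy(res)
  expect_true("pooled" %in% td$reader_id)
  gl <- glance(res)
  expect_true(all(c("F", "ddf", "p_value") %in% names(gl)))
  expect_error(dbm_anova(dplyr::filter(pv, modality == "m1")),
               class = "cadmrmc_input_error")
  expect_error(dbm_anova(pv[-1, ]), "incomplete")
})

test_that("analyze_study assembles both reading conditions end to end", {
  st <- simulate_study(small_config(n_readers = 3), seed = 21)
  rep <- suppressMessages(analyze_study(st))
  expect_s3_class(rep, "study_report")
  expect_named(rep$mrmc, c("auc", "pauc", "sens_at_spec"))
  expect_identical(nrow(rep$foms), 6L)   # 2 modalities x 3 readers
  # DBM estimates equal the per-reader empirical FOMs
  auc_tidy <- tidy(rep$mrmc$auc)
  for (mm in c("unaided", "cad_validated")) {
    joined <- dplyr::inner_join(
      auc_tidy[auc_tidy$reader_id != "pooled" & auc_tidy$modality == mm, ],
      rep$foms[rep$foms$modality == mm, ],
      by = "reader_id")
    expect_equal(joined$estimate, joined$auc_empirical, tolerance = 1e-10)
  }
  # table1 layout: one row per FOM kind per reader plus pooled
  expect_identical(nrow(rep$table1), 3L * 4L)
  expect_true(all(c("delta_se", "p_value") %in% names(rep$table1)))
})

test_that("an oracle CAD with FP-free readers leaves both arms identical", {
  cfg <- small_config(n_readers = 2, reader_fp_rate = 0, reader_jitter_sd = 0.5,
                      cad_fp_rate = 0, cad_jitter_sd = 0, cad_offset_prob = 0,
                      cad_single_volume_prob = 0, multi_volume_fraction = 0,
                      cad_sensitivity = 1, cad_benign_sensitivity = 1,
                      cad_conspicuity_wt = 0)
  st <- simulate_study(cfg, seed = 9)
  rep <- suppressMessages(analyze_study(st))
  for (kind in names(rep$mrmc)) {
    expect_equal(rep$mrmc[[kind]]$difference$estimate, 0, tolerance = 1e-12)
    expect_equal(rep$mrmc[[kind]]$difference$p_value, 1)
  }
})

test_that("pooled confidence intervals cover a known true FOM", {
  # latent model with known population FOM: reader effects shift both
  # classes of a reader equally and cancel in the ranks, so
  # theta = pnorm(delta / sqrt(2 * (sC2 + sRC2 + se2)))
  delta <- 1.2; sC2 <- 0.3; sRC2 <- 0.2; se2 <- 0.2
  theta_true <- pnorm(delta / sqrt(2 * (sC2 + sRC2 + se2)))
  r <- 4; nd <- 20; nn <- 40
  cls <- rep(c("diseased", "nondiseased"), c(nd, nn))
  mu <- ifelse(cls == "diseased", delta, 0)
  ids <- sprintf("k%03d", seq_len(nd + nn))
  set.seed(606060)
  covered <- 0L; n_rep <- 300L
  for (s in seq_len(n_rep)) {
    C <- rnorm(nd + nn, sd = sqrt(sC2))
    pv <- purrr::map_dfr(1:2, function(i) {
      purrr::map_dfr(seq_len(r), function(j) {
        x <- mu + C + rnorm(nd + nn, sd = sqrt(sRC2)) + rnorm(1, sd = 0.1) +
          rnorm(nd + nn, sd = sqrt(se2))
        sc <- tibble::tibble(reader_id = paste0("r", j), case_id = ids,
                             class = cls, score = x)
        dplyr::mutate(jackknife_pseudovalues(sc),
                      modality = paste0("m", i), reader_id = paste0("r", j))
      })
    })
    po <- dbm_anova(pv)$pooled
    covered <- covered +
      (po$ci_lo[1] <= theta_true && theta_true <= po$ci_hi[1])
  }
  expect_gte(covered / n_rep, 0.90)
  expect_lte(covered / n_rep, 0.98)
})
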