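test_that("titration converges to the latent onset from below", {
  # coarse sweep stops at 100, refinement ascends 82, 84, ..., records 96
  r <- simulate_titration(95, 0.3)
  expect_equal(r$status, "threshold")
  expect_equal(r$amplitude, 96)
  # first coarse level stimulates; fine scan starts at one fine step
  r <- simulate_titration(15, 0.3)
  expect_equal(r$amplitude, 16)
  # unreachable latent threshold is censored (cap 90 at 0.1 ms)
  r <- simulate_titration(250, 0.1)
  expect_equal(r$status, "no_pns")
  expect_true(is.na(r$amplitude))
  # the cap itself is tested even when off the coarse grid
  expect_equal(simulate_titration(85, 0.1)$amplitude, 86)
  expect_equal(simulate_titration(90, 0.1)$amplitude, 90)
})

test_that("deterministic titration bias is within one fine step", {
  set.seed(31)
  prot <- protocol_config()
  env <- hardware_envelope()
  for (i in 1:300) {
    tau <- sample(c(0.1, 0.22, 0.3, 0.5), 1)
    t_star <- runif(1, 0.5, 260)
    cap <- hardware_max_amplitude(tau, env)
    r <- simulate_titration(t_star, tau, prot, env)
    if (t_star > cap) {
      expect_equal(r$status, "no_pns")
    } else {
      expect_equal(r$status, "threshold")
      expect_gte(r$amplitude - t_star, 0)
      expect_lt(r$amplitude - t_star, prot$fine_step)
      expect_lte(r$amplitude, cap)
    }
  }
})

test_that("the generated cohort is a deterministic function of the config", {
  cfg <- cohort_sim_config(n_subjects = 8, seed = 99, z_offsets = c(0, 2))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$measurements, c2$measurements)
  c3 <- simulate_cohort(cohort_sim_config(n_subjects = 8, seed = 100,
                                          z_offsets = c(0, 2)))
  expect_false(identical(c1$measurements, c3$measurements))
})

test_that("a degenerate population collapses to one latent curve", {
  cfg <- cohort_sim_config(n_subjects = 5, seed = 3, dgmin_sd = 0,
                           srmin_sd = 0, age_effect = 0, sex_effect = 0)
  pop <- sample_population(cfg)
  expect_equal(unique(pop$a), cfg$dgmin_mean)
  expect_equal(unique(pop$b), cfg$srmin_mean)
  coh <- simulate_cohort(cfg)
  per_cell <- tapply(coh$measurements$amplitude_mTm,
                     coh$measurements$rise_time_ms,
                     function(x) length(unique(x)))
  expect_true(all(per_cell == 1))
})

test_that("latent thresholds are linear in rise time and offset", {
  cfg <- cohort_sim_config(z_effect = 20)
  subj <- list(a = 60, b = 150)
  expect_equal(latent_threshold(subj, 0.3, 0, cfg), 105)
  expect_equal(latent_threshold(subj, 0.3, 2, cfg), 145)
  cfg0 <- cohort_sim_config(z_effect = 0)
  expect_equal(latent_threshold(subj, 0.3, 4, cfg0),
               latent_threshold(subj, 0.3, 0, cfg0))
})

test_that("population sampling matches its configured distribution", {
  cfg <- cohort_sim_config(n_subjects = 10000, seed = 42, dgmin_mean = 60,
                           dgmin_sd = 10)
  pop <- sample_population(cfg)
  expect_lt(abs(mean(pop$a) - 60), 0.5)
  expect_true(all(pop$a > 0))
  expect_true(all(pop$b > 0))
  expect_true(all(pop$age_years >= 18 & pop$age_years <= 100))
})

test_that("written tables round-trip through the reader with a manifest", {
  cfg <- cohort_sim_config(n_subjects = 6, seed = 5, z_offsets = c(0, 4))
  td <- withr::local_tempdir()
  coh <- generate_cohort_tables(cfg, td)
  expect_true(all(file.exists(file.path(td, c("subjects.csv",
                                              "measurements.csv",
                                              "manifest.json")))))
  back <- read_cohort(file.path(td, "subjects.csv"),
                      file.path(td, "measurements.csv"),
                      envelope = cfg$envelope)
  expect_identical(back$measurements, coh$measurements)
  # byte-identical on regeneration
  td2 <- withr::local_tempdir()
  generate_cohort_tables(cfg, td2)
  expect_identical(readLines(file.path(td, "measurements.csv")),
                   readLines(file.path(td2, "measurements.csv")))
  man <- jsonlite::read_json(file.path(td, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  # recorded minus latent is within [0, fine_step) for uncensored rows
  m <- coh$measurements
  pop <- coh$truth$population
  for (i in which(m$status == "threshold")) {
    s <- pop[pop$subject_id == m$subject_id[i], ]
    t_star <- latent_threshold(s, m$rise_time_ms[i], m$z_offset_cm[i], cfg)
    expect_gte(m$amplitude_mTm[i] - t_star, 0)
    expect_lt(m$amplitude_mTm[i] - t_star, cfg$protocol$fine_step)
  }
})

test_that("logistic response mode censors like the deterministic mode when steep", {
  set.seed(8)
  # near-deterministic response: very steep logistic
  r <- simulate_titration(95, 0.3, response = "logistic", kappa = 50)
  expect_equal(r$status, "threshold")
  expect_lt(abs(r$amplitude - 95), 6)
  expect_error(cohort_sim_config(response = "logistic", kappa = 0), "kappa")
})
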