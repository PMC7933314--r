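test_that("partition model reproduces hand-evaluated dose chains", {
  # uniform limit: TNR = 1, no shunt -> both compartments at 49.67/1.03 Gy/kg
  d <- partition_dose(1, 100, 900, tnr = 1, hps = 0)
  expect_equal(d$dose_tumor_gy, 49.67 / 1.03, tolerance = 1e-12)
  expect_equal(d$dose_normal_gy, 49.67 / 1.03, tolerance = 1e-12)

  # zero activity
  d0 <- partition_dose(0, 100, 900, tnr = 2, hps = 0.1)
  expect_equal(c(d0$dose_tumor_gy, d0$dose_normal_gy, d0$dose_lung_gy),
               c(0, 0, 0))

  # independent hand evaluation of the full chain at study-scale TNR/HPS
  m_t <- 100 * 1.03 / 1000; m_n <- 900 * 1.03 / 1000
  a_h <- 1 * (1 - 0.069)
  a_t <- a_h * (2.6 * m_t) / (2.6 * m_t + m_n)
  a_n <- a_h - a_t
  d <- partition_dose(1, 100, 900, tnr = 2.6, hps = 0.069)
  expect_equal(d$dose_tumor_gy, 49.67 * a_t / m_t, tolerance = 1e-12)
  expect_equal(d$dose_normal_gy, 49.67 * a_n / m_n, tolerance = 1e-12)
  expect_equal(d$dose_lung_gy, 49.67 * 0.069 / 1.0, tolerance = 1e-12)
  expect_equal(round(d$dose_tumor_gy, 1), 100.6)
  expect_equal(round(d$dose_normal_gy, 1), 38.7)
})

test_that("uniform_dose matches its closed form and the TNR=1 partition", {
  expect_equal(uniform_dose(1, 1000, 0), 49.67 / 1.03, tolerance = 1e-12)
  expect_equal(round(uniform_dose(1, 957, 0), 1), 50.4)
  expect_equal(uniform_dose(2, 500, 1), 0)
  expect_error(uniform_dose(1, 0), "positive")

  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 0.1, 4); vt <- runif(1, 10, 400); vn <- runif(1, 100, 2000)
    h <- runif(1, 0, 0.3)
    p <- partition_dose(a, vt, vn, tnr = 1, hps = h)
    u <- uniform_dose(a, vt + vn, h)
    expect_equal(p$dose_tumor_gy, u, tolerance = 1e-9)
    expect_equal(p$dose_normal_gy, u, tolerance = 1e-9)
  }
})

test_that("activity is conserved and doses move monotonically", {
  set.seed(99)
  for (i in 1:1000) {
    a <- runif(1, 0, 5); vt <- runif(1, 1, 500); vn <- runif(1, 50, 2500)
    tnr <- runif(1, 0.2, 8); h <- runif(1, 0, 0.5)
    d <- partition_dose(a, vt, vn, tnr, h)
    expect_lt(abs(d$activity_tumor_gbq + d$activity_normal_gbq +
                  d$activity_lung_gbq - a), 1e-9)
    expect_gte(d$dose_tumor_gy, 0)
    expect_gte(d$dose_normal_gy, 0)
  }
  # monotonicity sweeps at fixed other inputs
  base <- function(tnr, vt) partition_dose(1.5, vt, 800, tnr, 0.05)
  tnrs <- seq(0.5, 6, length.out = 40)
  dt <- vapply(tnrs, function(t) base(t, 150)$dose_tumor_gy, 0)
  dn <- vapply(tnrs, function(t) base(t, 150)$dose_normal_gy, 0)
  expect_true(all(diff(dt) > 0))
  expect_true(all(diff(dn) < 0))
  vts <- seq(20, 600, length.out = 40)
  dt_v <- vapply(vts, function(v) base(2.6, v)$dose_tumor_gy, 0)
  expect_true(all(diff(dt_v) < 0))
})

test_that("prescription rules land exactly on their binding constraints", {
  # cirrhotic with spared volume 30% -> normal dose capped at 40 Gy
  pol <- prescription_policy(cirrhotic = TRUE)
  p <- prescribe_activity(pol, tumor_ml = 200, normal_ml = 850,
                          whole_liver_ml = 1500, tnr = 2.6, hps = 0.069)
  expect_equal(p$rule, "safety_cap")
  expect_lt(abs(p$dose_report$dose_normal_gy - 40), 1e-6)

  # non-cirrhotic small target -> tumor dose just above 100 Gy
  pol2 <- prescription_policy(cirrhotic = FALSE)
  p2 <- prescribe_activity(pol2, tumor_ml = 80, normal_ml = 370,
                           whole_liver_ml = 1500, tnr = 3, hps = 0.05)
  expect_equal(p2$rule, "tumoricidal")
  expect_gt(p2$dose_report$dose_tumor_gy, 100)
  expect_lt(abs(p2$dose_report$dose_tumor_gy - 100), 1e-5)

  # intermediate case never exceeds the cap
  pol3 <- prescription_policy(cirrhotic = TRUE)
  p3 <- prescribe_activity(pol3, tumor_ml = 300, normal_ml = 600,
                           whole_liver_ml = 2500, tnr = 2, hps = 0)
  expect_equal(p3$rule, "combined")
  expect_lte(p3$dose_report$dose_normal_gy, 40 + 1e-9)

  expect_error(prescribe_activity(pol, 800, 900, 1500, 2, 0), "exceeds")
})

test_that("tumoricidal activity decreases as TNR increases", {
  pol <- prescription_policy(cirrhotic = FALSE)
  presc <- function(tnr) prescribe_activity(pol, 100, 500, 2000, tnr,
                                            0.05)$activity_gbq
  tnrs <- seq(1, 6, by = 0.5)
  a <- vapply(tnrs, presc, 0)
  expect_true(all(diff(a) < 0))
  # grid-search oracle at one TNR: the returned activity is the smallest on
  # a fine grid achieving the tumoricidal floor
  grid <- seq(0.01, 5, by = 0.001)
  dt <- vapply(grid, function(g)
    partition_dose(g, 100, 500, 3, 0.05)$dose_tumor_gy, 0)
  oracle <- grid[which(dt > 100)[1]]
  expect_lt(abs(presc(3) - oracle), 0.001)
})

test_that("activity splitting is proportional to perfused tumor volume", {
  expect_equal(unname(split_activity(c(32, 68), 1.0)), c(0.32, 0.68))
  expect_equal(unname(split_activity(c(50, 50), 1.0)), c(0.5, 0.5))
  expect_equal(unname(split_activity(120, 2.4)), 2.4)
  expect_error(split_activity(c(0, 0), 1), "zero")
  s <- split_activity(c(10, 25, 65), 1.85)
  expect_equal(sum(s), 1.85)
})

test_that("percent change follows its definition and sign convention", {
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(50, 100), -50)
  expect_equal(percent_change(82, 100), -18)
  expect_equal(percent_change(110, 100), 10)
  expect_error(percent_change(50, 0), "positive")
})

test_that("modality dose table compares each modality against the reference", {
  one <- data.frame(patient_id = 1, tumor_ml = 50, tnr = 2, hps = 0,
                    tgv_cect_ml = 800, tgv_cbct_ml = NA, tgv_maa_ml = 800,
                    tgv_pet_ml = 957)
  tab <- modality_dose_table(one)
  d_mod <- partition_dose(1, 50, 800 - 50, 2, 0)
  d_ref <- partition_dose(1, 50, 957 - 50, 2, 0)
  got <- tab[tab$modality == "maa", ]
  expect_equal(got$dose_tumor_gy, d_mod$dose_tumor_gy, tolerance = 1e-12)
  expect_equal(got$pct_change_tumor,
               100 * (d_ref$dose_tumor_gy - d_mod$dose_tumor_gy) /
                 d_mod$dose_tumor_gy, tolerance = 1e-12)

  # identical volumes -> all percent changes zero
  same <- data.frame(patient_id = 1:3, tumor_ml = 40, tnr = 2.6, hps = 0.05,
                     tgv_cect_ml = c(500, 700, 900),
                     tgv_cbct_ml = c(500, 700, 900),
                     tgv_maa_ml = c(500, 700, 900),
                     tgv_pet_ml = c(500, 700, 900))
  tab2 <- modality_dose_table(same)
  plan <- tab2$modality != "reference"
  expect_true(all(abs(tab2$pct_change_tumor[plan]) < 1e-12))

  # a modality TgV not exceeding the tumor volume is excluded and logged
  bad <- data.frame(patient_id = 1, tumor_ml = 600, tnr = 2, hps = 0,
                    tgv_cect_ml = 500, tgv_cbct_ml = NA, tgv_maa_ml = 800,
                    tgv_pet_ml = 900)
  tab3 <- modality_dose_table(bad)
  expect_false("cect" %in% tab3$modality)
  excl <- attr(tab3, "excluded")
  expect_equal(excl$modality, "cect")
})
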