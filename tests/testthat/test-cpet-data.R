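test_that("work rate follows the staged protocol", {
  nom <- cpet_protocol("nominal")
  lgt <- cpet_protocol("light")
  expect_equal(work_rate_at_time(100, nom), 50)
  expect_equal(work_rate_at_time(200, nom), 75)
  expect_equal(work_rate_at_time(200, lgt), 60)
  expect_equal(work_rate_at_time(180, nom), 50)  # boundary still warm-up
  expect_error(work_rate_at_time(-1, nom), "non-negative")

  # non-decreasing, piecewise constant, jumps exactly one increment
  t <- seq(0, 1200, by = 5)
  w <- work_rate_at_time(t, nom)
  jumps <- diff(w)
  expect_true(all(jumps >= 0))
  expect_true(all(jumps %in% c(0, nom$increment)))
})

test_that("protocol round-trips through the plain-text run config", {
  p <- cpet_protocol("custom", warmup_watts = 60, warmup_duration = 120,
                     increment = 20, stage_duration = 30)
  f <- withr::local_tempfile(fileext = ".txt")
  write_protocol(p, f)
  q <- read_protocol(f)
  expect_equal(q$warmup_watts, 60)
  expect_equal(q$increment, 20)
  expect_equal(read_protocol({
    g <- withr::local_tempfile()
    write_protocol(cpet_protocol("light"), g)
    g
  })$increment, 15)
})

test_that("series CSV round-trip is bit-identical and validation catches bad grids", {
  set.seed(3)
  s <- make_series(vo2 = runif(60, 0.5, 3.5), hr = 90 + seq_len(60),
                   protocol = cpet_protocol("nominal"))
  expect_equal(nrow(s), 60)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cpet_csv(s, f)
  s2 <- read_cpet_csv(f)
  for (ch in c("time", "vo2", "vco2", "ve", "hr", "rer", "work")) {
    expect_identical(s2[[ch]], s[[ch]])
  }
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cpet_csv(s2, f2)
  expect_identical(readLines(f2), readLines(f))

  # broken grid at a named row
  bad <- data.frame(time = c(seq(10, 110, 10), 115, seq(125, 175, 10)),
                    vo2 = rep(1, 18), vco2 = rep(0.9, 18), ve = rep(20, 18))
  fb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE)
  expect_error(read_cpet_csv(fb), "row 12")

  # missing mandatory column is named
  fb2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad[c("time", "vo2", "vco2")], fb2, row.names = FALSE)
  expect_error(read_cpet_csv(fb2), "ve")
})

test_that("vendor columns can be mapped onto the canonical names", {
  d <- data.frame(`Time (sec)` = seq(10, 100, 10), `VO2 STPD` = rep(2, 10),
                  `VCO2 STPD` = rep(1.8, 10), `VE BTPS` = rep(45, 10),
                  check.names = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE)
  s <- read_cpet_csv(f, col_map = c(time = "Time (sec)", vo2 = "VO2 STPD",
                                    vco2 = "VCO2 STPD", ve = "VE BTPS"))
  expect_s3_class(s, "cpet_series")
  expect_equal(s$ve[1], 45)
})

test_that("warm-up exclusion keeps exactly the post-warm-up samples", {
  nom <- cpet_protocol("nominal")
  s <- make_series(vo2 = rep(2, 60))  # 600 s test
  post <- exclude_warmup(s, nom)
  expect_equal(nrow(post), 42)
  expect_equal(post$time[1], 190)
  expect_equal(nrow(post) + sum(s$time <= nom$warmup_duration), nrow(s))

  p0 <- cpet_protocol("custom", warmup_watts = 50, warmup_duration = 1e-9,
                      increment = 25, stage_duration = 60)
  expect_equal(nrow(exclude_warmup(s, p0)), nrow(s))

  short <- make_series(vo2 = rep(2, 15))  # 150 s < warm-up
  expect_error(exclude_warmup(short, nom), "warm-up")
})

test_that("maximal-effort criteria count to a 4-of-5 verdict", {
  expect_equal(predicted_hrmax(40), 180.2)
  s <- make_series(vo2 = seq(1, 3.5, length.out = 40),
                   hr = seq(100, 172, length.out = 40),
                   rpe = c(rep(NA, 39), 19), subject_age = 40)
  # peak RER here is 0.9 -> criterion 1 fails; HR 172 >= 180.2 - 10 passes
  v <- check_maximality(s, plateau = TRUE, rpm_fall = TRUE)
  expect_equal(v$n_met, 4)
  expect_true(v$maximal)
  expect_equal(v$predicted_hrmax, 180.2)

  v3 <- check_maximality(s, plateau = FALSE, rpm_fall = TRUE)
  expect_equal(v3$n_met, 3)
  expect_false(v3$maximal)

  # all five criteria
  s5 <- make_series(vo2 = rep(2, 40), vco2 = rep(2.56, 40),
                    hr = rep(175, 40), rpe = rep(19, 40), subject_age = 40)
  v5 <- check_maximality(s5, plateau = TRUE, rpm_fall = TRUE)
  expect_equal(v5$n_met, 5)

  # missing channels degrade gracefully
  s_min <- make_series(vo2 = rep(2, 40))
  expect_false(check_maximality(s_min)$maximal)
})
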