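# Scenario construction, outcome classification, ensemble statistics.

test_that("scenario presets encode the documented challenge schedules", {
  g <- scenario("gram_negative")
  expect_equal(nrow(g$config$injections), 1L)
  expect_true(g$config$injections$has_lps)
  expect_equal(g$config$injections$step, 0L)
  expect_gt(g$config$ag_replication, 0)

  v <- scenario("vaccine_il4")
  inj <- v$config$injections
  expect_false(any(inj$has_lps))
  expect_equal(v$config$ag_replication, 0)
  il4 <- inj[inj$species == "IL4", ]
  expect_equal(nrow(il4), 7L)                     # daily for a week
  expect_equal(min(il4$step), 3L * v$config$steps_per_day)  # from day 3
  expect_equal(diff(sort(il4$step)),
               rep(v$config$steps_per_day, 6L))

  b <- scenario("bacterium_il10", il10_dose = 999)
  inj_b <- b$config$injections
  expect_true(inj_b$has_lps[inj_b$species == "Ag"])
  expect_equal(nrow(inj_b[inj_b$species == "IL10", ]), 7L)
  expect_true(all(inj_b$amount[inj_b$species == "IL10"] == 999L))

  # volume scaling preserves densities
  b2 <- scenario("bacterium_il10", L = 8)
  expect_equal(unname(b2$config$cells["mac"]), round(500 / 8))
  expect_equal(b2$config$injections$amount[1], round(4000 / 8))
})

test_that("outcome classification follows the antigen-control criterion", {
  expect_equal(classify_outcome(make_fixture("timeseries",
                                             pattern = "controlled")),
               "controlled")
  expect_equal(classify_outcome(make_fixture("timeseries",
                                             pattern = "dampened")),
               "dampened")
  empty <- make_fixture("timeseries")[0, ]
  expect_error(classify_outcome(empty), "empty")
})

test_that("dampened fraction is the share of uncontrolled replicates", {
  expect_equal(dampened_fraction(rep("controlled", 5)), 0)
  expect_equal(dampened_fraction(c(rep("dampened", 43), rep("controlled", 57))),
               0.43)
  expect_equal(dampened_fraction("dampened"), 1)
  expect_error(dampened_fraction(character()), "no replicates")
})

test_that("a single-replicate ensemble has mean equal to its series, sd zero", {
  scn <- scenario("gram_negative", L = 6, n_steps = 30,
                  cells = c(mac = 30L, b = 40L, h1 = 40L, h2 = 40L, hr = 40L))
  ens <- run_scenario(scn, n_replicates = 1, base_seed = 10)
  config <- scn$config
  config$seed <- 11L  # base_seed + r
  ts <- simulate_run(config)
  expect_equal(as.matrix(ens$mean[, -1]), as.matrix(as.data.frame(ts)[, -1]),
               ignore_attr = TRUE)
  expect_true(all(ens$sd[, -1] == 0))
  expect_length(ens$outcomes, 1L)
})

test_that("ensemble aggregation matches replicate-level statistics", {
  scn <- scenario("gram_negative", L = 6, n_steps = 20,
                  cells = c(mac = 20L, b = 30L, h1 = 30L, h2 = 30L, hr = 30L))
  ens <- run_scenario(scn, n_replicates = 4, base_seed = 1, keep_series = TRUE)
  m <- sapply(ens$replicates, function(ts) as.data.frame(ts)$Ag_lps)
  expect_equal(ens$mean$Ag_lps, rowMeans(m))
  expect_equal(ens$sd$Ag_lps, apply(m, 1, stats::sd))
  expect_equal(dampened_fraction(ens) + mean(ens$outcomes == "controlled"), 1)
})

test_that("ensemble outputs serialize to the documented directory layout", {
  scn <- scenario("gram_negative", L = 6, n_steps = 10,
                  cells = c(mac = 10L, b = 10L, h1 = 10L, h2 = 10L, hr = 10L))
  ens <- run_scenario(scn, n_replicates = 2, base_seed = 3)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, c("mean.csv", "sd.csv",
                                               "outcomes.csv",
                                               "summary.json")))))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$n_replicates, 2L)
  out <- utils::read.csv(file.path(dir, "outcomes.csv"))
  expect_equal(out$seed, c(4L, 5L))
})

test_that("calibration grid is validated and selection responds to pilots", {
  expect_error(calibrate_dampening(doses = 1:11), "1..10")
  # a tiny desk calibration: 3 doses, few pilots, reduced lattice and horizon
  cal <- calibrate_dampening(doses = c(200, 1500, 4000), n_pilot = 4,
                             base_seed = 2, L = 8, n_steps = 100)
  expect_s3_class(cal, "mp_calibration")
  expect_true(cal$dose >= 200 && cal$dose <= 4000)
  expect_equal(nrow(cal$grid), 3L)
})
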