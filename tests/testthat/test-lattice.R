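# Lattice orchestration: initialization, diffusion, stepping, determinism.

test_that("initial population respects configured counts and states", {
  config <- small_config()
  set.seed(config$seed)
  lat <- init_population(config)
  ag <- lat$agents
  expect_equal(unname(table(factor(ag$kind, levels = 1:5))),
               unname(config$cells), ignore_attr = TRUE)
  # macrophages: resting, M0, naive network state
  expect_true(all(ag$act[ag$kind == 1] == 1L))
  expect_true(all(ag$phen == 0L))
  expect_true(all(ag$grn == 0L))
  # B cells active, helpers resting at the all-resting default
  expect_true(all(ag$act[ag$kind == 2] == 2L))
  expect_true(all(ag$act[ag$kind >= 3] == 1L))
  expect_true(all(ag$site >= 0 & ag$site < config$L^3))
  # the step-0 antigen dose is in the first census row
  expect_equal(unname(lat$census[1, "Ag_lps"]), 300L)
  # a configured active fraction is honoured
  config2 <- small_config(helper_active_frac = 0.5)
  set.seed(1)
  lat2 <- init_population(config2)
  h <- lat2$agents[lat2$agents$kind >= 3, ]
  expect_equal(sum(h$act == 2L), round(nrow(h) / 2), tolerance = 2)
})

test_that("an empty configuration yields an empty lattice", {
  config <- simulation_config(L = 4, n_steps = 5, seed = 1,
                              cells = c(mac = 0L, b = 0L, h1 = 0L, h2 = 0L,
                                        hr = 0L))
  ts <- simulate_run(config)
  expect_equal(nrow(ts), 6L)
  expect_true(all(as.matrix(ts[, -1]) == 0L))
})

test_that("diffusion conserves every entity and stays on the lattice", {
  config <- small_config()
  set.seed(1)
  lat <- init_population(config)
  before_agents <- nrow(lat$agents)
  before_mol <- colSums(lat$mol)
  lat2 <- diffuse(lat)
  expect_equal(nrow(lat2$agents), before_agents)
  expect_equal(colSums(lat2$mol), before_mol)
  expect_true(all(lat2$agents$site >= 0 & lat2$agents$site < config$L^3))
})

test_that("walkers equilibrate to the uniform distribution on the torus", {
  set.seed(21)
  L <- 4L
  sites <- rep(0L, 4000L)   # all walkers start at the origin
  for (i in 1:60) sites <- macpol:::.diffuse_sites_cpp(sites, L)
  visits <- tabulate(sites + 1L, L^3)
  p <- stats::chisq.test(visits)$p.value
  expect_gt(p, 1e-4)
})

test_that("identical config and seed give byte-identical output", {
  config <- small_config()
  ts1 <- simulate_run(config)
  ts2 <- simulate_run(config)
  expect_identical(as.data.frame(ts1), as.data.frame(ts2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts1, f1)
  write_timeseries(ts2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed diverges
  config3 <- config; config3$seed <- 2L
  ts3 <- simulate_run(config3)
  expect_false(identical(as.data.frame(ts1), as.data.frame(ts3)))
})

test_that("zero-step runs return exactly the initial census", {
  config <- small_config(n_steps = 0L)
  ts <- simulate_run(config)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$step, 0L)
  expect_equal(ts$Ag_lps, 300L)
})

test_that("a co-located resting macrophage and IFNg token react in one step", {
  lat <- make_fixture("micro_lattice", L = 2,
                      agents = data.frame(kind = "Macrophage",
                                          activation = "resting"),
                      molecules = c(IFNg = 1L))
  set.seed(3)
  lat2 <- sim_step(lat)
  expect_equal(unname(lat2$census[2, "M0_a"]), 1L)
  expect_equal(unname(lat2$census[2, "IFNg"]), 0L)
})

test_that("macrophage totals are conserved across a run", {
  config <- small_config(n_steps = 80L)
  ts <- simulate_run(config)
  mac <- rowSums(ts[, c("M0_r", "M0_a", "M0_p", "M1_r", "M1_a", "M1_p",
                        "M2_r", "M2_a", "M2_p")])
  expect_true(all(mac == mac[1]))
  hr <- rowSums(ts[, c("Hr_r", "Hr_a")])
  expect_true(all(hr == hr[1]))  # Tregs never duplicate
})
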