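# The synchronous Boolean layer: update map, clamping, iteration, exact
# fixed-point enumeration and M1/M2 classification.

net <- default_network()

test_that("update map: activation requires an active activator and no inhibitor", {
  zero <- network_state(net)
  expect_identical(boolean_update(zero, net), zero)
  # a lone active receptor hands its signal downstream and decays itself
  s <- boolean_update(network_state(net, "IFNgR"), net)
  expect_setequal(active_nodes(s), "STAT1")
  # an active inhibitor vetoes activation: STAT1 with SOCS1 on stays silenced
  s2 <- boolean_update(network_state(net, c("IFNgR", "SOCS1")), net)
  expect_false(s2[["STAT1"]])
  # misaligned state is refused
  expect_error(boolean_update(logical(3), net), "aligned")
})

test_that("input clamping overwrites exactly the four stimulus bits", {
  zero <- network_state(net)
  expect_identical(apply_input(zero, input_vector(), net), zero)
  s <- apply_input(zero, input_vector(IFNg = TRUE), net)
  expect_setequal(active_nodes(s), "IFNg")
  s2 <- apply_input(network_state(net, "STAT6"), input_vector(IL4 = TRUE), net)
  expect_true(s2[["STAT6"]])
  expect_true(s2[["IL4"]])
  expect_equal(sum(s2), 2L)
  # clamping also turns stimuli off
  s3 <- apply_input(network_state(net, c("IFNg", "STAT1")), input_vector(), net)
  expect_setequal(active_nodes(s3), "STAT1")
})

test_that("iterated clamped dynamics reach the documented attractors", {
  zero <- network_state(net)
  x1 <- iterate(zero, input_vector(IFNg = TRUE, LPS = TRUE), 6, net)
  expect_setequal(active_nodes(x1),
                  c("IFNg", "LPS", "IFNgR", "TLR4", "STAT1", "SOCS3",
                    "NF-kB", "NOS2"))
  expect_equal(classify(x1, net), "M1_committed")
  x2 <- iterate(zero, input_vector(IL4 = TRUE), 6, net)
  expect_setequal(active_nodes(x2),
                  c("IL4", "IL4Ra", "STAT6", "PPARg", "SOCS1", "KLF4", "Arg1"))
  expect_equal(classify(x2, net), "M2_committed")
  # a fixed point is invariant under further iteration, for any k
  for (k in c(1, 3, 10))
    expect_identical(iterate(x1, input_vector(IFNg = TRUE, LPS = TRUE), k, net),
                     x1)
  expect_error(iterate(zero, input_vector(), 0, net), "positive")
})

test_that("transition table agrees with the pure-R update on random states", {
  tab <- transition_table(net)
  set.seed(11)
  n <- length(net$nodes)
  for (i in 1:200) {
    s <- structure(stats::runif(n) < 0.4, names = net$nodes)
    via_r <- boolean_update(s, net)
    code <- sum(as.integer(s) * 2^(seq_len(n) - 1))
    via_tab <- tab[code + 1]
    expect_equal(sum(as.integer(via_r) * 2^(seq_len(n) - 1)), via_tab)
  }
})

test_that("monotone absence: no active activator forces inactivity", {
  set.seed(12)
  n <- length(net$nodes)
  for (i in 1:100) {
    s <- structure(stats::runif(n) < 0.3, names = net$nodes)
    nxt <- boolean_update(s, net)
    for (node in net$nodes[net$role != "input"]) {
      act <- net$activators[[node]]
      if (length(act) == 0L || !any(s[act]))
        expect_false(nxt[[node]])
    }
  }
})

test_that("fixed-point enumeration matches the brute-force single-step oracle", {
  toy <- toy_network()
  for (ival in c(FALSE, TRUE)) {
    I <- c(IN = ival)
    got <- enumerate_fixed_points(toy, I)
    want <- brute_fixed_points(toy, I)
    expect_setequal(
      vapply(got, function(s) paste(active_nodes(s), collapse = "+"), ""),
      vapply(want, function(s) paste(active_nodes(s), collapse = "+"), ""))
  }
  # default network, documented regimes
  fp0 <- enumerate_fixed_points(net, input_vector())
  expect_true(0L %in% attr(fp0, "codes"))  # the all-zero state is fixed
  att <- attractors(net)
  fp_m1 <- enumerate_fixed_points(net, input_vector(IFNg = TRUE, LPS = TRUE))
  labs <- vapply(fp_m1, classify, "", net = net)
  expect_equal(sum(labs == "M1_committed"), 1L)
  expect_equal(sum(labs == "M2_committed"), 0L)
  fp_m2 <- enumerate_fixed_points(net, input_vector(IL10 = TRUE, IL4 = TRUE))
  labs2 <- vapply(fp_m2, classify, "", net = net)
  expect_equal(sum(labs2 == "M2_committed"), 1L)
  expect_equal(sum(labs2 == "M1_committed"), 0L)
  expect_error(enumerate_fixed_points(make_fixture("random_network",
                                                   n_nodes = 30), c(IN1 = TRUE, IN2 = TRUE)),
               "refus|large")
})

test_that("classification is exclusive and zero is uncommitted", {
  att <- attractors(net)
  # marker fixed points are disjoint across all stimuli
  expect_length(intersect(stats::na.omit(att$m1_fp), stats::na.omit(att$m2_fp)), 0L)
  expect_equal(classify(network_state(net), net), "uncommitted")
  set.seed(13)
  for (i in 1:100) {
    s <- structure(stats::runif(18) < 0.5, names = net$nodes)
    expect_true(classify(s, net) %in%
                  c("M1_committed", "M2_committed", "uncommitted"))
  }
})

test_that("limit cycles are detected and reported, never classified", {
  cyc <- cyclic_network()
  res <- iterate_until_convergence(network_state(cyc, "A"), c(IN = TRUE), cyc)
  expect_false(res$converged)
  expect_gte(length(res$cycle), 2L)
  # the default network always converges from the naive state
  res2 <- iterate_until_convergence(network_state(net),
                                    input_vector(IFNg = TRUE, LPS = TRUE), net)
  expect_true(res2$converged)
  expect_equal(classify(res2$state, net), "M1_committed")
})

test_that("attractor report covers every stimulus with consistent labels", {
  rep <- attractor_report(net)
  expect_true(all(c("stimulus", "fixed_point", "active", "label") %in% names(rep)))
  expect_true(all(rep$label %in% c("M1", "M2", "none")))
  expect_gte(sum(rep$label == "M1"), 1L)
  expect_gte(sum(rep$label == "M2"), 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  attractor_report(net, f)
  expect_identical(utils::read.csv(f)$label, rep$label)
})
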