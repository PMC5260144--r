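# The mesoscopic contact rules and the differentiation bridge.

test_that("rule table encodes the 15 reactions with unit probabilities", {
  rules <- rule_table()
  expect_equal(nrow(rules), 15L)
  expect_true(all(rules$p == 1))
  expect_equal(rules$reactants[1], "M^r + IFNg")
  expect_equal(rules$products[15], "0")
  expect_setequal(rules$id[rules$il10_inhibited], c(2L, 5L, 8L, 14L))
  expect_error(rule_table(p = 2), "0, 1")
  expect_error(rule_table(il10_inhibited = 99), "1..15")
})

test_that("rule files round-trip; structural edits are rejected", {
  rules <- rule_table(p = c(rep(1, 14), 0.5), il10_inhibited = c(2L, 8L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, f)
  back <- read_rules(f)
  expect_equal(back$p, rules$p)
  expect_equal(back$il10_inhibited, rules$il10_inhibited)
  txt <- readLines(f)
  txt[2] <- sub("M\\^r \\+ IFNg", "M^r + IL4", txt[2])
  writeLines(txt, f)
  expect_error(read_rules(f), "structural")
})

test_that("activation and neutralisation rules fire as printed", {
  # R1: a resting macrophage consumes one IFNg and activates
  s <- site_contents(data.frame(kind = "Macrophage", activation = "resting"),
                     c(IFNg = 1L))
  set.seed(1)
  out <- apply_rules_at_site(s)
  expect_equal(out$agents$activation, "active")
  expect_equal(out$molecules[["IFNg"]], 0L)
  expect_equal(unname(attr(out, "fires")["R1"]), 1L)
  # R15: antibody and antigen annihilate pairwise
  s2 <- site_contents(molecules = c(Ab = 3L, Ag_lps = 2L))
  out2 <- apply_rules_at_site(s2)
  expect_equal(out2$molecules[["Ab"]], 1L)
  expect_equal(out2$molecules[["Ag_lps"]], 0L)
  # R2: phagocytosis consumes the antigen token
  s3 <- site_contents(data.frame(kind = "Macrophage", activation = "active"),
                      c(Ag_lps = 1L))
  repeat {  # shuffle may fire R4 (deactivation) before R2; force an R2 pass
    out3 <- apply_rules_at_site(s3)
    if (attr(out3, "fires")["R2"] == 1L) break
  }
  expect_equal(out3$agents$activation, "presenting")
  expect_equal(out3$molecules[["Ag_lps"]], 0L)
})

test_that("a consumed entity cannot participate in two rules in one step", {
  # resting macrophage + IFNg + antigen: R1 activates it, but the same-step
  # R2 must not also make it presenting, whatever the shuffle order
  s <- site_contents(data.frame(kind = "Macrophage", activation = "resting"),
                     c(IFNg = 1L, Ag_lps = 1L))
  set.seed(2)
  for (i in 1:25) {
    out <- apply_rules_at_site(s)
    expect_equal(out$agents$activation, "active")
    expect_equal(out$molecules[["Ag_lps"]], 1L)
  }
})

test_that("B-cell help duplicates and releases cytokine plus antibody", {
  s <- site_contents(data.frame(kind = c("Bcell", "Th1"),
                                activation = c("presenting", "active")))
  set.seed(3)
  repeat {  # R9/R13 may fire first in some shuffles
    out <- apply_rules_at_site(s)
    if (attr(out, "fires")["R10"] == 1L) break
  }
  expect_equal(sum(out$agents$kind == "Bcell"), 2L)
  expect_equal(sum(out$agents$kind == "Th1"), 2L)
  expect_true(all(out$agents$activation[out$agents$kind == "Bcell"] == "presenting"))
  expect_equal(out$molecules[["IFNg"]], 1L)
  expect_equal(out$molecules[["Ab"]], 1L)
})

test_that("presenting cells release cytokine once per helper pairing", {
  # R5: M^p + H1^a adds exactly one IFNg per disjoint pair
  s <- site_contents(data.frame(
    kind = c("Macrophage", "Th1", "Th1"),
    activation = c("presenting", "active", "active")))
  set.seed(4)
  fires <- replicate(40, {
    out <- apply_rules_at_site(s)
    unname(attr(out, "fires")["R5"])
  })
  expect_true(all(fires <= 1L))  # one M^p supports at most one pairing
  expect_true(any(fires == 1L))
})

test_that("IL-10 at a site vetoes presentation and IFNg release", {
  s <- site_contents(data.frame(kind = "Bcell", activation = "active"),
                     c(Ag_lps = 2L, IL10 = 1L))
  set.seed(5)
  for (i in 1:20) {
    out <- apply_rules_at_site(s)
    expect_equal(out$agents$activation, "active")     # R8 blocked
    expect_equal(out$molecules[["Ag_lps"]], 2L)
  }
  # with suppression disabled in the rule table the same site presents
  rules_off <- rule_table(il10_inhibited = integer())
  repeat {
    out2 <- apply_rules_at_site(s, rules_off)
    if (attr(out2, "fires")["R8"] == 1L) break
  }
  expect_equal(out2$agents$activation, "presenting")
})

test_that("differentiation requires activation and is terminal", {
  net <- default_network()
  m <- cell_agent("Macrophage")
  site_m1 <- site_contents(molecules = c(IFNg = 1L, Ag_lps = 1L))
  # resting macrophages do not read the network
  expect_identical(differentiation_update(m, site_m1, net), m)
  # an active M0 under sustained IFNg+LPS commits to M1
  m$activation <- "active"
  m2 <- differentiation_update(m, site_m1, net, k = 6)
  expect_equal(m2$phenotype, "M1")
  expect_equal(classify(m2$grn_state, net), "M1_committed")
  # commitment is absorbing: a committed macrophage is never updated again
  m3 <- differentiation_update(m2, site_contents(molecules = c(IL4 = 5L)), net)
  expect_identical(m3, m2)
  # IL-4 drives an active M0 to M2
  m4 <- m
  m4$grn_state <- network_state(net)
  m4 <- differentiation_update(m4, site_contents(molecules = c(IL4 = 1L)),
                               net, k = 6)
  expect_equal(m4$phenotype, "M2")
  # an empty site leaves the naive state fixed at zero forever
  m5 <- differentiation_update(m, site_contents(), net, k = 6)
  expect_equal(m5$phenotype, "M0")
  expect_equal(sum(m5$grn_state), 0L)
  expect_error(differentiation_update(cell_agent("Th1", "active"),
                                      site_contents(), net),
               "macrophages only")
})

test_that("a macrophage never reaches M1 and M2 in the same update", {
  net <- default_network()
  set.seed(6)
  for (i in 1:50) {
    mol <- c(IFNg = rbinom(1, 1, 0.5), IL10 = rbinom(1, 1, 0.5),
             IL4 = rbinom(1, 1, 0.5), Ag_lps = rbinom(1, 1, 0.5))
    m <- cell_agent("Macrophage", activation = "active")
    m$grn_state <- structure(stats::runif(18) < 0.3, names = net$nodes)
    out <- differentiation_update(m, site_contents(molecules = mol), net, k = 6)
    expect_true(out$phenotype %in% c("M0", "M1", "M2"))
  }
})
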