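# Model right-hand sides against independent transcriptions, structural
# reductions, invariant enforcement, and checkpoint variants.

test_that("model right-hand sides vanish where mass-action terms vanish", {
  p1 <- table1_parameters("model1")
  d <- model1_rhs(c(0, 0, 0))
  expect_equal(unname(d), c(p1$ksy_cycb, 0, 0))
  d2 <- model2_rhs(rep(0, 5))
  expect_equal(unname(d2), c(table1_parameters("model2")$ksy_cycb, 0, 0, 0, 0))
  d3 <- model3_rhs(rep(0, 5))
  expect_equal(unname(d3)[-1], rep(0, 4))
  d4 <- model4_rhs(rep(0, 6))
  expect_equal(unname(d4)[1:2], rep(table1_parameters("model4")$ksy_cycb, 2))
})

test_that("each rhs agrees with an independently transcribed oracle to the oracle's own conditioning", {
  set.seed(21)
  m1 <- cc_model("model1"); m2 <- cc_model("model2")
  m3 <- cc_model("model3"); m4 <- cc_model("model4")
  for (i in 1:100) {
    x1 <- random_state(m1)
    expect_equal(unname(model1_rhs(x1)), unname(oracle_rhs_model1(x1, m1$params)),
                 tolerance = 1e-12)
    x2 <- random_state(m2)
    expect_equal(unname(model2_rhs(x2)),
                 unname(oracle_rhs_model23(x2, m2$params, FALSE)), tolerance = 1e-10)
    x3 <- random_state(m3)
    expect_equal(unname(model3_rhs(x3)),
                 unname(oracle_rhs_model23(x3, m3$params, TRUE)), tolerance = 1e-10)
    x4 <- random_state(m4)
    expect_equal(unname(model4_rhs(x4)), unname(oracle_rhs_model4(x4, m4$params)),
                 tolerance = 1e-10)
  }
})

test_that("model3 with kdp2_gwl = 0 reduces exactly to model2", {
  p <- table1_parameters("model2")
  p$kdp2_gwl <- 0
  set.seed(22)
  m2 <- cc_model("model2")
  for (i in 1:25) {
    x <- random_state(m2)
    expect_identical(model3_rhs(x, params = p), model2_rhs(x))
  }
})

test_that("the flow cannot enter the unreachable region MPF > CycBT", {
  set.seed(23)
  m4 <- cc_model("model4")
  for (i in 1:25) {
    x <- random_state(m4)
    x["MPF"] <- x["CycBT"]          # on the boundary
    d <- model4_rhs(x)
    expect_gte(d[["CycBT"]] - d[["MPF"]], -1e-12)
  }
})

test_that("state invariants are enforced at evaluation", {
  expect_error(model1_rhs(c(0, 0)), "3 entries")
  expect_error(model2_rhs(c(0.1, 0.1, 0.1, 0.1, 0.5)), "APCPC20 > APCP")
  expect_error(model4_rhs(c(0.5, 0.9, 0, 0, 0, 0)), "unreachable")
  expect_error(model2_rhs(c(-0.2, 0, 0, 0, 0)), "negative")
})

test_that("steady states found by the root solver annihilate the rhs", {
  m <- cc_model("model1")
  ss <- find_steady_states(m)
  expect_gte(length(ss), 1L)
  for (s in ss) {
    expect_lt(max(abs(model1_rhs(s$state))), 1e-10)
  }
})

test_that("checkpoint scenarios touch only their own parameter", {
  m <- cc_model("model4")
  expect_identical(apply_checkpoint(m, "none"), m)
  g2 <- apply_checkpoint(m, "G2")
  expect_equal(g2$params$Cdc25_tot, 0.4)
  expect_identical(g2$params[setdiff(names(g2$params), "Cdc25_tot")],
                   m$params[setdiff(names(m$params), "Cdc25_tot")])
  sac <- apply_checkpoint(m, "SAC")
  expect_equal(sac$params$Cdc20_tot, 0.1)
  g1 <- apply_checkpoint(m, "G1")
  expect_equal(g1$params$kde3_cycb, 0.2)
  # restoring the parameter restores the rhs exactly
  restored <- apply_checkpoint(g2, checkpoint_scenario("G2", value = 1))
  set.seed(24)
  x <- random_state(m)
  expect_identical(restored$rhs(0, x, restored$params),
                   m$rhs(0, x, m$params))
  expect_error(apply_checkpoint(cc_model("model2"), "G2"), "model4")
})

test_that("the G1 variant with zero Cdh1 activity is plain model4", {
  m <- cc_model("model4")
  g1_null <- apply_checkpoint(m, checkpoint_scenario("G1", value = 0))
  set.seed(25)
  for (i in 1:10) {
    x <- random_state(m)
    expect_equal(g1_null$rhs(0, x, g1_null$params), m$rhs(0, x, m$params),
                 tolerance = 1e-15)
  }
})

test_that("clamping a state removes its equation and fixes its value", {
  m <- cc_model("model4")
  red <- clamp_state(m, "CycBT", value = 1.3)
  expect_equal(length(red$states), 5L)
  set.seed(26)
  x <- random_state(m)
  x["CycBT"] <- 1.3
  full_d <- m$rhs(0, as.numeric(x), m$params)[[1]]
  red_d <- red$rhs(0, as.numeric(x[-1]), red$params)[[1]]
  expect_equal(red_d, full_d[-1], tolerance = 1e-15)
  expect_error(clamp_state(m, "nope"), "not a state")
})
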