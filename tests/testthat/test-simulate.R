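# Integration front-end, limit-cycle measurement, arrest classification.

# Attracting circular oscillator with exactly known period 2*pi/omega,
# used to calibrate the period-measurement machinery.
make_ring_oscillator <- function(omega = 0.5) {
  structure(list(
    id = "ring", states = c("MPF", "y"),
    rhs = function(t, x, p) {
      r2 <- x[1]^2 + x[2]^2
      list(c(x[1] * (1 - r2) - p$omega * x[2],
             x[2] * (1 - r2) + p$omega * x[1]))
    },
    closures = function(x, p) numeric(0),
    params = list(omega = omega), scenario = "none"), class = "cc_model")
}

test_that("zero synthesis from the empty state stays identically zero", {
  p <- table1_parameters("model1")
  p$ksy_cycb <- 0
  tr <- cc_integrate(cc_model("model1", params = p), times = c(0, 100))
  expect_lt(max(abs(tr$states)), 1e-12)
})

test_that("halving tolerances barely moves the terminal state", {
  m <- cc_model("model1")
  a <- cc_integrate(m, times = c(0, 300), rtol = 1e-8, atol = 1e-10)
  b <- cc_integrate(m, times = c(0, 300), rtol = 5e-9, atol = 5e-11)
  rel <- max(abs(a$states[nrow(a$states), ] - b$states[nrow(b$states), ])) /
    max(abs(a$states[nrow(a$states), ]))
  expect_lt(rel, 1e-6)
})

test_that("oscillation extrema agree across independent integrators", {
  m <- cc_model("model2")
  a <- cc_integrate(m, times = c(0, 600), rtol = 1e-10, atol = 1e-12)
  b <- cc_integrate(m, times = c(0, 600), rtol = 1e-10, atol = 1e-12,
                    method = "radau")
  sel <- a$times > 300
  for (v in colnames(a$states)) {
    expect_equal(max(a$states[sel, v]), max(b$states[sel, v]),
                 tolerance = 1e-5, info = v)
    expect_equal(min(a$states[sel, v]), min(b$states[sel, v]),
                 tolerance = 1e-5, info = v)
  }
})

test_that("trajectories respect conservation bounds and positivity", {
  for (id in c("model2", "model3", "model4")) {
    m <- cc_model(id)
    p <- m$params
    tr <- cc_integrate(m, times = c(0, 800))
    expect_gte(min(tr$states), -1e-9)
    expect_lte(max(tr$states[, "GwlP"]), p$Gwl_tot + 1e-9)
    expect_lte(max(tr$states[, "ENSAP"]), p$ENSA_tot + 1e-9)
    expect_lte(max(tr$states[, "APCP"]), p$APC_tot + 1e-9)
    # the complex cannot exceed either binding partner pool; note that
    # transient APCPC20 > APCP excursions are genuine model behaviour
    # (dephosphorylation drains APC_P faster than the complex dissociates)
    expect_lte(max(tr$states[, "APCPC20"]), p$Cdc20_tot + 1e-9)
    if (id == "model4")
      expect_true(all(tr$states[, "MPF"] <= tr$states[, "CycBT"] + 1e-7))
    # the tQSSA closure keeps free plus complexed B55 at the total exactly
    expect_equal(tr$derived[, "B55_free"] + tr$derived[, "ENSAPB55"],
                 rep(p$B55_tot, nrow(tr$derived)), tolerance = 1e-9)
  }
})

test_that("the period of a known oscillator is recovered to 0.1%", {
  m <- make_ring_oscillator(omega = 0.5)
  lc <- find_limit_cycle(m, x0 = c(1, 0), max_time = 300, transient = 50,
                         dt = 0.05)
  expect_true(lc$oscillating)
  expect_true(lc$converged)
  expect_equal(lc$period, 2 * pi / 0.5, tolerance = 1e-3)
})

test_that("limit-cycle statistics do not depend on the initial condition", {
  for (id in c("model2", "model4")) {
    m <- cc_model(id)
    x_a <- initial_state(m)
    x_b <- initial_state(m)
    x_b[] <- c(0.7, 0.3, 0.2, 0.4, 0.1, 0.05)[seq_along(x_b)]
    if (id == "model4") x_b[1] <- 1.5    # keep MPF below CycBT
    a <- find_limit_cycle(m, x0 = x_a, max_time = 3000)
    b <- find_limit_cycle(m, x0 = x_b, max_time = 3000)
    expect_true(a$oscillating && b$oscillating)
    expect_equal(a$period, b$period, tolerance = 5e-3)
    expect_equal(a$max[["MPF"]], b$max[["MPF"]], tolerance = 5e-3)
  }
})

test_that("checkpoint variants arrest and recover as the captions state", {
  base <- cc_model("model4")
  ref <- find_limit_cycle(base)
  expect_true(ref$oscillating)
  cyc_mean_cycbt <- mean(c(ref$max[["CycBT"]], ref$min[["CycBT"]]))

  g2 <- detect_arrest(apply_checkpoint(base, "G2"))
  expect_identical(g2$classification, "steady-state")
  expect_gt(g2$terminal_state[["CycBT"]], cyc_mean_cycbt)
  expect_lt(g2$terminal_state[["MPF"]], 0.2)

  sac <- detect_arrest(apply_checkpoint(base, "SAC"))
  expect_identical(sac$classification, "steady-state")
  expect_gt(sac$terminal_state[["MPF"]], 0.5)
  sac2 <- detect_arrest(apply_checkpoint(base, checkpoint_scenario("SAC", 0.2)))
  expect_identical(sac2$classification, "steady-state")
  expect_gt(sac2$terminal_state[["MPF"]], 0.5)

  g1 <- detect_arrest(apply_checkpoint(base, "G1"))
  expect_identical(g1$classification, "steady-state")
  expect_lt(g1$terminal_state[["CycBT"]], 0.2 * ref$max[["CycBT"]])

  # lifting the G2 checkpoint restores the oscillation, starting from the
  # arrested state
  lifted <- find_limit_cycle(base, x0 = g2$terminal_state)
  expect_true(lifted$oscillating)
})

test_that("a steady initial state of an arrested variant reports no cycle", {
  g2 <- apply_checkpoint(cc_model("model4"), "G2")
  arr <- detect_arrest(g2)
  lc <- find_limit_cycle(g2, x0 = arr$terminal_state, max_time = 1500)
  expect_false(lc$oscillating)
})

test_that("dual bistability drives kinase and phosphatase out of phase", {
  # phase-overlap index: time-average of MPF*B55_free over one cycle,
  # normalised by the product of the individual averages (1 = uncorrelated,
  # < 1 = anti-phase).  The raw product is not comparable across models
  # because the oscillation amplitudes differ severalfold.
  overlap_index <- function(id) {
    m <- cc_model(id)
    lc <- find_limit_cycle(m)
    orb <- lc$orbit
    b55 <- apply(orb[, -1, drop = FALSE], 1L, function(x)
      m$closures(stats::setNames(x, m$states), m$params)[["B55_free"]])
    w <- diff(orb[, "time"])
    tavg <- function(v) sum(0.5 * (v[-1] + v[-length(v)]) * w) / sum(w)
    tavg(orb[, "MPF"] * b55) / (tavg(orb[, "MPF"]) * tavg(b55))
  }
  i2 <- overlap_index("model2")
  i4 <- overlap_index("model4")
  expect_lt(i4, i2)
  expect_lt(i4, 1)      # strictly anti-phase in the dual-bistable engine
})
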