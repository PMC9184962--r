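# Steady-state location, Jacobians, continuation, fold/Hopf/SNIC detection
# and pseudo-nullclines.

make_linear_model <- function(A, b = c(0, 0)) {
  structure(list(
    id = "linear", states = paste0("x", seq_len(nrow(A))),
    rhs = function(t, x, p) list(as.numeric(A %*% x + b)),
    closures = function(x, p) numeric(0),
    params = list(dummy = 1), scenario = "none"), class = "cc_model")
}

make_fold_nf <- function() structure(list(
  id = "fold_nf", states = "x",
  rhs = function(t, x, p) list(p$p - x^2),
  closures = function(x, p) numeric(0),
  params = list(p = 1), scenario = "none"), class = "cc_model")

make_hopf_nf <- function() structure(list(
  id = "hopf_nf", states = c("x", "y"),
  rhs = function(t, x, p) list(c(
    p$p * x[1] - x[2] - x[1] * (x[1]^2 + x[2]^2),
    x[1] + p$p * x[2] - x[2] * (x[1]^2 + x[2]^2))),
  closures = function(x, p) numeric(0),
  params = list(p = -1), scenario = "none"), class = "cc_model")

test_that("finite-difference Jacobian is exact on a linear system", {
  A <- matrix(c(-1, 2, 0.5, -3), 2, 2)
  m <- make_linear_model(A)
  J <- cc_jacobian(m, c(0.3, 0.7))
  expect_equal(J, A, tolerance = 1e-9)
  # step-halving consistency
  expect_silent(cc_jacobian(m, c(0.3, 0.7), check = TRUE))
  expect_error(cc_jacobian(cc_model("model1"), c(-1, 0, 0)), "non-negativity")
})

test_that("a linear system's fixed point is recovered exactly", {
  A <- matrix(c(-2, 1, 0, -1), 2, 2)
  b <- c(0.6, 0.2)
  m <- make_linear_model(A, b)
  ss <- find_steady_states(m)
  expect_length(ss, 1L)
  expect_equal(unname(ss[[1]]$state), as.numeric(solve(A, -b)),
               tolerance = 1e-9)
  expect_identical(ss[[1]]$class, "stable node")
})

test_that("the delayed-feedback oscillator circles an unstable focus", {
  m <- cc_model("model1")
  ss <- find_steady_states(m)
  expect_length(ss, 1L)
  ev <- ss[[1]]$eigenvalues
  expect_true(any(abs(Im(ev)) > 1e-6))
  expect_gt(max(Re(ev)), 0)
})

test_that("the G2-arrested switch network has coexisting steady states", {
  g2 <- apply_checkpoint(cc_model("model4"), "G2")
  ss <- find_steady_states(g2)
  expect_gte(length(ss), 2L)
  cls <- vapply(ss, `[[`, character(1), "class")
  mpf <- vapply(ss, function(s) s$state[["MPF"]], numeric(1))
  expect_true(any(startsWith(cls, "stable") & mpf < 0.2))
  expect_true(all(vapply(ss, `[[`, numeric(1), "residual") < 1e-10))
})

test_that("the feed-forward oscillator has a single interior unstable state", {
  ss <- find_steady_states(cc_model("model2"))
  expect_length(ss, 1L)
  expect_false(startsWith(ss[[1]]$class, "stable"))
})

test_that("normal-form bifurcations are located to 1e-6", {
  fold <- continue_branch(make_fold_nf(), "p", c(-0.5, 1), x0 = 1,
                          direction = -1, ds = 0.01, ds_max = 0.05)
  expect_length(fold$folds, 1L)
  expect_lt(abs(fold$folds[[1]]$param), 1e-6)
  expect_lt(abs(fold$folds[[1]]$state[["x"]]), 1e-4)
  hopf <- continue_branch(make_hopf_nf(), "p", c(-1, 1), x0 = c(0, 0),
                          ds = 0.01, ds_max = 0.05)
  expect_length(hopf$hopfs, 1L)
  expect_lt(abs(hopf$hopfs[[1]]$param), 1e-6)
  expect_equal(hopf$hopfs[[1]]$omega, 1, tolerance = 1e-3)
})

test_that("a saddle-node without an invariant circle is a plain fold", {
  cls <- classify_snic(make_fold_nf(), "p", 0, side = -1,
                       offsets = c(0.3, 0.1, 0.03), x0 = 0.1, max_time = 200)
  expect_identical(cls$classification, "fold")
})

test_that("pseudo-nullcline of a two-variable system is the true nullcline", {
  # dx/dt = y - x^3 + x ; dy/dt = 0.3 - x  (cubic x-nullcline)
  m <- structure(list(
    id = "cubic2", states = c("x", "y"),
    rhs = function(t, x, p) list(c(x[2] - x[1]^3 + x[1], p$a - x[1])),
    closures = function(x, p) numeric(0),
    params = list(a = 0.3), scenario = "none"), class = "cc_model")
  red <- clamp_state(m, "y", value = -2)
  br <- continue_branch(red, "y", c(-2, 2), ds = 0.01, ds_max = 0.05,
                        max_points = 2000)
  # every traced point must satisfy x^3 - x = y exactly
  err <- abs(br$points$x^3 - br$points$x - br$points$y)
  expect_lt(max(err), 1e-6)
  # the cubic has two folds, at x = +/- 1/sqrt(3)
  expect_gte(length(br$folds), 2L)
  fx <- sort(abs(vapply(br$folds, function(f) f$state[["x"]], numeric(1))))
  expect_equal(fx[1:2], rep(1 / sqrt(3), 2), tolerance = 1e-6)
})

test_that("the tyrosine-phosphorylation switch is hysteretic in total cyclin", {
  nc <- pseudo_nullcline(cc_model("model4"), "CycBT", c(0.2, 2),
                         response_var = "MPF")
  expect_identical(nc$shape, "S-shaped")
  expect_named(nc$folds, c("activation", "inactivation"))
  act <- nc$folds$activation$param
  inact <- nc$folds$inactivation$param
  expect_gt(act, inact)              # non-empty bistable window
  # the full oscillation traverses the entire hysteresis loop
  lc <- find_limit_cycle(cc_model("model4"))
  expect_gt(lc$max[["CycBT"]], act)
  expect_lt(lc$min[["CycBT"]], inact)
})

test_that("the APC/C response to MPF sharpens from monotone to bistable", {
  nc2 <- pseudo_nullcline(cc_model("model2"), "MPF", c(1e-3, 1.4),
                          response_var = "APCPC20")
  expect_identical(nc2$shape, "monotone")
  nc3 <- pseudo_nullcline(cc_model("model3"), "MPF", c(1e-3, 1.4),
                          response_var = "APCPC20")
  expect_identical(nc3$shape, "S-shaped")
  expect_length(nc3$folds, 2L)
})

test_that("stability flips across detected folds along a branch", {
  red <- clamp_state(cc_model("model4"), "CycBT", 0.2)
  br <- continue_branch(red, "CycBT", c(0.2, 2), stop_at_first_fold = TRUE)
  expect_gte(length(br$folds), 1L)
  i <- br$folds[[1]]$index
  expect_true(br$points$n_unstable[max(1, i - 1)] !=
              br$points$n_unstable[min(nrow(br$points), i + 2)])
})

test_that("the growth-clamped network loses its interphase state at a SNIC", {
  br <- continue_branch(cc_model("model4"), "Cdc25_tot", c(0.005, 1.3),
                        ds_max = 0.006)
  folds <- vapply(br$folds, `[[`, numeric(1), "param")
  expect_gte(length(folds), 1L)
  snic <- max(folds)
  # below the fold the system sits at a low-MPF steady state, above it the
  # only attractor is a large-amplitude cycle
  env <- cycle_envelope(cc_model("model4"), "Cdc25_tot",
                        c(snic - 0.05, snic + 0.25))
  expect_false(env$oscillating[1])
  expect_lt(env$max[1], 0.3)
  expect_true(env$oscillating[2])
  # envelope extrema bracket the (unstable) branch continuation value
  pt <- br$points[which.min(abs(br$points$Cdc25_tot - (snic + 0.25))), ]
  expect_gt(env$max[2], pt$MPF)
  expect_lt(env$min[2], pt$MPF)
  # Hopf on the upper branch, with periods diverging towards the fold
  expect_gte(length(br$hopfs), 1L)
  cls <- classify_snic(cc_model("model4"), "Cdc25_tot", snic, side = 1)
  expect_identical(cls$classification, "SNIC")
  expect_true(all(diff(cls$periods) > 0))
})
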