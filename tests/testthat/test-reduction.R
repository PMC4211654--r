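# Constant-trajectory detection and model reduction.

test_that("models without known initial conditions are untouched", {
  m <- builtin_examples("2comp")
  r <- detect_constant_states(m)
  expect_false(r$reducible)
  expect_length(r$constant_states, 0)
  expect_true(identicombo:::model_equal(r$reduced_model, m))
})

test_that("a state pinned at an equilibrium initial value is constant", {
  # x1(0) = 0 with x1' = p1*x1 gives x1 == 0, so the output carries no
  # information and p1 is unidentifiable
  m <- parse_model("x1' = p1*x1 ; x2' = u1 - p2*x2 ; y1 = x1 ; y2 = x2 ; x1(0) = 0")
  r <- detect_constant_states(m)
  expect_true(r$reducible)
  expect_equal(r$constant_states, "x1")
  expect_equal(length(r$reduced_model$states), 1)
  rep <- run_analysis(m, seed = 3)
  expect_equal(rep$parameters$status[rep$parameters$name == "p1"],
               "unidentifiable")
})

test_that("nonzero and non-equilibrium initial conditions do not reduce", {
  m <- parse_model("x1' = p1*x1 ; y1 = x1 ; x1(0) = 5")
  expect_false(detect_constant_states(m)$reducible)
  # substituted value must make the equation identically zero, not just small
  m2 <- parse_model(
    "x1' = p1*x1 - p1 ; x2' = u1 - p2*x2 ; y1 = x1 ; y2 = x2 ; x1(0) = 1")
  r <- detect_constant_states(m2)
  expect_true(r$reducible)
  expect_equal(r$constant_states, "x1")
})

test_that("a fully frozen model reports every parameter unidentifiable", {
  m <- parse_model("x1' = p1*x1 ; y1 = x1 ; x1(0) = 0")
  r <- detect_constant_states(m)
  expect_true(r$reducible)
  expect_length(r$reduced_model$states, 0)
  rep <- run_analysis(m, seed = 1)
  expect_equal(rep$model_status, "unidentifiable")
  expect_true(all(rep$parameters$status == "unidentifiable"))
})

test_that("the closure iterates: states feeding each other both freeze", {
  m <- builtin_examples("nl2out_ic")
  r <- detect_constant_states(m)
  expect_true(r$reducible)
  expect_setequal(r$constant_states, c("x1", "x3"))
  # reduction is idempotent
  r2 <- detect_constant_states(r$reduced_model)
  expect_false(r2$reducible)
})

test_that("parameter-expression initial values participate in the closure", {
  m <- parse_model(
    "x1' = p1*(x1 - p2) ; x2' = u1 - p3*x2 ; y1 = x1 ; y2 = x2 ; x1(0) = p2")
  r <- detect_constant_states(m)
  expect_true(r$reducible)
  expect_equal(r$constant_states, "x1")
})
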