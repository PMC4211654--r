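# Model text parsing, validation and rendering.

test_that("models parse with canonical parameter mapping and comma names", {
  m <- parse_model("x1' = k0,1*x1 + u1 ; y1 = x1/V")
  expect_s3_class(m, "icb_model")
  expect_equal(m$states, "x1")
  expect_equal(m$inputs, "u1")
  expect_equal(m$outputs, "y1")
  expect_equal(m$user_parameters, c("k0,1", "V"))
  expect_equal(m$name_map$canonical, c("p1", "p2"))

  m2 <- parse_model("x1' = -p1*x1 ; y1 = x1")
  expect_equal(length(m2$parameters), 1)
  expect_equal(length(m2$inputs), 0)

  # dx/dt notation and newline separators are accepted
  m3 <- parse_model("dx1/dt = -a*x1\n y1 = x1")
  expect_true(identicombo:::model_equal(m3, parse_model("x1' = -a*x1 ; y1 = x1")))
})

test_that("numbering, reserved letters and placement rules are enforced", {
  expect_error(parse_model("x1' = -p1*x1 ; y2 = x1"), "numbering")
  expect_error(parse_model("x2' = -p1*x2 ; y1 = x2"), "numbering")
  expect_error(parse_model("x1' = -p1*x1 + u2 ; y1 = x1"), "numbering")
  expect_error(parse_model("x1' = -tau*x1 ; y1 = x1"), "reserved")
  expect_error(parse_model("x1' = -p1*x1*t ; y1 = x1"), "time")
  expect_error(parse_model("x1' = -p1*x1 ; y1 = y1 + x1"), "outputs")
  expect_error(parse_model("x1' = -p1*x1 ; y1 = x1 ; x1(0) = x1 + 1"),
               "parameters")
  expect_error(parse_model("x1' = -p1*x1 ; y1 = x1 ; x2(0) = 1"), "undefined")
  expect_error(parse_model("x1' = -p1*x1 + ; y1 = x1"), ".")
  expect_error(parse_model("x1' = -p1*x1 ; y1 = x1",
                           max_parameters = 0), "limit")
})

test_that("numeric literals become exact rationals", {
  m <- parse_model("x1' = -4.32*p1*x1 ; y1 = 0.5*x1")
  rf <- identicombo:::ast_to_rf(m$output_eqs$y1, c(m$states, m$parameters))
  expect_equal(rf$num$c, "1/2")    # 0.5 converts exactly, with a monic denominator
  expect_equal(rf$den$c, "1")
})

test_that("initial conditions may be numbers or parameter functions", {
  m <- parse_model(
    "x1' = -p1*x1 + p3*x2 ; x2' = p1*x1 - p3*x2 ; y1 = x1 ; x2(0) = 3*p1 + p3")
  expect_named(m$ics, "x2")
  expect_length(validate_model(m), 0)
})

test_that("transcendental-looking names yield a diagnostic, not an error", {
  m <- parse_model("x1' = -sin*x1 ; y1 = x1")
  expect_true("sin" %in% m$user_parameters)
  d <- validate_model(m)
  expect_match(d, "transcendental", all = FALSE)
})

test_that("parse and render round-trip on every built-in example", {
  for (m in builtin_examples()) {
    expect_length(validate_model(m), 0)
    m2 <- parse_model(render_copy_paste(m), constant_inputs = m$const_inputs)
    expect_true(identicombo:::model_equal(m, m2))
  }
  for (fam in 1:5) {
    m <- generate_test_model(fam, if (fam == 2) 2 else 1)
    expect_true(identicombo:::model_equal(m, parse_model(render_copy_paste(m))))
  }
})

test_that("rendering lists known initial conditions only", {
  m <- builtin_examples("mammillary4_ic")
  txt <- render_copy_paste(m)
  expect_match(txt, "x2(0)", fixed = TRUE)
  expect_match(txt, "x3(0)", fixed = TRUE)
  expect_false(grepl("x1(0)", txt, fixed = TRUE))
  expect_false(grepl("x1(0)", render_copy_paste(builtin_examples("2comp")),
                     fixed = TRUE))
})
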