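# Built-in registry and benchmark families.

test_that("every registry model parses, validates and round-trips", {
  reg <- builtin_examples()
  expect_gte(length(reg), 14)
  for (nm in names(reg)) {
    m <- reg[[nm]]
    expect_s3_class(m, "icb_model")
    expect_length(validate_model(m), 0)
  }
  expect_error(builtin_examples("nope"), "unknown example")
})

test_that("registry models have the documented shapes", {
  m <- builtin_examples("2comp")
  expect_length(m$parameters, 5)
  hiv <- builtin_examples("hiv")
  expect_length(hiv$states, 4)
  expect_length(hiv$outputs, 2)
  # nonlinear: some state equation has a degree-2 state monomial
  vars <- c(hiv$states, hiv$inputs, hiv$parameters)
  deg2 <- any(vapply(hiv$states, function(s) {
    rf <- identicombo:::ast_to_rf(hiv$odes[[s]], vars)
    any(rowSums(rf$num$exp[, 1:4, drop = FALSE]) >= 2)
  }, TRUE))
  expect_true(deg2)
  expect_equal(builtin_examples("viral")$const_inputs, "u1")
})

test_that("benchmark family construction matches its definition", {
  m <- generate_test_model(1, 3)
  expect_length(m$parameters, 9)
  expect_length(m$outputs, 3)
  m2 <- generate_test_model(2, 3)
  expect_length(m2$outputs, 2)
  m5 <- generate_test_model(5, 3)
  expect_length(m5$outputs, 2)
  expect_error(generate_test_model(1, 8), "limit")
  expect_error(generate_test_model(2, 1), "family 2")
})

test_that("the fully measured family is globally identifiable at small n", {
  for (n in 1:3) {
    rep <- run_analysis(generate_test_model(1, n), seed = 1)
    expect_equal(rep$model_status, "globally identifiable", info = paste0("n=", n))
  }
})

test_that("single-parameter members are uniquely identifiable", {
  for (fam in c(1, 3, 4, 5)) {
    rep <- run_analysis(generate_test_model(fam, 1), seed = 2)
    expect_equal(rep$model_status, "globally identifiable")
    expect_equal(rep$parameters$name, "p11")
  }
})

test_that("family 2 at n = 2 reproduces the published combination set", {
  m <- generate_test_model(2, 2)
  rep <- run_analysis(m, seed = 1)
  expect_equal(rep$model_status, "unidentifiable")
  fs <- fiber_for(m, seed = 1)
  for (tx in c("p11", "p22", "p12*p21"))
    expect_equal(combo_count(fs, m, tx), 1, info = tx)
  expect_equal(combo_rank(fs, m, c("p11", "p22", "p12*p21")), 3)
  expect_equal(rep$rank, 3)
})
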