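# Pipeline orchestration and report formatting.

test_that("analysis is deterministic under a fixed seed", {
  m <- builtin_examples("2comp")
  r1 <- run_analysis(m, seed = 5)
  r2 <- run_analysis(m, seed = 5)
  expect_identical(as.character(format_report(r1, "json")),
                   as.character(format_report(r2, "json")))
})

test_that("the JSON report is schema-stable and machine-readable", {
  r <- run_analysis(builtin_examples("2comp"), seed = 1)
  obj <- jsonlite::fromJSON(format_report(r, "json"))
  expect_equal(obj$schema, "identicombo-report/1")
  expect_equal(obj$model_status, "unidentifiable")
  expect_setequal(names(obj$pstar), r$model$user_parameters)
  expect_equal(nrow(obj$parameters), 5)
  expect_false(obj$aborted)
  expect_equal(obj$orderings_used, 15)   # 3P for the five parameters
})

test_that("reports are expressed in the user's parameter names", {
  r <- run_analysis(builtin_examples("3comp"), seed = 1)
  expect_setequal(r$parameters$name,
                  c("k21", "k31", "k12", "k13", "k02", "k03", "V1"))
  # no canonical p-symbols leak into rendered combination expressions
  expect_false(any(grepl("\\bp[0-9]+\\b", r$combos$expression)))
  txt <- format_report(r, "text")
  expect_match(txt, "Verdict: unidentifiable")
  expect_match(txt, "V1")
})

test_that("identifiable models short-circuit: combos are the parameters", {
  r <- run_analysis(builtin_examples("2comp_k01_0"), seed = 1)
  expect_equal(r$model_status, "globally identifiable")
  expect_true(all(r$combos$provenance == "parameter"))
  expect_setequal(r$combos$expression, r$parameters$name)
})

test_that("reduction results are surfaced in the report", {
  r <- run_analysis(builtin_examples("nl2out_ic"), seed = 1)
  expect_true(r$reducible)
  expect_setequal(r$constant_states, c("x1", "x3"))
  expect_equal(r$model_status, "unidentifiable")
})

test_that("tidy and glance provide the tabular views", {
  r <- run_analysis(builtin_examples("2comp"), seed = 1)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("name", "canonical", "status", "max_solutions"))
  g <- glance(r)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_unique, 1)
  expect_equal(g$n_unidentifiable, 4)
  expect_output(print(r), "Structural identifiability")
})
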