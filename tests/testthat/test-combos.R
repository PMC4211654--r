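# Ordering schedule, candidate harvesting and independent-set selection.

test_that("the ordering schedule follows the shift/reorder rules", {
  s1 <- generate_orderings(1)
  expect_equal(dim(s1), c(3, 1))
  expect_true(all(s1 == 1))

  s4 <- generate_orderings(4)
  expect_equal(dim(s4), c(12, 4))
  # block 1: cyclic shifts of the identity
  expect_equal(s4[1, ], 1:4)
  expect_equal(s4[2, ], c(2, 3, 4, 1))
  # block 2 starts from the even-P reordering (1,3,2,4)
  expect_equal(s4[5, ], c(1, 3, 2, 4))
  # odd P: (p1, p3, ..., pP, p2, p4, ..., p_{P-1})
  s5 <- generate_orderings(5)
  expect_equal(s5[6, ], c(1, 3, 5, 2, 4))
  # every row is a permutation; shifting P times returns the start
  for (i in seq_len(nrow(s4))) expect_setequal(s4[i, ], 1:4)
  expect_equal(s4[1, ], s4[1, ][c(4, 1:3)][c(4, 1:3)][c(4, 1:3)][c(4, 1:3)])
})

test_that("harvest at the published pseudo-random point recovers the known combos", {
  # canonical order of appearance in the model text: k01, k21, k12, k02, V1;
  # the reference point (k01,k02,k12,k21,V1) = (8,7,13,12,3)
  m <- builtin_examples("2comp")
  fs <- fiber_for(m, seed = 0, pstar = c(8, 12, 13, 7, 3))
  cands <- harvest_candidates(fs)
  vals <- vapply(cands, function(cand) {
    v <- identicombo:::rf_eval(identicombo:::cand_rf(cand, 5), fs$pstar)
    if (is.null(v)) NA_real_ else identicombo:::rat_to_num(v)
  }, 0)
  exprs <- vapply(cands, function(cand)
    identicombo:::combo_string(cand, m$user_parameters), "")
  # k02 + k12 = 20, k12*k21 = 156, k01 + k21 = 20
  expect_true(any(exprs == "k12 + k02" & vals == 20))
  expect_true(any(exprs == "k21*k12" & vals == 156))
  expect_true(any(exprs == "k01 + k21" & vals == 20))
})

test_that("Example-1 selection is equivalent to the classical combination set", {
  m <- builtin_examples("2comp")
  fs <- fiber_for(m, seed = 1)
  cs <- select_independent_set(harvest_candidates(fs), fs)
  expect_equal(cs$rank, 4)
  expect_equal(cs$achieved_rank, 4)
  expect_true(all(cs$max_solutions == 1))
  targets <- c("V1", "k01 + k21", "k02 + k12", "k12*k21")
  for (tx in targets) expect_equal(combo_count(fs, m, tx), 1, info = tx)
  expect_equal(combo_rank(fs, m, targets), 4)
})

test_that("Example-3 selection carries the published solution counts", {
  m <- builtin_examples("3comp")
  fs <- fiber_for(m, seed = 1)
  cs <- select_independent_set(harvest_candidates(fs), fs)
  expect_equal(cs$rank, 6)
  expect_equal(sort(cs$max_solutions), c(1, 1, 2, 2, 2, 2))
})

test_that("selected combinations are independent and fiber-consistent", {
  for (nm in c("2comp", "3comp", "viral")) {
    m <- builtin_examples(nm)
    fs <- fiber_for(m, seed = 1)
    cs <- select_independent_set(harvest_candidates(fs), fs)
    P <- length(m$parameters)
    rfs <- lapply(cs$combos, identicombo:::cand_rf, P = P)
    J <- identicombo:::eng_jacobian_p(rfs, as.numeric(fs$pstar), fs$prime)
    expect_equal(identicombo:::eng_rank_p(J, fs$prime), length(cs$combos))
    expect_equal(length(cs$combos), cs$rank, info = nm)
    expect_true(all(is.finite(cs$max_solutions)))
    # unique combinations evaluate to their p* value (already stored exactly)
    for (i in seq_along(cs$combos)) {
      v <- identicombo:::rf_eval(rfs[[i]], fs$pstar)
      expect_equal(v, cs$values[i])
    }
  }
})

test_that("a binomial basis element yields a monomial-ratio candidate", {
  m <- generate_test_model(2, 3)
  fs <- fiber_for(m, seed = 1)
  cands <- harvest_candidates(fs)
  keys <- vapply(cands, function(cand)
    identicombo:::combo_string(cand, m$user_parameters), "")
  expect_true(any(keys %in% c("p23/p13", "p13/p23")))
})

test_that("reparameterized models close the loop", {
  rep <- run_analysis(builtin_examples("2comp_repar"), seed = 1)
  expect_equal(rep$model_status, "globally identifiable")
  # viral reparameterization: the two loss rates stay interchangeable but
  # everything is at least locally identifiable
  rep2 <- run_analysis(builtin_examples("viral_repar"), seed = 1)
  expect_true(all(is.finite(rep2$parameters$max_solutions)))
  expect_equal(sort(rep2$parameters$max_solutions), c(1, 1, 1, 2, 2))
})
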