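# Analytic Bayesian model reduction over initial-state Dirichlet priors.

test_that("log multivariate beta matches known values and the telescoping oracle", {
  expect_equal(log_mbeta(c(1, 1)), 0)                     # B(1,1) = 1
  expect_equal(log_mbeta(c(2, 2)), log(1 / 6), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    x <- runif(sample(2:8, 1), min = 0.05, max = 1e4)
    expect_equal(log_mbeta(x), lbeta_oracle(x), tolerance = 1e-10)
  }
  expect_error(log_mbeta(c(1, 0)), "positive")
})

test_that("evidence differences have the right sign, zero point, and antisymmetry", {
  # identical models: exactly zero
  expect_identical(bmr_delta_F(c(1, 1), c(6, 6), c(1, 1)), 0)

  # level 2 never visited: eliminating it gains evidence
  # (frozen value computed with the independent pairwise-beta oracle)
  d1 <- bmr_delta_F(c(1, 1), c(11, 1), c(1, 0.125))
  oracle <- (lbeta_oracle(c(11, 0.125)) - lbeta_oracle(c(1, 0.125))) -
    (lbeta_oracle(c(11, 1)) - lbeta_oracle(c(1, 1)))
  expect_equal(d1, oracle, tolerance = 1e-12)
  expect_equal(d1, 2.043162, tolerance = 1e-5)
  expect_gt(d1, 0)

  # both levels used: reduction loses evidence
  expect_lt(bmr_delta_F(c(1, 1), c(6, 6), c(1, 0.125)), 0)

  # antisymmetric under swapping the two priors with the data fixed
  n <- c(10, 0)
  ab <- bmr_delta_F(c(1, 1), c(1, 1) + n, c(1, 0.125))
  ba <- bmr_delta_F(c(1, 0.125), c(1, 0.125) + n, c(1, 1))
  expect_equal(ab, -ba, tolerance = 1e-12)

  expect_error(bmr_delta_F(c(2, 2), c(1, 2), c(1, 1)), "dominate")
})

test_that("eliminating an untouched level is favored once q is small enough, monotonically", {
  prior <- rep(1, 4)
  post <- c(41, 31, 21, 1) # level 4 untouched
  dFs <- vapply(c(0.9, 0.5, 0.25, 0.125, 0.05), function(q) {
    bmr_delta_F(prior, post, c(1, 1, 1, q))
  }, numeric(1))
  expect_true(all(diff(dFs) > 0) || all(dFs > 0)) # grows as -ln q grows
  expect_gt(dFs[4], 0)                            # favored at the default q
})

test_that("candidate enumeration covers every non-empty proper subset", {
  c8 <- enumerate_candidates(8, 1, 0.125)
  expect_length(c8, 254)
  expect_true(all(vapply(c8, function(cc)
    min(cc$prior[cc$eliminate]) < min(cc$prior[cc$retain]), logical(1))))
  c3 <- enumerate_candidates(3, 1, 0.125)
  subsets <- lapply(c3, `[[`, "retain")
  expect_setequal(vapply(subsets, paste, character(1), collapse = ","),
                  c("1", "2", "3", "1,2", "1,3", "2,3"))
  expect_error(enumerate_candidates(3, 1, 1), "smaller")
})

test_that("winner selection is a pure function of the evidence vector", {
  cand <- enumerate_candidates(3, 1, 0.125)
  allneg <- select_model(cand, rep(-1, 6))
  expect_identical(allneg$winner, 0L)           # full model retained
  expect_length(allneg$retain, 3)

  one <- rep(-1, 6); one[4] <- 2.5              # only candidate 4 positive
  sel <- select_model(cand, one)
  expect_identical(sel$winner, 4L)
  expect_identical(sel$retain, cand[[4]]$retain)
  expect_equal(sel$gap, 2.5) # runner-up is the full model at relative evidence 0
  expect_equal(sum(sel$m), 1)

  # equal-evidence singletons: tie broken toward the lexicographically
  # smallest retained subset
  tie <- rep(-1, 6); tie[c(1, 4)] <- 1          # retain {1} vs retain {3}
  sel2 <- select_model(cand, tie)
  expect_identical(sel2$retain, cand[[1]]$retain)
})

test_that("d learning with a clamped likelihood recovers the presented set exactly", {
  red <- exp_reduction(n_true = 5, exposures = 40, repeats = 3,
                       precise_A = TRUE, seed = 5)
  expect_true(all(red$per_repeat$exact_set))
  expect_true(all(red$per_repeat$n_retained == 5))
})

test_that("slot reset is local, restores naivety, and re-enables novelty capture", {
  set.seed(17)
  m <- build_agent_model(concept_task("slots", slots = 1L)) # hawk unknown
  gp <- build_generative_process(m$task)
  m$d <- list(rep(1, 8), NULL); m$d_init <- m$d; m$learn_d <- TRUE
  stream <- c(rep(1, 15), sample_stimulus_stream(2:8, n = 20, kind = "uniform"))
  learned <- run_learning_block(m, gp, stream)$model

  expect_identical(reset_slots(learned, integer(0)), learned)

  r1 <- reset_slots(learned, 1L)
  for (mod in 1:4) { # only column-1 slices and d[1] may change
    expect_identical(r1$a[[mod]][, -1, ], learned$a[[mod]][, -1, ])
  }
  expect_identical(r1$d[[1]][-1], learned$d[[1]][-1])
  expect_equal(r1$d[[1]][1], 1)
  expect_lt(max(r1$a[[1]][, 1, 1]), 2) # back to naive magnitude

  # the reset slot is engaged again by a novel stream (and not before)
  a_before <- r1$a
  relearn <- run_learning_block(r1, gp, rep(2, 10))$model # parrot is known
  inc_slot <- sum(relearn$a[[1]][, 1, ] - a_before[[1]][, 1, ])
  inc_all <- sum(relearn$a[[1]] - a_before[[1]])
  expect_lt(inc_slot / inc_all, 0.01)
  relearn2 <- run_learning_block(r1, gp, rep(1, 10))$model # hawk is novel again
  inc_slot2 <- sum(relearn2$a[[1]][, 1, ] - a_before[[1]][, 1, ])
  inc_all2 <- sum(relearn2$a[[1]] - a_before[[1]])
  expect_gt(inc_slot2 / inc_all2, 0.5)
})
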