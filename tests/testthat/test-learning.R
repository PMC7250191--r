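# Count accumulation (a, d), frozen probes, duplication avoidance.

test_that("likelihood counts accumulate as outcome-by-posterior outer products", {
  m <- build_agent_model(concept_task("slots", slots = 5L, naive_jitter = 0))
  m$learn_d <- FALSE
  gp <- build_generative_process(m$task)
  tr <- run_trial(m, gp, 1) # hawk: known column, posterior is (nearly) a delta
  expect_gt(tr$bma[[1]][1, 1], 0.99)

  m0 <- learn_A(m, tr, eta = 0)
  expect_identical(m0$a, m$a)

  m1 <- learn_A(m, tr, eta = 1)
  inc <- m1$a[[1]] - m$a[[1]]
  # features are observed at both time points with the report at start:
  # a single (large | hawk, start) entry receives (almost) all the mass
  expect_equal(sum(inc), 2, tolerance = 1e-9)
  expect_equal(inc[1, 1, 1], 2, tolerance = 5e-3)
  expect_lt(max(abs(inc[, , 2:11])), 1e-12) # untouched report slices

  # shape mismatch errors
  bad <- tr
  bad$obs <- bad$obs[1:2, , drop = FALSE]
  expect_error(learn_A(m, bad), "subscript|bounds|missing")
})

test_that("repeated identical trials drive the touched column to the empirical frequencies", {
  set.seed(10)
  m <- build_agent_model(concept_task("slots", slots = 5L))
  m$learn_d <- FALSE
  gp <- build_generative_process(m$task)
  for (i in 1:50) {
    tr <- run_trial(m, gp, 5) # always sturgeon -> slot engaged
    m <- learn_A(m, tr)
  }
  col <- normalize_counts(m$a[[1]][, 5, 1]) # size modality, slot column
  expect_gt(col[1], 0.95) # sturgeon is large on every exposure; the gap to 1
                          # is bounded by the flat prior over the accumulated counts
})

test_that("initial-state counts conserve eta per trial and concentrate on shown animals", {
  set.seed(12)
  m <- build_agent_model(concept_task("reduction", precise_A = TRUE))
  gp <- build_generative_process(m$task)
  shown <- c(1, 5, 2, 7, 4) # 5 animals
  stream <- sample_stimulus_stream(shown, per_animal = 20, kind = "balanced")
  d0 <- m$d[[1]]
  for (animal in stream) {
    tr <- run_trial(m, gp, animal)
    m <- learn_D(m, tr)
  }
  inc <- m$d[[1]] - d0
  expect_equal(sum(inc), m$eta * length(stream), tolerance = 1e-9)
  expect_gt(min(inc[shown]), 19.9) # ~eta * 20 each
  expect_lt(max(inc[-shown]), 0.1)
  # uniform posteriors leave d uniform
  m2 <- m
  fake <- tr
  fake$bma[[1]][, 1] <- 1 / 8
  m2 <- learn_D(m2, fake)
  expect_equal(diff(range(m2$d[[1]][-shown])), 0, tolerance = 0.2)
})

test_that("frozen probes evaluate without mutating the model and cover every checkpoint", {
  m <- build_agent_model(concept_task("full_knowledge"))
  gp <- build_generative_process(m$task)
  pr <- freeze_and_probe(m, gp, probes_per_animal = 2)
  expect_equal(pr$accuracy, 1)
  expect_equal(pr$prop_specific, 1)

  set.seed(21)
  naive <- build_agent_model(concept_task("granularity", prior_basic = FALSE))
  gp2 <- build_generative_process(naive$task)
  before <- naive$a
  pr2 <- freeze_and_probe(naive, gp2, probes_per_animal = 2)
  expect_identical(naive$a, before)   # pure evaluation
  expect_lt(pr2$accuracy, 0.3)        # uninformed agent at or below chance
  expect_lt(pr2$prop_specific, 0.5)   # basic / no reports dominate

  set.seed(22)
  m3 <- build_agent_model(concept_task("slots", slots = 5L))
  gp3 <- build_generative_process(m3$task)
  stream <- sample_stimulus_stream(1:8, n = 30, kind = "uniform")
  blk <- run_learning_block(m3, gp3, stream, checkpoints = c(0, 10, 30),
                            probes_per_animal = 1)
  expect_equal(blk$curve$checkpoint, c(0, 10, 30)) # none skipped
})

test_that("learning leaves counts non-decreasing and disabled learning leaves them bit-identical", {
  set.seed(31)
  m <- build_agent_model(concept_task("slots", slots = c(4L, 7L)))
  gp <- build_generative_process(m$task)
  a0 <- m$a
  tr <- run_trial(m, gp, 4)
  m1 <- learn_A(m, tr)
  for (mod in 1:4) expect_true(all(m1$a[[mod]] >= a0[[mod]] - 1e-15))
  frozen <- m
  frozen$learn_a <- FALSE
  frozen$learn_d <- FALSE
  blk <- run_learning_block(frozen, gp, c(1, 2, 3))
  expect_identical(blk$model$a, a0)
})

test_that("spare slots are not engaged by familiar animals but capture novel ones", {
  # scaled version of the duplication-avoidance protocol
  dup <- exp_duplication(known = 7, familiar_trials = 30, novel_trials = 10,
                         seed = 2)
  expect_lt(dup$per_repeat$familiar_slot_mass, 0.01)
  expect_gt(dup$per_repeat$novel_slot_mass, 0.5)
})
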