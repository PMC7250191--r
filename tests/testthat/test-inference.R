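# Belief updating, expected free energy, precision, action selection, trials.

test_that("state inference matches exact Bayes by enumeration on T = 2 models", {
  set.seed(42)
  for (rep in 1:6) {
    m <- random_single_factor(ns = 3 + rep %% 3, no = 4)
    ns <- m$factor_sizes[1]
    o1 <- sample.int(4, 1); o2 <- sample.int(4, 1)
    res <- infer_states(m, matrix(c(o1, o2), 1, 2), policy = matrix(1L, 1, 1))
    oracle <- enum_posterior_T2(m$D[[1]], matrix(m$A[[1]], 4, ns),
                                m$B[[1]][, , 1], o1, o2)
    expect_lt(max(abs(res$x[[1]][, 1] - oracle$t1)), 1e-6)
    expect_lt(max(abs(res$x[[1]][, 2] - oracle$t2)), 1e-6)
    expect_true(res$converged)
  }
})

test_that("a fully precise likelihood pins the concept posterior on the true animal", {
  m <- build_agent_model(concept_task("full_knowledge"))
  gp <- build_generative_process(m$task)
  # sturgeon: large, gray, gills
  obs <- matrix(c(observe(gp, 5, 1)), ncol = 1)
  res <- infer_states(m, obs, policy = m$policies[1, , ])
  expect_gt(res$x[[1]][5, 1], 0.999)
})

test_that("uniform counts and priors give a uniform concept posterior", {
  set.seed(2)
  m <- build_agent_model(concept_task("granularity", prior_basic = FALSE,
                                      naive_jitter = 0))
  gp <- build_generative_process(m$task)
  obs <- matrix(observe(gp, 3, 1), ncol = 1)
  res <- infer_states(m, obs, policy = m$policies[1, , ])
  expect_equal(res$x[[1]][, 1], rep(1 / 8, 8), tolerance = 1e-10)
})

test_that("with a deterministic likelihood and flat preferences, G is the negative predicted-outcome entropy", {
  # two states; action 1 keeps the state uncertain, action 2 collapses it
  A <- diag(2); dim(A) <- c(2, 2)
  B <- array(0, c(2, 2, 2))
  B[, , 1] <- diag(2)
  B[, , 2] <- matrix(c(1, 0, 1, 0), 2, 2)
  m <- generative_model(A = list(A), B = list(B), C = list(c(0, 0)),
                        D = list(c(0.5, 0.5)),
                        policies = array(1:2, c(2, 1, 1)), T = 2L)
  cache <- conceptmdp:::model_cache(m)
  xs <- lapply(1:2, function(p)
    infer_states(m, matrix(numeric(0), 1, 0), policy = matrix(p, 1, 1))$x)
  g1 <- expected_free_energy(m, xs[[1]], t_from = 2)
  g2 <- expected_free_energy(m, xs[[2]], t_from = 2)
  expect_equal(g1$G, -log(2), tolerance = 1e-8) # maximally uncertain outcome
  expect_equal(g2$G, 0, tolerance = 1e-8)       # deterministic outcome
  expect_lt(g1$G, g2$G)
  expect_equal(g1$ambiguity, 0, tolerance = 1e-10)
  expect_equal(g1$novelty, 0)
})

test_that("novelty vanishes as concentration grows and is nonnegative", {
  set.seed(8)
  base <- build_agent_model(concept_task("slots", slots = 5L))
  gp <- build_generative_process(base$task)
  novelty_at <- function(scale) {
    m <- base
    m$a <- lapply(m$a, function(x) x * scale)
    tr <- run_trial(m, gp, 5)
    tr$evaluation$t1$novelty[1]
  }
  n1 <- novelty_at(1)
  n2 <- novelty_at(100)
  n3 <- novelty_at(10000)
  expect_true(all(c(n1, n2, n3) >= 0))
  expect_gt(n1, n2)
  expect_gt(n2, n3)
  expect_lt(n3, 1e-3)
})

test_that("uncertainty between the four birds makes the basic report safer than any specific one", {
  m <- build_agent_model(concept_task("basic_only"))
  gp <- build_generative_process(m$task)
  obs <- matrix(observe(gp, 1, 1), ncol = 1) # a hawk: posterior uniform over birds
  np <- dim(m$policies)[1]
  xs <- lapply(seq_len(np), function(p)
    infer_states(m, obs, policy = m$policies[p, , ]))
  ev <- evaluate_policies(m, lapply(xs, `[[`, "x"), obs, t = 1)
  G_bird <- ev$G[10]               # policy 10 reports "bird"
  G_specific <- ev$G[2:5]          # policies reporting each single bird
  expect_true(all(G_bird < G_specific))
})

test_that("policy distributions behave in the degenerate and limiting cases", {
  # single allowed policy
  set.seed(3)
  m <- build_agent_model(concept_task("slots", slots = 5L))
  gp <- build_generative_process(m$task)
  tr <- run_trial(m, gp, 2)
  expect_equal(tr$pi, 1)
  # two policies with equal F and G split evenly
  pr <- update_precision(G = c(1.3, 1.3), Fv = c(0.2, 0.2), beta0 = 1)
  expect_equal(pr$pi, c(0.5, 0.5))
  expect_equal(pr$pi0, c(0.5, 0.5))
  # gamma -> 0 leaves only F in the posterior softmax
  G <- c(0.5, 2); Fv <- c(1, 0.25)
  g0 <- 1e-9
  pip <- exp(-Fv - g0 * G) / sum(exp(-Fv - g0 * G))
  pr2 <- update_precision(G, Fv, beta0 = 1e9)
  expect_equal(pr2$pi, pip, tolerance = 1e-6)
})

test_that("the precision fixed point matches a bisection oracle", {
  G <- c(2.5, -1.0)
  Fv <- c(0.3, 0.9)
  pr <- update_precision(G, Fv, beta0 = 1, max_iter = 64, tol = 1e-12)
  expect_equal(pr$beta_post, precision_oracle(G, Fv, 1), tolerance = 1e-6)
  # no belief shift -> beta stays at prior, flat dopamine
  pr0 <- update_precision(G = c(1, 1), Fv = c(0, 0), beta0 = 1)
  expect_equal(pr0$beta_post, 1, tolerance = 1e-12)
  expect_equal(max(abs(pr0$dopamine)), 0, tolerance = 1e-12)
  # posterior concentrating on the lowest-G policy raises gamma
  pr1 <- update_precision(G = c(-2, 2), Fv = c(-4, 4), beta0 = 1,
                          max_iter = 64)
  expect_gt(pr1$gamma, 1)
  expect_gt(sum(pr1$dopamine), 0)
})

test_that("action selection maximizes the policy-weighted action marginal", {
  m <- build_agent_model(concept_task("full_knowledge"))
  ev <- structure(list(pi = c(0.6, rep(0.4 / 10, 10))), class = "policy_evaluation")
  expect_equal(select_action(ev, m, 1), c(1L, 1L)) # stay wins
  ev2 <- structure(list(pi = c(rep(0, 1), 0.9, rep(0.1 / 9, 9))),
                   class = "policy_evaluation")
  expect_equal(select_action(ev2, m, 1)[2], 2L)    # report hawk
  # sampling mode is reproducible under a fixed seed
  set.seed(11); u1 <- select_action(ev, m, 1, sample = TRUE)
  set.seed(11); u2 <- select_action(ev, m, 1, sample = TRUE)
  expect_identical(u1, u2)
})

test_that("trials are deterministic given the model and observation sequence", {
  m <- build_agent_model(concept_task("full_knowledge"))
  gp <- build_generative_process(m$task)
  t1 <- run_trial(m, gp, 4)
  t2 <- run_trial(m, gp, 4)
  expect_identical(t1$report_state, t2$report_state)
  expect_identical(t1$pi, t2$pi)
  expect_identical(t1$bma, t2$bma)
})

test_that("learning-mode trials stay at start and observe only null feedback", {
  set.seed(4)
  m <- build_agent_model(concept_task("slots", slots = 5L))
  gp <- build_generative_process(m$task)
  tr <- run_trial(m, gp, 5)
  expect_identical(tr$report_state, 1L)
  expect_identical(tr$feedback, 1L)      # null level
  expect_equal(max(abs(tr$dopamine)), 0, tolerance = 1e-12) # single policy
})

test_that("dimension mismatch between agent and process is an error", {
  m <- build_agent_model(concept_task("full_knowledge"))
  gp <- build_generative_process(concept_task("generalization"))
  gp$features_one_hot[[1]] <- gp$features_one_hot[[1]][, 1:4]
  gp$features_one_hot[[1]] <- rbind(gp$features_one_hot[[1]],
                                    gp$features_one_hot[[1]])
  expect_error(run_trial(m, gp, 1), "dimension")
})
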