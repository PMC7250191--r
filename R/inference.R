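# Per-trial variational belief updating, expected-free-energy policy
# evaluation, precision dynamics, and action selection.

# Per-trial cache of model-derived arrays: expected log-likelihoods,
# posterior-mean likelihoods (as outcome x joint-state matrices), conditional
# outcome entropies H, and the novelty kernel W.
model_cache <- function(model) {
  nm <- model$n_modalities
  fs <- model$factor_sizes
  nj <- prod(fs)
  lnA <- Abar_mat <- Hvec <- W_mat <- vector("list", nm)
  for (m in seq_len(nm)) {
    no <- model$modality_sizes[m]
    if (!is.null(model$a)) {
      am <- matrix(model$a[[m]], no, nj) # flat view over the joint state
      tot <- .colSums(am, no, nj)
      lnA[[m]] <- digamma(am) - rep(digamma(tot), each = no)
      Ab <- am * rep(1 / tot, each = no)
      if (model$learn_a) W_mat[[m]] <- 0.5 * (1 / am - rep(1 / tot, each = no))
    } else {
      Ab <- matrix(model$A[[m]], no, nj)
      lnA[[m]] <- ln_safe(Ab)
    }
    Abar_mat[[m]] <- Ab
    Hvec[[m]] <- -.colSums(Ab * ln_safe(Ab), no, nj)
  }
  list(lnA = lnA, Abar_mat = Abar_mat, Hvec = Hvec, W_mat = W_mat,
       lnD = lapply(model$D, ln_safe), nj = nj)
}

# Contract the o-slice of a per-modality (flat) log-likelihood matrix with
# the posteriors of every factor except `f` (time column `tt` of each xs
# entry).
contract_lnA <- function(lnA_m, o, xs, f, tt, fs) {
  nf <- length(fs)
  vec <- lnA_m[o, ]
  if (nf == 1) return(vec)
  if (nf == 2) {
    sl <- matrix(vec, fs[1], fs[2])
    if (f == 1) return(as.vector(sl %*% xs[[2]][, tt]))
    return(as.vector(crossprod(sl, xs[[1]][, tt])))
  }
  res <- array(vec, fs)
  dims_left <- seq_len(nf)
  for (g in rev(seq_len(nf))) {
    if (g == f) next
    pos <- match(g, dims_left)
    d <- dim(res)
    if (is.null(d)) d <- length(res)
    perm <- c(setdiff(seq_along(d), pos), pos)
    res <- aperm(array(res, d), perm)
    res <- matrix(res, ncol = d[pos]) %*% xs[[g]][, tt]
    dims_left <- dims_left[-pos]
    if (length(dims_left) > 1) dim(res) <- fs[dims_left] else dim(res) <- NULL
  }
  as.vector(res)
}

# Exact two-filter (forward-backward) smoothing for one factor along the
# trial, given per-time-point likelihood weights.
fb_smooth <- function(lik, D, Bf, actions) {
  ns <- length(D)
  TT <- ncol(lik)
  al <- matrix(0, ns, TT)
  al[, 1] <- norm1(D * lik[, 1])
  if (TT > 1) {
    for (tt in 2:TT) {
      al[, tt] <- norm1(lik[, tt] * (Bf[, , actions[tt - 1]] %*% al[, tt - 1]))
    }
  }
  be <- matrix(1, ns, TT)
  if (TT > 1) {
    for (tt in (TT - 1):1) {
      be[, tt] <- norm1(crossprod(Bf[, , actions[tt]], lik[, tt + 1] * be[, tt + 1]))
    }
  }
  x <- al * be
  x * rep(1 / .colSums(x, ns, TT), each = ns)
}

# One variational sweep: refresh every factor's likelihood messages from the
# other factors' current posteriors and re-smooth along the trial. `lambda`
# applies log-space damping (used when recording gradual iterates).
vb_sweep <- function(xs, lambda, model, cache, obs, policy, fs, TT, t_obs) {
  nf <- length(fs)
  nm <- model$n_modalities
  delta <- 0
  vs <- vector("list", nf)
  for (f in seq_len(nf)) {
    Lf <- matrix(0, fs[f], TT)
    if (t_obs > 0) {
      for (tt in seq_len(t_obs)) {
        acc <- Lf[, tt]
        for (m in seq_len(nm)) {
          acc <- acc + contract_lnA(cache$lnA[[m]], obs[m, tt], xs, f, tt, fs)
        }
        Lf[, tt] <- acc
      }
    }
    lik <- Lf
    for (tt in seq_len(TT)) lik[, tt] <- exp(Lf[, tt] - max(Lf[, tt]))
    target <- fb_smooth(lik, model$D[[f]], model$B[[f]], policy[, f])
    if (lambda > 0) {
      v <- (1 - lambda) * ln_safe(xs[[f]]) + lambda * ln_safe(target)
      xnew <- v
      for (tt in seq_len(TT)) xnew[, tt] <- softmax(v[, tt])
    } else {
      v <- ln_safe(target)
      xnew <- target
    }
    delta <- max(delta, abs(xnew - xs[[f]]))
    xs[[f]] <- xnew
    vs[[f]] <- v
  }
  list(xs = xs, vs = vs, delta = delta)
}

#' Infer hidden states under a policy
#'
#' Fixed-point variational state estimation for one policy: each sweep
#' recomputes, for every factor, the per-time-point likelihood messages
#' (expected log-likelihoods of the observations so far, marginalized over the
#' other factors' current posteriors) and combines them with the prior and
#' transition messages along the trial. Sweeps repeat until the posteriors
#' stop changing. Time points beyond the observations carry pure predictions.
#'
#' When `keep_history = TRUE` the first `n_sweeps` sweeps are damped in log
#' space and every iterate is recorded: the recorded log-potentials play the
#' role of depolarization trajectories and the softmaxed iterates that of
#' population firing rates; a final undamped pass then polishes the fixed
#' point.
#'
#' @param model a `genmdp` object.
#' @param obs integer matrix `n_modalities x t_observed` of outcome indices
#'   observed so far (columns are time points).
#' @param policy integer matrix `(T - 1) x n_factors` of action indices (a
#'   vector is accepted for single-factor models).
#' @param keep_history record per-sweep iterates for neural readouts.
#' @param n_sweeps number of recorded (damped) sweeps when
#'   `keep_history = TRUE`.
#' @param damping log-space damping of recorded sweeps (0 = undamped).
#' @param tol convergence tolerance on posterior change.
#' @param max_sweeps cap on undamped sweeps; if still changing, the last
#'   iterate is returned with `converged = FALSE` and a warning.
#' @param cache optional precomputed [model_cache()] (internal use).
#' @return List with `x` (per-factor `levels x T` posterior matrices),
#'   `history` (per-factor `levels x T x sweeps` arrays of iterates, plus
#'   `v` log-potential arrays, when recorded), `n_sweeps`, `converged`.
#' @export
infer_states <- function(model, obs, policy, keep_history = FALSE,
                         n_sweeps = 16L, damping = 0.5, tol = 1e-11,
                         max_sweeps = 64L, cache = NULL) {
  if (is.null(cache)) cache <- model_cache(model)
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 1)
  if (is.null(dim(policy))) policy <- matrix(policy, nrow = model$T - 1)
  nf <- model$n_factors
  fs <- model$factor_sizes
  TT <- model$T
  t_obs <- ncol(obs)
  xs <- lapply(fs, function(ns) matrix(1 / ns, ns, TT))
  hist_x <- hist_v <- if (keep_history) {
    lapply(fs, function(ns) array(NA_real_, c(ns, TT, 0)))
  }

  if (keep_history) {
    for (i in seq_len(n_sweeps)) {
      st <- vb_sweep(xs, damping, model, cache, obs, policy, fs, TT, t_obs)
      xs <- st$xs
      for (f in seq_len(nf)) {
        hist_x[[f]] <- array(c(hist_x[[f]], st$xs[[f]]), c(fs[f], TT, i))
        hist_v[[f]] <- array(c(hist_v[[f]], st$vs[[f]]), c(fs[f], TT, i))
      }
    }
  }
  converged <- FALSE
  n_used <- 0L
  for (i in seq_len(max_sweeps)) {
    st <- vb_sweep(xs, 0, model, cache, obs, policy, fs, TT, t_obs)
    xs <- st$xs
    n_used <- i
    if (st$delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("state inference did not converge; returning last iterate")
  list(x = xs,
       history = if (keep_history) list(x = hist_x, v = hist_v),
       n_sweeps = n_used, converged = converged)
}

joint_posterior <- function(xs, tt) {
  v <- xs[[1]][, tt]
  if (length(xs) > 1) {
    for (f in 2:length(xs)) v <- as.vector(outer(v, xs[[f]][, tt]))
  }
  v
}

#' Expected free energy of a policy
#'
#' Scores the outcomes predicted under a policy from the current time point to
#' the trial horizon. For each future time point the predicted outcome
#' distribution is `Abar %*% s` (with `Abar` the posterior-mean likelihood and
#' `s` the predicted joint state); the score sums risk
#' (`o * (ln o - C)`, divergence of predicted outcomes from preferences),
#' ambiguity (expected conditional outcome entropy given states), and
#' subtracts novelty (`o * (W s)` with `W = (1/a - 1/a0)/2`), the expected
#' information gain about the likelihood parameters. Novelty is zero when
#' parameter learning is disabled.
#'
#' @param model a `genmdp` object.
#' @param xs per-factor posterior matrices (from [infer_states()] under the
#'   policy, so that future columns hold predictions).
#' @param t_from first time point to score (typically the current one).
#' @param cache optional precomputed [model_cache()].
#' @return List with total `G` and components `risk`, `ambiguity`, `novelty`.
#' @export
expected_free_energy <- function(model, xs, t_from = 1L, cache = NULL) {
  if (is.null(cache)) cache <- model_cache(model)
  risk <- amb <- nov <- 0
  if (t_from <= model$T) {
    for (tt in t_from:model$T) {
      sj <- joint_posterior(xs, tt)
      for (m in seq_len(model$n_modalities)) {
        op <- as.vector(cache$Abar_mat[[m]] %*% sj)
        risk <- risk + sum(op * (ln_safe(op) - model$C[[m]]))
        amb <- amb + sum(sj * cache$Hvec[[m]])
        if (!is.null(cache$W_mat[[m]]))
          nov <- nov + sum(op * (cache$W_mat[[m]] %*% sj))
      }
    }
  }
  list(G = risk + amb - nov, risk = risk, ambiguity = amb, novelty = nov)
}

# Accumulated negative log evidence of the observed outcomes under the
# policy-conditioned posteriors.
policy_free_energy <- function(model, xs, obs, cache) {
  if (is.null(dim(obs))) obs <- matrix(obs, ncol = 1)
  Fv <- 0
  for (tt in seq_len(ncol(obs))) {
    sj <- joint_posterior(xs, tt)
    for (m in seq_len(model$n_modalities)) {
      p <- sum(cache$Abar_mat[[m]][obs[m, tt], ] * sj)
      Fv <- Fv - log(max(p, .prob_floor))
    }
  }
  Fv
}

#' Update policy precision (simulated dopamine)
#'
#' Iterates the precision fixed point: `beta_post <- beta0 + (pi - pi0) . G`
#' with `gamma = 1 / beta_post`, where `pi0 = softmax(-gamma * G)` and
#' `pi = softmax(-F - gamma * G)` are the prior and posterior policy
#' distributions. Successive increments of `gamma` are the model's phasic
#' dopamine analogue.
#'
#' @param G numeric vector of per-policy expected free energies.
#' @param Fv numeric vector of per-policy variational free energies.
#' @param beta0 prior precision hyperparameter.
#' @param beta_init starting value of the iteration (defaults to `beta0`;
#'   within a trial the previous time point's posterior is carried forward).
#' @param max_iter,tol iteration controls.
#' @return List with `beta_post`, `gamma`, the `gamma_traj` trajectory over
#'   iterations, `dopamine` (successive increments of `gamma`), and the
#'   converged `pi0` and `pi` distributions.
#' @export
update_precision <- function(G, Fv, beta0 = 1, beta_init = beta0,
                             max_iter = 16L, tol = 1e-8) {
  beta <- beta_init
  gtr <- numeric(0)
  for (i in seq_len(max_iter)) {
    g <- 1 / beta
    pi0 <- softmax(-g * G)
    pip <- softmax(-Fv - g * G)
    target <- beta0 + sum((pip - pi0) * G)
    if (target <= 0) {
      warning("precision update drove beta non-positive; flooring at 1e-3")
      target <- 1e-3
    }
    bnew <- beta + (target - beta) / 2
    gtr <- c(gtr, 1 / bnew)
    done <- abs(bnew - beta) < tol
    beta <- bnew
    if (done) break
  }
  g <- 1 / beta
  list(beta_post = beta, gamma = g,
       gamma_traj = gtr, dopamine = diff(c(1 / beta_init, gtr)),
       pi0 = softmax(-g * G), pi = softmax(-Fv - g * G))
}

#' Evaluate the allowed policies
#'
#' Computes per-policy expected free energy `G` (with components), accumulated
#' free energy `F` of the observations so far, and — after iterating the
#' precision fixed point — the prior (`softmax(-gamma G)`) and posterior
#' (`softmax(-F - gamma G)`) policy distributions.
#'
#' @param model a `genmdp` object.
#' @param xs_by_policy list of per-policy posterior sets (each the `x` entry
#'   of an [infer_states()] result).
#' @param obs integer matrix of observations so far.
#' @param t current time point (expected free energy is scored from here to
#'   the horizon).
#' @param beta_init starting precision for [update_precision()].
#' @param cache optional [model_cache()].
#' @return List of class `policy_evaluation`: `G`, `F`, component matrices,
#'   `pi0`, `pi`, and the `precision` state.
#' @export
evaluate_policies <- function(model, xs_by_policy, obs, t = 1L,
                              beta_init = model$beta0, cache = NULL) {
  if (is.null(cache)) cache <- model_cache(model)
  np <- dim(model$policies)[1]
  if (np < 1) stop("empty policy set")
  if (length(xs_by_policy) != np) stop("one posterior set per policy required")
  G <- Fv <- risk <- amb <- nov <- numeric(np)
  for (p in seq_len(np)) {
    ge <- expected_free_energy(model, xs_by_policy[[p]], t_from = t, cache = cache)
    G[p] <- ge$G; risk[p] <- ge$risk; amb[p] <- ge$ambiguity; nov[p] <- ge$novelty
    Fv[p] <- policy_free_energy(model, xs_by_policy[[p]], obs, cache)
  }
  prec <- update_precision(G, Fv, beta0 = model$beta0, beta_init = beta_init)
  structure(list(G = G, F = Fv, risk = risk, ambiguity = amb, novelty = nov,
                 pi0 = prec$pi0, pi = prec$pi, precision = prec),
            class = "policy_evaluation")
}

#' Select an action from a policy evaluation
#'
#' Marginalizes the posterior policy distribution over the action each policy
#' prescribes at the current time point, then either takes the argmax (ties
#' broken toward the lowest action index; the default) or samples from the
#' marginal.
#'
#' @param evaluation a `policy_evaluation`.
#' @param model the evaluated `genmdp`.
#' @param t time point (transition index) of the action.
#' @param sample draw the action from the marginal instead of maximizing.
#' @return Integer vector: one action index per factor.
#' @export
select_action <- function(evaluation, model, t = 1L, sample = FALSE) {
  nf <- model$n_factors
  u <- integer(nf)
  for (f in seq_len(nf)) {
    acts <- model$policies[, t, f]
    nu <- dim(model$B[[f]])[3]
    marg <- vapply(seq_len(nu), function(k) sum(evaluation$pi[acts == k]),
                   numeric(1))
    u[f] <- if (sample) sample.int(nu, 1, prob = marg) else which.max(marg)
  }
  u
}

#' Run one trial
#'
#' Simulates a complete two-phase trial: at the first time point the agent
#' observes the stimulus features (the report factor rests at "start"), infers
#' hidden states under every allowed policy, evaluates policies and precision,
#' and selects an action; the action moves the report factor, the generative
#' process returns the features again plus feedback, and beliefs, policy
#' posteriors and precision are updated once more. Policies that prescribed a
#' different report are retained as counterfactuals whose free energy
#' discounts them.
#'
#' @param model a `genmdp` agent (its active policy set determines whether the
#'   trial is a restricted learning trial or a reporting trial).
#' @param gp a generative process from [build_generative_process()].
#' @param animal true hidden-cause index drawn by the caller's schedule.
#' @param keep_history record per-sweep inference iterates (see
#'   [infer_states()]) for neural readouts.
#' @param sample_action sample rather than maximize the action marginal.
#' @return A `trial_record`: observations, chosen actions, final report state,
#'   per-policy and Bayesian-model-average posteriors, policy evaluation,
#'   precision/dopamine trajectories, and optional iteration histories.
#' @export
run_trial <- function(model, gp, animal, keep_history = FALSE,
                      sample_action = FALSE) {
  if (!identical(dim(model$A[[1]])[1], nrow(gp$features_one_hot[[1]])))
    stop("agent and generative process dimensions do not match")
  cache <- model_cache(model)
  np <- dim(model$policies)[1]
  TT <- model$T

  obs1 <- observe(gp, animal, report_state = 1L)
  obs <- matrix(obs1, ncol = 1)
  xs1 <- vector("list", np)
  for (p in seq_len(np)) {
    xs1[[p]] <- infer_states(model, obs, policy = model$policies[p, , ],
                             cache = cache)$x
  }
  ev1 <- evaluate_policies(model, xs1, obs, t = 1L, cache = cache)
  u <- select_action(ev1, model, t = 1L, sample = sample_action)
  rep_state <- which(gp$B_report[, 1L, u[length(u)]] == 1)

  obs2 <- observe(gp, animal, report_state = rep_state)
  obs <- cbind(obs, obs2)
  xs2 <- vector("list", np)
  hist_rec <- NULL
  for (p in seq_len(np)) {
    res <- infer_states(model, obs, policy = model$policies[p, , ],
                        keep_history = keep_history, cache = cache)
    xs2[[p]] <- res$x
    if (keep_history && p == 1L) hist_rec <- res$history
  }
  ev2 <- evaluate_policies(model, xs2, obs, t = TT,
                           beta_init = ev1$precision$beta_post, cache = cache)

  bma <- lapply(seq_len(model$n_factors), function(f) {
    acc <- matrix(0, model$factor_sizes[f], TT)
    for (p in seq_len(np)) acc <- acc + ev2$pi[p] * xs2[[p]][[f]]
    acc
  })
  if (keep_history && np > 1L) {
    # weight recorded iterates by the final policy posterior
    hx <- hist_rec$x
    for (p in seq_len(np)) {
      if (p == 1L) next
      res <- infer_states(model, obs, policy = model$policies[p, , ],
                          keep_history = TRUE, cache = cache)$history
      for (f in seq_along(hx)) {
        hx[[f]] <- hx[[f]] + ev2$pi[p] * (res$x[[f]] - hist_rec$x[[f]])
      }
    }
    hist_rec$x <- hx
  }

  structure(list(
    obs = obs, actions = u, report_state = rep_state, animal = animal,
    feedback = obs2[length(obs2)],
    evaluation = list(t1 = ev1, t2 = ev2),
    pi = ev2$pi, bma = bma,
    gamma_traj = c(ev1$precision$gamma_traj, ev2$precision$gamma_traj),
    dopamine = c(ev1$precision$dopamine, ev2$precision$dopamine),
    history = hist_rec,
    mode = model$mode, learn = c(a = model$learn_a, d = model$learn_d)
  ), class = "trial_record")
}
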