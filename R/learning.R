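# Experience-dependent accumulation of Dirichlet counts for likelihood (a)
# and initial-state (d) parameters.

#' Accumulate likelihood concentration parameters after a trial
#'
#' For every modality and time point, adds `eta` times the outer product of
#' the observed-outcome indicator with the Bayesian-model-average posterior
#' over the joint hidden state: the count of how often the agent observed an
#' outcome while believing it occupied each state.
#'
#' @param model a `genmdp` with `a` counts present.
#' @param trial a `trial_record` from [run_trial()].
#' @param eta learning rate (count increment scale); `eta = 0` leaves the
#'   model untouched.
#' @return The model with updated `a`.
#' @export
learn_A <- function(model, trial, eta = model$eta) {
  if (is.null(model$a)) stop("model has no likelihood concentration parameters")
  if (eta == 0) return(model)
  nf <- model$n_factors
  for (tt in seq_len(ncol(trial$obs))) {
    sj <- trial$bma[[1]][, tt]
    if (nf > 1) for (f in 2:nf) sj <- as.vector(outer(sj, trial$bma[[f]][, tt]))
    for (m in seq_len(model$n_modalities)) {
      am <- model$a[[m]]
      no <- dim(am)[1]
      idx <- trial$obs[m, tt] + no * (seq_along(sj) - 1L)
      am[idx] <- am[idx] + eta * sj
      model$a[[m]] <- am
    }
  }
  # model$A holds posterior means only at build time; inference reads the
  # counts directly, so the probabilities are refreshed on demand instead of
  # per trial
  model
}

#' Refresh posterior-mean likelihoods from the learned counts
#'
#' @param model a `genmdp` with `a` counts.
#' @return The model with `A = normalize_counts(a)`.
#' @export
sync_likelihood <- function(model) {
  if (!is.null(model$a)) model$A <- lapply(model$a, normalize_counts)
  model
}

#' Accumulate initial-state concentration parameters after a trial
#'
#' Adds `eta` times the Bayesian-model-average posterior over the first
#' hidden-state factor at the first time point: a count of how often the agent
#' believes it started the trial in each state. Factors without `d` counts
#' (e.g. the report factor, which always starts at "start") are untouched.
#'
#' @inheritParams learn_A
#' @return The model with updated `d` (and refreshed `D`).
#' @export
learn_D <- function(model, trial, eta = model$eta) {
  if (is.null(model$d)) stop("model has no initial-state concentration parameters")
  if (eta == 0) return(model)
  for (f in seq_len(model$n_factors)) {
    if (is.null(model$d[[f]])) next
    df <- model$d[[f]] + eta * trial$bma[[f]][, 1]
    model$d[[f]] <- df
    model$D[[f]] <- df / sum(df)
  }
  model
}

apply_learning <- function(model, trial) {
  if (model$learn_a) model <- learn_A(model, trial)
  if (model$learn_d) model <- learn_D(model, trial)
  model
}

#' Run a block of unsupervised learning trials
#'
#' Loops [run_trial()] over a stimulus stream, accumulating counts after each
#' trial, and optionally probes reporting accuracy at scheduled checkpoints
#' (with learning frozen; see [freeze_and_probe()]).
#'
#' @param model a `genmdp` agent (typically in `learning` mode).
#' @param gp generative process.
#' @param stream integer vector of true hidden-cause indices, one per trial.
#' @param checkpoints trial indices at which to freeze and probe (0 probes the
#'   starting model); `NULL` for none.
#' @param probes_per_animal probe trials per hidden cause at each checkpoint.
#' @return List with the updated `model` and, when probed, a `curve` data
#'   frame (checkpoint, accuracy, proportion basic/specific reports).
#' @export
run_learning_block <- function(model, gp, stream, checkpoints = NULL,
                               probes_per_animal = 20L) {
  curve <- NULL
  probe_now <- function(model, at) {
    pr <- freeze_and_probe(model, gp, probes_per_animal = probes_per_animal)
    rbind(curve, data.frame(checkpoint = at, accuracy = pr$accuracy,
                            prop_basic = pr$prop_basic,
                            prop_specific = pr$prop_specific))
  }
  if (!is.null(checkpoints) && 0 %in% checkpoints) curve <- probe_now(model, 0L)
  for (i in seq_along(stream)) {
    trial <- run_trial(model, gp, stream[i])
    model <- apply_learning(model, trial)
    if (!is.null(checkpoints) && i %in% checkpoints) curve <- probe_now(model, i)
  }
  list(model = model, curve = curve)
}

#' Freeze learning and probe reporting accuracy
#'
#' Copies the model, disables count accumulation, switches to the reporting
#' policy set, and runs a balanced block of probe trials (each hidden cause
#' presented `probes_per_animal` times). Probing is a pure evaluation: the
#' learned model is never mutated.
#'
#' Because learning is unsupervised, the agent routinely assigns a novel
#' category to a different spare column than the generative process uses; a
#' report is scored as correct when it names the column's acquired identity.
#' The identity map is the likelihood-optimal bijection between the model's
#' spare columns and the animals they were free to learn (known columns map to
#' themselves); see [slot_identity_map()].
#'
#' @param model learned `genmdp` agent.
#' @param gp generative process.
#' @param probes_per_animal probe trials per hidden cause.
#' @param relabel_slots integer vector of spare-column indices to relabel
#'   before scoring (defaults to the model's recorded slot set); use
#'   `integer(0)` to score raw report labels.
#' @return List with overall specific-report `accuracy`, proportions of basic
#'   and specific reports, a per-animal accuracy vector, and the per-trial
#'   results table.
#' @export
freeze_and_probe <- function(model, gp, probes_per_animal = 20L,
                             relabel_slots = NULL) {
  probe <- model
  probe$learn_a <- FALSE
  probe$learn_d <- FALSE
  if (!is.null(probe$policy_sets$reporting)) probe <- set_mode(probe, "reporting")
  if (is.null(relabel_slots)) relabel_slots <- probe$task$slots
  col_to_animal <- seq_len(model$factor_sizes[1])
  if (length(relabel_slots) > 0) {
    col_to_animal <- slot_identity_map(probe, gp, relabel_slots)
  }
  n_animals <- model$factor_sizes[1]
  n <- n_animals * probes_per_animal
  animal_v <- rep(seq_len(n_animals), each = probes_per_animal)
  state_v <- integer(n)
  type_v <- character(n)
  cs_v <- cb_v <- logical(n)
  for (k in seq_len(n)) {
    animal <- animal_v[k]
    trial <- run_trial(probe, gp, animal)
    cl <- classify_report(gp, trial$report_state)
    state_v[k] <- trial$report_state
    type_v[k] <- cl$type
    cs_v[k] <- cl$type == "specific" && col_to_animal[cl$index] == animal
    cb_v[k] <- cl$type == "basic" && cl$class == gp$class[animal]
  }
  tab <- data.frame(
    animal = animal_v, probe = rep(seq_len(probes_per_animal), n_animals),
    report_state = state_v, report_type = type_v,
    correct_specific = cs_v, correct_basic = cb_v)
  per_animal <- tapply(tab$correct_specific, tab$animal, mean)
  list(accuracy = mean(tab$correct_specific),
       prop_basic = mean(tab$report_type == "basic"),
       prop_specific = mean(tab$report_type == "specific"),
       generic_accuracy = mean(tab$correct_basic),
       per_animal = as.numeric(per_animal),
       trials = tab,
       col_to_animal = col_to_animal)
}

#' Identify which animal each spare column has acquired
#'
#' Scores every (spare column, candidate animal) pair by the expected
#' log-likelihood the column assigns to the animal's true feature bundle and
#' returns the bijection (over the spare set) that maximizes the total score;
#' known columns keep their own label.
#'
#' @param model learned `genmdp` agent.
#' @param gp generative process.
#' @param slots integer vector of spare-column indices.
#' @return Integer vector mapping each concept column to the animal label a
#'   report of that column should be scored as.
#' @export
slot_identity_map <- function(model, gp, slots) {
  n <- model$factor_sizes[1]
  col_to_animal <- seq_len(n)
  k <- length(slots)
  if (k == 0) return(col_to_animal)
  cache <- model_cache(model)
  score <- matrix(0, k, k) # slot column x candidate animal (both over `slots`... candidates = slots' true animals
  candidates <- slots      # the animals the spare columns were free to learn
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      s <- 0
      for (m in seq_along(gp$features_one_hot)) {
        o <- gp$feature_obs[m, candidates[j]]
        lnA <- cache$lnA[[m]]
        s <- s + matrix(lnA, nrow = dim(lnA)[1])[o, slots[i]] # report = start slice
      }
      score[i, j] <- s
    }
  }
  perms <- all_permutations(k)
  totals <- apply(perms, 1, function(p) sum(score[cbind(seq_len(k), p)]))
  best <- perms[which.max(totals), ]
  col_to_animal[slots] <- candidates[best]
  col_to_animal
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
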