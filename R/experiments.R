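# Scripted, seeded reproductions of the simulation studies: concept addition,
# duplication avoidance, granularity learning, model recovery by Bayesian
# model reduction, and one-shot generalization.

#' Spawn per-repeat seeds from a master seed
#'
#' All experiment-level randomness flows from one master seed through this
#' rule: the master seed initializes the RNG once and `n` integer seeds are
#' drawn, one per repeat.
#'
#' @param master master seed (integer).
#' @param n number of repeats.
#' @return Integer vector of `n` seeds.
#' @export
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(2^31 - 2, n))
}

# canonical presentation order used when only a subset of animals is shown:
# alternating bird / fish so any prefix mixes both classes
.presentation_order <- c(1L, 5L, 2L, 7L, 4L, 6L, 3L, 8L)

default_slots <- function(n_new) {
  switch(as.character(n_new),
         "1" = 5L,          # sturgeon unknown
         "2" = c(4L, 7L),   # parakeet and minnow unknown
         "4" = 1:4,         # all four birds unknown
         stop("n_new must be 1, 2, or 4"))
}

new_experiment <- function(name, params, seeds, per_repeat, extra = list()) {
  agg <- list(
    mean_accuracy = mean(per_repeat$accuracy),
    sd_accuracy = stats::sd(per_repeat$accuracy),
    range_accuracy = range(per_repeat$accuracy))
  structure(c(list(name = name, params = params, seeds = seeds,
                   per_repeat = per_repeat, aggregate = agg), extra),
            class = "concept_experiment")
}

#' @export
print.concept_experiment <- function(x, ...) {
  cat("Experiment:", x$name, "\n")
  cat("  repeats:", nrow(x$per_repeat), "\n")
  if (!is.null(x$aggregate$mean_accuracy) && !is.na(x$aggregate$mean_accuracy)) {
    cat(sprintf("  accuracy: mean %.4f, sd %.4f, range [%.4f, %.4f]\n",
                x$aggregate$mean_accuracy, x$aggregate$sd_accuracy,
                x$aggregate$range_accuracy[1], x$aggregate$range_accuracy[2]))
  }
  invisible(x)
}

#' Concept addition by state-space expansion
#'
#' One, two, or four concept columns start as naive slots; the agent receives
#' `trials` unsupervised exposures to all eight animals with equal probability
#' (reports disabled, so no corrective feedback), after which learning is
#' frozen and reporting accuracy is probed with `probes_per_animal` trials per
#' animal.
#'
#' @param n_new number of concepts to learn (1, 2, or 4).
#' @param trials unsupervised exposures per repeat.
#' @param repeats independent repeats (fresh jitter and stream).
#' @param seed master seed.
#' @param probes_per_animal probe trials per animal at each evaluation.
#' @param checkpoints optional trial indices for a learning curve.
#' @return A `concept_experiment` with per-repeat accuracy, report
#'   proportions, and optional curves.
#' @export
exp_expansion <- function(n_new = 1, trials = 2000, repeats = 8, seed = 1,
                          probes_per_animal = 20, checkpoints = NULL) {
  slots <- default_slots(n_new)
  seeds <- spawn_seeds(seed, repeats)
  rows <- vector("list", repeats)
  curves <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    model <- build_agent_model(concept_task("slots", slots = slots))
    gp <- build_generative_process(model$task)
    stream <- sample_stimulus_stream(1:8, n = trials, kind = "uniform")
    blk <- run_learning_block(model, gp, stream, checkpoints = checkpoints,
                              probes_per_animal = probes_per_animal)
    pr <- freeze_and_probe(blk$model, gp, probes_per_animal)
    curves[[r]] <- blk$curve
    rows[[r]] <- data.frame(repeat_ = r, seed = seeds[r],
                            accuracy = pr$accuracy,
                            prop_basic = pr$prop_basic,
                            prop_specific = pr$prop_specific)
  }
  new_experiment(sprintf("expansion_%d_slot", n_new),
                 list(n_new = n_new, trials = trials, slots = slots,
                      probes_per_animal = probes_per_animal),
                 seeds, do.call(rbind, rows), list(curves = curves))
}

#' Duplication avoidance
#'
#' An agent that already knows `known` concepts (and holds the remaining
#' columns as naive slots) is exposed only to familiar animals; adaptive
#' learning should leave the spare columns unengaged. A subsequent novel phase
#' presents the first unknown animal, which should engage a slot.
#'
#' @param known number of known concepts (4 to 7).
#' @param familiar_trials exposures to known animals.
#' @param novel_trials exposures to the novel animal afterwards (0 to skip).
#' @param seed master seed.
#' @return A `concept_experiment` whose per-repeat table holds the fraction of
#'   newly accumulated likelihood mass landing in the spare columns during
#'   each phase.
#' @export
exp_duplication <- function(known = 7, familiar_trials = 80, novel_trials = 20,
                            seed = 1) {
  stopifnot(known >= 1, known <= 7)
  slots <- seq_len(8 - known)              # hawk first
  familiar <- setdiff(1:8, slots)
  set.seed(spawn_seeds(seed, 1))
  model <- build_agent_model(concept_task("slots", slots = slots))
  gp <- build_generative_process(model$task)
  slot_mass <- function(before, after) {
    tot <- new <- 0
    for (m in 1:3) {
      inc <- after$a[[m]] - before$a[[m]]
      tot <- tot + sum(inc)
      new <- new + sum(inc[, slots, , drop = FALSE])
    }
    c(slot = new / max(tot, .Machine$double.eps), total = tot)
  }
  stream1 <- sample_stimulus_stream(familiar, n = familiar_trials,
                                    kind = "uniform")
  m0 <- model
  model <- run_learning_block(model, gp, stream1)$model
  fam <- slot_mass(m0, model)
  nov <- c(slot = NA_real_, total = NA_real_)
  if (novel_trials > 0) {
    m1 <- model
    stream2 <- rep(slots[1], novel_trials)
    model <- run_learning_block(model, gp, stream2)$model
    nov <- slot_mass(m1, model)
  }
  per <- data.frame(repeat_ = 1, seed = seed, accuracy = NA_real_,
                    familiar_slot_mass = fam["slot"],
                    novel_slot_mass = nov["slot"])
  new_experiment(sprintf("duplication_known_%d", known),
                 list(known = known, slots = slots,
                      familiar_trials = familiar_trials,
                      novel_trials = novel_trials),
                 seed, per, list(model = model))
}

#' Granularity learning
#'
#' All eight specific concepts must be differentiated from unsupervised
#' exposure. With `prior_basic = TRUE` the agent starts out knowing the
#' bird/fish distinction (wings/gills rows precise, size and color rows
#' naive); with `prior_basic = FALSE` every feature row starts naive.
#'
#' @inheritParams exp_expansion
#' @param prior_basic start with basic-category knowledge.
#' @return A `concept_experiment`.
#' @export
exp_granularity <- function(prior_basic = TRUE, trials = 2000, repeats = 8,
                            seed = 1, probes_per_animal = 20,
                            checkpoints = NULL) {
  seeds <- spawn_seeds(seed, repeats)
  rows <- vector("list", repeats)
  curves <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    model <- build_agent_model(concept_task("granularity",
                                            prior_basic = prior_basic))
    gp <- build_generative_process(model$task)
    stream <- sample_stimulus_stream(1:8, n = trials, kind = "uniform")
    blk <- run_learning_block(model, gp, stream, checkpoints = checkpoints,
                              probes_per_animal = probes_per_animal)
    pr <- freeze_and_probe(blk$model, gp, probes_per_animal)
    curves[[r]] <- blk$curve
    rows[[r]] <- data.frame(repeat_ = r, seed = seeds[r],
                            accuracy = pr$accuracy,
                            prop_basic = pr$prop_basic,
                            prop_specific = pr$prop_specific)
  }
  new_experiment(sprintf("granularity_%s", if (prior_basic) "basic_prior"
                         else "no_prior"),
                 list(prior_basic = prior_basic, trials = trials,
                      probes_per_animal = probes_per_animal),
                 seeds, do.call(rbind, rows), list(curves = curves))
}

#' Model recovery by Bayesian model reduction
#'
#' Only `n_true` of the eight animals are presented (250 exposures each in
#' randomized order while initial-state counts accumulate); afterwards all
#' reduced priors over the concept factor are compared analytically and the
#' winner's retained set is recorded. With `precise_A = TRUE` the likelihood
#' is clamped to the generative process and only initial-state counts are
#' learned; otherwise likelihood and initial-state counts are learned
#' simultaneously from fully naive columns.
#'
#' @param n_true number of animals actually presented (2 to 7).
#' @param exposures exposures per presented animal.
#' @param repeats independent repeats.
#' @param precise_A clamp the likelihood to the truth.
#' @param seed master seed.
#' @param q eliminated-level prior value (default 1/8 of the retained value).
#' @return A `concept_experiment`; its per-repeat table records the winner's
#'   retained-level count, exact-set recovery (meaningful when the likelihood
#'   is clamped), the runner-up, and the winner-vs-runner-up log-evidence gap.
#' @export
exp_reduction <- function(n_true = 5, exposures = 250, repeats = 100,
                          precise_A = FALSE, seed = 1, q = NULL) {
  stopifnot(n_true >= 2, n_true <= 7)
  presented <- .presentation_order[seq_len(n_true)]
  seeds <- spawn_seeds(seed, repeats)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    model <- build_agent_model(concept_task("reduction",
                                            precise_A = precise_A))
    gp <- build_generative_process(model$task)
    stream <- sample_stimulus_stream(presented, per_animal = exposures,
                                     kind = "balanced")
    model <- run_learning_block(model, gp, stream)$model
    d0 <- model$d_init[[1]]
    qq <- if (is.null(q)) min(d0) / 8 else q
    red <- bmr_reduce(d0, model$d[[1]], q = qq)
    sel <- red$selection
    n_ret <- length(sel$retain)
    rows[[r]] <- data.frame(
      repeat_ = r, seed = seeds[r], accuracy = NA_real_,
      n_retained = n_ret,
      exact_set = setequal(sel$retain, presented),
      correct_count = n_ret == n_true,
      runner_up_count = length(sel$runner_up_retain),
      runner_up_correct = length(sel$runner_up_retain) == n_true,
      gap = sel$gap)
  }
  per <- do.call(rbind, rows)
  wrong <- !per$correct_count
  extra <- list(
    recovery_rate = mean(per$correct_count),
    exact_rate = mean(per$exact_set),
    retained_table = table(factor(per$n_retained, levels = 2:8)),
    second_best_correct = sum(per$runner_up_correct & wrong),
    mean_gap_when_wrong = if (any(wrong)) mean(-abs(per$gap[wrong])) else NA_real_)
  new_experiment(sprintf("reduction_n%d_%s", n_true,
                         if (precise_A) "preciseA" else "learnedA"),
                 list(n_true = n_true, presented = presented,
                      exposures = exposures, precise_A = precise_A),
                 seeds, per, extra)
}

#' One-shot generalization in the distance-question task
#'
#' The agent is asked "could this animal be seen from a distance?" (yes only
#' for large, colorful animals) about an animal whose concept column is naive,
#' with learning disabled. Variant `parrot` withholds a yes-case animal,
#' `minnow` a no-case one; `none` is the fully informed control probed on all
#' eight animals.
#'
#' @param variant which animal is withheld.
#' @param probes probe trials (per animal for the control).
#' @param seed master seed (jitter of the naive column).
#' @return A `concept_experiment`; accuracy is the fraction of correct yes/no
#'   answers.
#' @export
exp_generalization <- function(variant = c("parrot", "minnow", "none"),
                               probes = 20, seed = 1) {
  variant <- match.arg(variant)
  set.seed(spawn_seeds(seed, 1))
  task <- concept_task("generalization",
                       variant = if (variant == "none") "parrot" else variant)
  if (variant == "none") task$slots <- integer(0)
  model <- build_agent_model(task)
  gp <- build_generative_process(task)
  fm <- animal_features()
  truth <- fm$size == "large" & fm$color == "colorful"
  shown <- if (variant == "none") rep(1:8, each = probes)
           else rep(match(variant, .animals), probes)
  res <- vapply(shown, function(animal) {
    trial <- run_trial(model, gp, animal)
    rep_cl <- classify_report(gp, trial$report_state)
    if (rep_cl$type != "answer") return(FALSE)
    (rep_cl$answer == "yes") == truth[animal]
  }, logical(1))
  per <- data.frame(repeat_ = 1, seed = seed, accuracy = mean(res))
  new_experiment(sprintf("generalization_%s", variant),
                 list(variant = variant, probes = probes),
                 seed, per,
                 list(answers = data.frame(animal = shown, correct = res)))
}
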