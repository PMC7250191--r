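# Simulated neurophysiology: firing rates, local field potentials, and
# phasic dopamine derived from stored trial records.

#' Extract simulated neural traces from trial records
#'
#' Under the process theory accompanying this model family, the per-iteration
#' state expectations play the role of population firing rates, the rate of
#' change of the associated log-potentials (depolarization) yields local
#' field potentials, and successive increments of policy precision gamma are
#' the phasic dopamine signal.
#'
#' @param records list of `trial_record`s produced with
#'   `run_trial(..., keep_history = TRUE)`.
#' @param selection indices of the trials to concatenate (default all).
#' @param factor hidden-state factor whose populations are plotted.
#' @param time_point which within-trial time point's iterates to extract.
#' @return A `neural_traces` list: `firing` (populations x iterations),
#'   `lfp` (first differences of depolarization), `dopamine`, `trial` (trial
#'   index of each iteration column), and `final` (final-iteration posterior
#'   per selected trial).
#' @export
extract_traces <- function(records, selection = seq_along(records),
                           factor = 1L, time_point = 1L) {
  sel <- records[selection]
  if (any(vapply(sel, function(r) is.null(r$history), logical(1))))
    stop("selected records carry no iteration histories; rerun with keep_history = TRUE")
  fr <- lapply(sel, function(r) r$history$x[[factor]][, time_point, ])
  vv <- lapply(sel, function(r) r$history$v[[factor]][, time_point, ])
  firing <- do.call(cbind, fr)
  lfp <- do.call(cbind, lapply(vv, function(v) t(apply(v, 1, diff))))
  dopamine <- unlist(lapply(sel, function(r) r$dopamine))
  trial <- rep(selection, vapply(fr, ncol, integer(1)))
  structure(list(
    firing = firing, lfp = lfp, dopamine = dopamine, trial = trial,
    final = do.call(cbind, lapply(fr, function(x) x[, ncol(x)]))
  ), class = "neural_traces")
}

#' Simulate neural responses across concept learning
#'
#' Runs a granularity-learning session (basic categories known, specific ones
#' to be learned) while recording belief-updating iterates on equally spaced
#' presentations of one target animal, then extracts firing-rate, LFP and
#' dopamine traces. With `condition = "unsupervised"` the policy space is
#' restricted to observation (no reports, a flat dopamine signal); with
#' `condition = "reporting"` reporting is enabled throughout, so precision
#' updates generate phasic dopamine responses that grow as the agent becomes
#' confident in reporting specific categories.
#'
#' @param condition `"unsupervised"` or `"reporting"`.
#' @param n_per_animal interleaved exposures per animal.
#' @param target animal whose presentations are recorded.
#' @param n_recorded number of equally spaced target presentations to record.
#' @param seed seed for jitter and stream.
#' @return List with the `traces` (a `neural_traces`), the recorded trial
#'   indices, and the learned model.
#' @export
simulate_neural_responses <- function(condition = c("unsupervised", "reporting"),
                                      n_per_animal = 50, target = "parakeet",
                                      n_recorded = 10, seed = 1) {
  condition <- match.arg(condition)
  set.seed(seed)
  model <- build_agent_model(concept_task("granularity", prior_basic = TRUE))
  if (condition == "reporting") model <- set_mode(model, "reporting")
  gp <- build_generative_process(model$task)
  stream <- sample_stimulus_stream(1:8, per_animal = n_per_animal,
                                   kind = "balanced")
  t_idx <- match(target, .animals)
  target_trials <- which(stream == t_idx)
  rec_at <- target_trials[unique(round(seq(1, length(target_trials),
                                           length.out = n_recorded)))]
  records <- vector("list", length(stream))
  for (i in seq_along(stream)) {
    rec <- run_trial(model, gp, stream[i], keep_history = i %in% rec_at)
    model <- apply_learning(model, rec)
    records[[i]] <- rec
  }
  list(traces = extract_traces(records, rec_at),
       recorded = rec_at, target = t_idx, model = model,
       dopamine_by_trial = vapply(records, function(r) max(r$dopamine, 0),
                                  numeric(1)))
}

#' @export
print.neural_traces <- function(x, ...) {
  cat("Simulated neural traces\n")
  cat("  populations:", nrow(x$firing),
      "; iterations:", ncol(x$firing),
      "; trials:", length(unique(x$trial)), "\n")
  cat("  dopamine samples:", length(x$dopamine), "\n")
  invisible(x)
}

#' Plot a firing-rate raster with LFPs and dopamine
#'
#' Base-graphics summary of a `neural_traces` object: an image of population
#' firing rates over concatenated iterations (darker = higher rate), the LFP
#' traces, and the phasic dopamine signal.
#'
#' @param x a `neural_traces`.
#' @param ... unused.
#' @export
plot.neural_traces <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(1 - x$firing), axes = FALSE,
                  col = grDevices::grey.colors(64),
                  main = "firing rates (dark = high)")
  graphics::matplot(t(x$lfp), type = "l", lty = 1,
                    ylab = "LFP", main = "local field potentials")
  graphics::plot(x$dopamine, type = "h", ylab = expression(Delta * gamma),
                 main = "phasic dopamine")
  invisible(x)
}
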