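# Bayesian model reduction over initial-state Dirichlet priors: candidate
# enumeration, analytic evidence differences, winner selection, slot reset.

#' Log multivariate beta function
#'
#' `ln B(x) = sum(lgamma(x)) - lgamma(sum(x))`: the log normalizer of a
#' Dirichlet distribution with concentration vector `x`.
#'
#' @param x numeric vector of strictly positive counts.
#' @return The log multivariate beta value.
#' @export
log_mbeta <- function(x) {
  if (any(x <= 0)) stop("beta function requires strictly positive counts")
  sum(lgamma(x)) - lgamma(sum(x))
}

#' Evidence difference of a reduced Dirichlet prior
#'
#' Analytic Bayesian model reduction for Dirichlet-categorical models. Given a
#' full prior, the posterior counts it accumulated, and an alternative
#' ("reduced") prior, returns the difference in log evidence the same data
#' provide for the reduced model:
#' `dF = [ln B(reduced posterior) - ln B(reduced prior)]
#'      - [ln B(posterior) - ln B(prior)]`,
#' where the reduced posterior adds the observed data counts
#' (`posterior - prior`) to the reduced prior. `dF > 0` means the reduced
#' model has more evidence.
#'
#' @param prior,posterior full-model concentration vectors; the posterior must
#'   dominate the prior elementwise (counts only accumulate).
#' @param reduced_prior concentration vector of the reduced model.
#' @return The evidence difference `dF` (positive favors the reduced model).
#' @export
bmr_delta_F <- function(prior, posterior, reduced_prior) {
  if (any(posterior < prior - 1e-12))
    stop("posterior counts must dominate the prior (counts only accumulate)")
  if (any(reduced_prior <= 0)) stop("reduced prior must be strictly positive")
  n <- posterior - prior
  reduced_posterior <- reduced_prior + n
  (log_mbeta(reduced_posterior) - log_mbeta(reduced_prior)) -
    (log_mbeta(posterior) - log_mbeta(prior))
}

#' Enumerate reduced priors over initial states
#'
#' One candidate per non-empty proper subset of levels to retain (254 for 8
#' levels). A candidate keeps the full prior on retained levels and assigns
#' the smaller value `q` to eliminated levels, making the to-be-eliminated
#' concepts less likely a priori than the to-be-retained ones.
#'
#' @param n_levels number of levels of the factor.
#' @param full_prior full-model prior counts (scalar recycled, or vector).
#' @param q prior count assigned to eliminated levels; must be smaller than
#'   every retained prior value.
#' @return List of candidates, each with `retain` (indices), `eliminate`, and
#'   `prior` (the reduced concentration vector).
#' @export
enumerate_candidates <- function(n_levels, full_prior = 1, q = full_prior / 8) {
  full_prior <- rep_len(full_prior, n_levels)
  if (any(q >= full_prior))
    stop("eliminated-level prior q must be smaller than every retained value")
  out <- vector("list", 2^n_levels - 2)
  k <- 0L
  for (mask in seq_len(2^n_levels - 2)) {
    retain <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n_levels) - 1L)) != 0)
    prior <- rep(q, n_levels)
    prior[retain] <- full_prior[retain]
    k <- k + 1L
    out[[k]] <- list(retain = retain,
                     eliminate = setdiff(seq_len(n_levels), retain),
                     prior = prior)
  }
  out
}

#' Select the winning model among reduced candidates
#'
#' The full model is retained when no candidate has positive evidence
#' difference; otherwise the candidate with the largest `dF` wins (ties broken
#' toward fewer retained levels, then the lexicographically smallest subset).
#' Also reports the runner-up, the winner-vs-runner-up log-evidence gap, and
#' the posterior model probabilities `m = softmax` of the log evidences over
#' the full model and all candidates.
#'
#' @param candidates list from [enumerate_candidates()].
#' @param delta_F numeric vector of evidence differences, one per candidate.
#' @return List with `winner` (0 = full model, otherwise candidate index),
#'   `retain` (levels the winner keeps), `runner_up`, `gap` (log evidence of
#'   winner minus runner-up), and `m`.
#' @export
select_model <- function(candidates, delta_F) {
  stopifnot(length(candidates) == length(delta_F))
  lev <- c(0, delta_F) # log evidence relative to the full model
  n_ret <- c(length(candidates[[1]]$prior),
             vapply(candidates, function(cc) length(cc$retain), integer(1)))
  subset_key <- c("", vapply(candidates, function(cc)
    paste(sprintf("%02d", cc$retain), collapse = ","), character(1)))
  ord <- order(-lev, n_ret, subset_key)
  best <- ord[1]
  second <- ord[2]
  if (max(delta_F) <= 0) { # full model retained
    best <- 1L
    second <- order(-delta_F)[1] + 1L
  }
  list(
    winner = best - 1L,
    retain = if (best == 1L) seq_len(n_ret[1]) else candidates[[best - 1L]]$retain,
    runner_up = second - 1L,
    runner_up_retain = if (second == 1L) seq_len(n_ret[1]) else
      candidates[[second - 1L]]$retain,
    gap = lev[best] - lev[second],
    m = softmax(lev)
  )
}

#' Run Bayesian model reduction over a learned initial-state prior
#'
#' Convenience wrapper: enumerates all reduced priors for the first
#' hidden-state factor, scores each against the learned counts, and selects
#' the winner.
#'
#' @param d_prior pre-learning concentration vector.
#' @param d_post learned concentration vector.
#' @param q eliminated-level prior value (default 1/8 of the smallest retained
#'   prior).
#' @return List with the `selection` (see [select_model()]), the candidate
#'   list, the `delta_F` vector, and a `report` data frame (subset, dF, m,
#'   winner flag).
#' @export
bmr_reduce <- function(d_prior, d_post, q = min(d_prior) / 8) {
  n <- length(d_prior)
  cand <- enumerate_candidates(n, d_prior, q)
  dF <- vapply(cand, function(cc) bmr_delta_F(d_prior, d_post, cc$prior),
               numeric(1))
  sel <- select_model(cand, dF)
  report <- data.frame(
    candidate = seq_along(cand),
    retain = vapply(cand, function(cc) paste(cc$retain, collapse = ","),
                    character(1)),
    n_retained = vapply(cand, function(cc) length(cc$retain), integer(1)),
    delta_F = dF,
    m = sel$m[-1],
    winner = seq_along(cand) == sel$winner)
  list(selection = sel, candidates = cand, delta_F = dF, report = report)
}

#' Reset eliminated concept slots to their naive state
#'
#' After model reduction licenses the removal of redundant concepts, the
#' corresponding likelihood columns are returned to a fresh flat-plus-jitter
#' initialization (feature modalities; the built-in feedback mapping is
#' restored to its initial counts) and their initial-state counts to the
#' pre-learning values, so the slots are again available for future learning.
#' Retained levels are untouched.
#'
#' @param model a learned `genmdp` built by [build_agent_model()].
#' @param eliminate integer vector of concept levels to reset (empty vector
#'   returns the model unchanged).
#' @return The model with those slots re-naive.
#' @export
reset_slots <- function(model, eliminate) {
  if (length(eliminate) == 0) return(model)
  if (is.null(model$task)) stop("reset_slots requires a task-built model")
  tk <- model$task
  for (m in seq_len(model$n_modalities)) {
    am <- model$a[[m]]
    if (is.null(am)) next
    no <- dim(am)[1]
    for (lev in eliminate) {
      if (m <= length(gp_feature_modalities(model))) {
        am[, lev, ] <- naive_column(no, tk$naive_base, tk$naive_jitter)
      } else {
        am[, lev, ] <- model$a_init[[m]][, lev, ]
      }
    }
    model$a[[m]] <- am
  }
  model$A <- lapply(model$a, normalize_counts)
  if (!is.null(model$d) && !is.null(model$d[[1]])) {
    model$d[[1]][eliminate] <- model$d_init[[1]][eliminate]
    model$D[[1]] <- model$d[[1]] / sum(model$d[[1]])
  }
  model
}

gp_feature_modalities <- function(model) {
  # feature modalities precede the feedback modality by construction
  seq_len(model$n_modalities - 1L)
}
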