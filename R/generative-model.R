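# Factorized discrete generative models with Dirichlet-parameterized
# likelihoods (a) and initial-state priors (d).

# probability floor used wherever a log of a probability array is taken
.prob_floor <- exp(-16)

ln_safe <- function(p) log(pmax(p, .prob_floor))

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

norm1 <- function(x) x / sum(x)

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a discrete (POMDP-style) generative model
#'
#' Bundles the arrays of a factorized categorical generative model: per-modality
#' likelihoods `A` (optionally Dirichlet-parameterized through concentration
#' counts `a`), per-factor transitions `B`, log-preferences `C`, initial-state
#' priors `D` (optionally with counts `d`), the policy set and the trial
#' horizon.
#'
#' @param A list, one entry per outcome modality; each an array of dimension
#'   `c(outcome levels, factor-1 levels, factor-2 levels, ...)` whose columns
#'   (probability of each outcome given a joint hidden state) sum to one.
#' @param B list, one entry per hidden-state factor; each an array
#'   `c(levels, levels, actions)` of column-stochastic transition slices, one
#'   slice per allowable action (a single slice for uncontrollable factors).
#' @param C list of per-modality log-preference vectors over outcome levels
#'   (unnormalized, shared across time points).
#' @param D list of per-factor initial-state probability vectors.
#' @param policies integer array `c(n_policies, T - 1, n_factors)`: the action
#'   index taken for each factor at each transition under each policy.
#' @param T number of time points per trial.
#' @param a optional list of Dirichlet concentration arrays, same shapes as
#'   `A`, strictly positive. When present, inference uses expected
#'   log-likelihoods `psi(a) - psi(a0)` rather than `log(A)`.
#' @param d optional list of per-factor Dirichlet counts over initial states
#'   (entries may be `NULL` for factors whose prior is fixed).
#' @param beta0 prior precision hyperparameter (expected inverse policy
#'   precision); larger values make policy selection more random.
#' @param eta learning rate: the concentration-count increment per inferred
#'   co-occurrence.
#' @param learn_a,learn_d logical flags: which count arrays accumulate.
#' @param labels optional list with character vectors `factors` (state names
#'   per factor) and `modalities` (outcome names per modality).
#' @param policy_sets optional named list of alternative policy arrays (e.g.
#'   `learning` and `reporting` sets) switchable with [set_mode()].
#' @param mode name of the active entry of `policy_sets`, if any.
#'
#' @return An object of class `genmdp`.
#' @seealso [validate_model()], [run_trial()], [build_agent_model()]
#' @export
generative_model <- function(A, B, C, D, policies, T = 2L,
                             a = NULL, d = NULL, beta0 = 1, eta = 1,
                             learn_a = !is.null(a), learn_d = !is.null(d),
                             labels = NULL, policy_sets = NULL, mode = NULL) {
  stopifnot(is.list(A), is.list(B), is.list(C), is.list(D))
  factor_sizes <- vapply(B, function(b) dim(b)[1], integer(1))
  modality_sizes <- vapply(A, function(x) dim(x)[1], integer(1))
  if (is.matrix(policies)) {
    policies <- array(policies, c(nrow(policies), 1L, ncol(policies)))
  }
  m <- structure(list(
    n_factors = length(B), factor_sizes = factor_sizes,
    n_modalities = length(A), modality_sizes = modality_sizes,
    A = A, a = a, B = B, C = C, D = D, d = d,
    policies = policies, T = as.integer(T),
    beta0 = beta0, eta = eta,
    learn_a = isTRUE(learn_a), learn_d = isTRUE(learn_d),
    labels = labels, policy_sets = policy_sets, mode = mode
  ), class = "genmdp")
  m
}

#' Switch a model between named policy sets
#'
#' Models built by [build_agent_model()] carry both a restricted `learning`
#' policy set (stay only: no verbal report, no feedback) and a `reporting`
#' set. This swaps the active set.
#'
#' @param model a `genmdp` object with a `policy_sets` entry.
#' @param mode name of the policy set to activate.
#' @return The model with `policies` replaced.
#' @export
set_mode <- function(model, mode) {
  if (is.null(model$policy_sets) || is.null(model$policy_sets[[mode]]))
    stop("model has no policy set named '", mode, "'")
  p <- model$policy_sets[[mode]]
  if (is.matrix(p)) p <- array(p, c(nrow(p), 1L, ncol(p)))
  model$policies <- p
  model$mode <- mode
  model
}

#' Validate a generative model
#'
#' Checks the structural invariants of a `genmdp` object: likelihood columns
#' sum to one, concentration parameters are strictly positive, transition
#' slices are column-stochastic, and every policy indexes a valid action for
#' each factor.
#'
#' @param model a `genmdp` object.
#' @param tol tolerance on column sums.
#' @return Character vector of violation descriptions; `character(0)` if the
#'   model is well formed.
#' @export
validate_model <- function(model, tol = 1e-10) {
  bad <- character(0)
  fs <- model$factor_sizes
  for (m in seq_len(model$n_modalities)) {
    Am <- model$A[[m]]
    cs <- apply(Am, seq_along(dim(Am))[-1], sum)
    off <- which(abs(cs - 1) > tol)
    for (j in off) {
      bad <- c(bad, sprintf(
        "A[[%d]] column %d sums to %.6g (must sum to 1)", m, j, cs[j]))
    }
    if (!is.null(model$a)) {
      am <- model$a[[m]]
      if (!is.null(am) && any(am <= 0))
        bad <- c(bad, sprintf(
          "a[[%d]] has %d non-positive entries (all counts must be > 0)",
          m, sum(am <= 0)))
    }
  }
  for (f in seq_len(model$n_factors)) {
    Bf <- model$B[[f]]
    for (u in seq_len(dim(Bf)[3])) {
      cs <- colSums(Bf[, , u])
      off <- which(abs(cs - 1) > tol)
      for (j in off) {
        bad <- c(bad, sprintf(
          "B[[%d]] action %d column %d sums to %.6g (must be column-stochastic)",
          f, u, j, cs[j]))
      }
    }
    if (abs(sum(model$D[[f]]) - 1) > 1e-8)
      bad <- c(bad, sprintf("D[[%d]] does not sum to 1", f))
    if (!is.null(model$d) && !is.null(model$d[[f]]) && any(model$d[[f]] <= 0))
      bad <- c(bad, sprintf(
        "d[[%d]] violates positivity (all initial-state counts must be > 0)", f))
  }
  pol <- model$policies
  if (dim(pol)[2] != model$T - 1)
    bad <- c(bad, sprintf("policies have %d transitions; expected T - 1 = %d",
                          dim(pol)[2], model$T - 1))
  for (f in seq_len(model$n_factors)) {
    nu <- dim(model$B[[f]])[3]
    if (any(pol[, , f] < 1 | pol[, , f] > nu))
      bad <- c(bad, sprintf("policy action index out of range for factor %d", f))
  }
  bad
}

#' Expected log-likelihood of a Dirichlet count array
#'
#' Converts concentration parameters into expected log-probabilities with
#' digamma functions: `psi(a) - psi(a0)`, where `a0` is the per-column total
#' over outcome levels. This is the likelihood surrogate used throughout
#' belief updating when parameter learning is enabled.
#'
#' @param a array (or matrix/vector) of strictly positive concentration
#'   parameters; the first dimension indexes outcome levels.
#' @return Array of the same shape with expected log-probabilities.
#' @export
expected_log_likelihood <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (any(a <= 0)) stop("concentration parameters must be strictly positive")
  no <- dim(a)[1]
  tot <- apply(a, seq_along(dim(a))[-1], sum)
  out <- digamma(a) - rep(digamma(tot), each = no)
  array(out, dim(a), dimnames = dimnames(a))
}

#' Posterior-mean probabilities of a Dirichlet count array
#'
#' Divides each column (over outcome levels, the first dimension) by its sum.
#'
#' @param a array of positive counts; first dimension indexes outcomes.
#' @return Column-stochastic array of the same shape.
#' @export
normalize_counts <- function(a) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (any(a < 0)) stop("counts must be non-negative")
  no <- dim(a)[1]
  tot <- apply(a, seq_along(dim(a))[-1], sum)
  if (any(tot == 0)) stop("zero-sum column cannot be normalized")
  array(a / rep(tot, each = no), dim(a), dimnames = dimnames(a))
}

#' Flat-plus-jitter initialization of a spare concept column
#'
#' Spare ("naive") hidden-state slots start with likelihood columns that are
#' flat over outcomes with a slight amount of Gaussian noise, so that they
#' predict every feature nearly equally while still breaking ties between
#' multiple empty slots.
#'
#' @param n_outcomes number of outcome levels in the modality.
#' @param base baseline concentration count per entry.
#' @param jitter standard deviation of the multiplicative Gaussian jitter.
#' @param seed optional seed; when given the column is drawn under a local
#'   RNG state, leaving the caller's stream untouched.
#' @return Numeric vector of `n_outcomes` positive counts.
#' @export
naive_column <- function(n_outcomes, base = 1, jitter = 0.1, seed = NULL) {
  stopifnot(base > 0)
  with_seed(seed, {
    z <- if (jitter > 0) stats::rnorm(n_outcomes, 0, jitter) else rep(0, n_outcomes)
    pmax(base * (1 + z), 0.01 * base)
  })
}

#' @export
print.genmdp <- function(x, ...) {
  cat("Discrete generative model (genmdp)\n")
  cat("  hidden-state factors: ",
      paste(x$factor_sizes, collapse = " x "), "\n", sep = "")
  cat("  outcome modalities:   ",
      paste(x$modality_sizes, collapse = ", "), "\n", sep = "")
  cat("  time points: ", x$T,
      "; policies: ", dim(x$policies)[1],
      if (!is.null(x$mode)) paste0(" (mode: ", x$mode, ")"), "\n", sep = "")
  cat("  learning: a = ", x$learn_a, ", d = ", x$learn_d,
      ", eta = ", x$eta, ", beta0 = ", x$beta0, "\n", sep = "")
  invisible(x)
}
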