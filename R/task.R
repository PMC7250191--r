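# The animal-categorization task: feature map, agent model presets, matching
# generative process, report semantics, and the distance-question variant.

.animals <- c("hawk", "parrot", "pigeon", "parakeet",
              "sturgeon", "whale_shark", "minnow", "clownfish")
.sizes <- c("large", "small")
.colors <- c("gray", "colorful")
.species <- c("wings", "gills")
.feedback_levels <- c("null", "correct_basic", "correct_specific", "incorrect")

#' The animal-to-feature map
#'
#' Eight animal concepts, each a unique point in the three-dimensional feature
#' space of size (large/small), color (gray/colorful) and the
#' species-differentiating feature (wings/gills). The four winged animals are
#' birds and the four gilled ones fish.
#'
#' @return Data frame with one row per animal: name, size, color, species
#'   feature, basic class, and the corresponding outcome indices.
#' @export
animal_features <- function() {
  idx <- rbind(
    hawk        = c(1, 1, 1),
    parrot      = c(1, 2, 1),
    pigeon      = c(2, 1, 1),
    parakeet    = c(2, 2, 1),
    sturgeon    = c(1, 1, 2),
    whale_shark = c(1, 2, 2),
    minnow      = c(2, 1, 2),
    clownfish   = c(2, 2, 2))
  data.frame(
    animal = .animals,
    size = .sizes[idx[, 1]], color = .colors[idx[, 2]],
    species = .species[idx[, 3]],
    class = ifelse(idx[, 3] == 1, "bird", "fish"),
    size_idx = idx[, 1], color_idx = idx[, 2], species_idx = idx[, 3],
    row.names = NULL)
}

#' Specify a concept-task preset
#'
#' Collects the parameters that define an agent for the animal task: which
#' concept columns start as naive "slots", the concentration scale of known
#' columns, the naive flat-plus-jitter initialization, the feedback
#' preferences, and which counts are learned.
#'
#' Presets:
#' \describe{
#'   \item{`full_knowledge`}{fully precise likelihood, reporting enabled,
#'     no learning.}
#'   \item{`basic_only`}{size and color rows flattened; only the wings/gills
#'     mapping is informative.}
#'   \item{`slots`}{`slots` concept columns start naive; likelihood counts
#'     are learned from unsupervised exposure.}
#'   \item{`granularity`}{all 8 columns must be differentiated; with
#'     `prior_basic = TRUE` the wings/gills rows start precise (the agent
#'     knows bird vs fish), otherwise every feature row starts naive.}
#'   \item{`reduction`}{the model-recovery setup: initial-state counts are
#'     learned alongside the likelihood (or alone when `precise_A = TRUE`,
#'     which clamps the likelihood to the generative process).}
#'   \item{`generalization`}{the distance-question variant; see
#'     [build_generalization_task()].}
#' }
#'
#' @param preset preset name (see Details).
#' @param slots integer indices of concept columns that start naive.
#' @param prior_basic granularity preset: start with basic-category knowledge.
#' @param precise_A reduction preset: clamp the likelihood to the truth and
#'   learn initial-state counts only.
#' @param variant generalization preset: which animal is withheld (`parrot`,
#'   whose answer is yes, or `minnow`, whose answer is no).
#' @param known_scale concentration scale of known (precise) columns.
#' @param known_eps probability smeared off the known outcome within a
#'   precise column (keeps all counts strictly positive).
#' @param naive_base,naive_jitter naive-slot initialization (see
#'   [naive_column()]).
#' @param preferences named log-preference values on the feedback modality.
#' @param d0 prior initial-state count per concept.
#' @param eta learning rate.
#' @param beta0 prior precision hyperparameter.
#' @return A `task_spec` list, input to [build_agent_model()].
#' @export
concept_task <- function(preset = c("full_knowledge", "basic_only", "slots",
                                    "granularity", "reduction",
                                    "generalization"),
                         slots = integer(0), prior_basic = TRUE,
                         precise_A = FALSE,
                         variant = c("parrot", "minnow"),
                         known_scale = 200, known_eps = 0.01,
                         naive_base = 1, naive_jitter = 0.1,
                         preferences = c(null = 0, correct_basic = 2,
                                         correct_specific = 4, incorrect = -6),
                         d0 = 1, eta = 1, beta0 = 1) {
  preset <- match.arg(preset)
  variant <- match.arg(variant)
  flatten <- integer(0)
  naive_cols <- integer(0) # columns naive in every feature modality
  clamped <- FALSE
  learn_a <- learn_d <- FALSE
  mode <- "reporting"
  if (preset == "full_knowledge") {
    clamped <- TRUE
    slots <- integer(0)
  } else if (preset == "basic_only") {
    clamped <- TRUE
    flatten <- c(1L, 2L)
    slots <- integer(0)
  } else if (preset == "slots") {
    if (length(slots) == 0) stop("slots preset requires slot indices")
    naive_cols <- slots
    learn_a <- TRUE
    mode <- "learning"
  } else if (preset == "granularity") {
    # all columns are relabelable, but naivety is per-row: with prior basic
    # knowledge the wings/gills rows stay precise
    slots <- 1:8
    if (prior_basic) flatten <- c(1L, 2L) else flatten <- 1:3
    learn_a <- TRUE
    mode <- "learning"
  } else if (preset == "reduction") {
    slots <- if (precise_A) integer(0) else 1:8
    flatten <- if (precise_A) integer(0) else 1:3
    clamped <- precise_A
    learn_a <- !precise_A
    learn_d <- TRUE
    mode <- "learning"
  } else if (preset == "generalization") {
    clamped <- TRUE
    slots <- match(variant, .animals)
    naive_cols <- slots
  }
  structure(list(
    preset = preset, slots = as.integer(slots), prior_basic = prior_basic,
    precise_A = precise_A, variant = variant, flatten = flatten,
    naive_cols = as.integer(naive_cols),
    clamped = clamped, learn_a = learn_a, learn_d = learn_d, mode = mode,
    known_scale = known_scale, known_eps = known_eps,
    naive_base = naive_base, naive_jitter = naive_jitter,
    preferences = preferences, d0 = d0, eta = eta, beta0 = beta0
  ), class = "task_spec")
}

# outcome indices of each animal's true features: 3 x 8 integer matrix
feature_index_matrix <- function() {
  fm <- animal_features()
  out <- t(as.matrix(fm[, c("size_idx", "color_idx", "species_idx")]))
  storage.mode(out) <- "integer"
  out
}

# feedback level generated for (animal/concept, report state) in the 8-animal
# task: null at start; correct_specific iff the specific report names the
# animal; correct_basic iff a basic report names its class; else incorrect.
feedback_matrix <- function() {
  fm <- animal_features()
  out <- matrix(0L, 8, 11)
  for (s1 in 1:8) {
    for (r in 1:11) {
      out[s1, r] <- if (r == 1) 1L
      else if (r <= 9) (if (r - 1 == s1) 3L else 4L)
      else if (r == 10) (if (fm$class[s1] == "bird") 2L else 4L)
      else (if (fm$class[s1] == "fish") 2L else 4L)
    }
  }
  out
}

# distance-question variant: could the animal be seen from a distance?
# yes is correct only for large, colorful animals.
distance_feedback_matrix <- function() {
  fm <- animal_features()
  yes <- fm$size == "large" & fm$color == "colorful"
  out <- matrix(0L, 8, 3)
  for (s1 in 1:8) {
    out[s1, ] <- c(1L,
                   if (yes[s1]) 2L else 3L,  # report yes
                   if (yes[s1]) 3L else 2L)  # report no
  }
  out
}

# report-factor transition array: action 1 stays; action k moves the start
# state to report level k; report states are absorbing within a trial.
report_transitions <- function(n_report) {
  B <- array(0, c(n_report, n_report, n_report))
  for (u in seq_len(n_report)) {
    for (s in seq_len(n_report)) {
      to <- if (u == 1 || s != 1) s else u
      B[to, s, u] <- 1
    }
  }
  B
}

#' Build the generative process for the animal task
#'
#' The true data-generating side: a fully precise feature map, the feedback
#' rule, and the report-factor dynamics. Observations are deterministic given
#' the true animal and the agent's report state.
#'
#' @param task a `task_spec` (only the preset's report semantics matter).
#' @return A `generative_process` list.
#' @export
build_generative_process <- function(task = concept_task("full_knowledge")) {
  fm <- animal_features()
  fidx <- feature_index_matrix()
  one_hot <- lapply(1:3, function(m) {
    M <- matrix(0, 2, 8)
    M[cbind(fidx[m, ], 1:8)] <- 1
    M
  })
  distance <- identical(task$preset, "generalization")
  n_report <- if (distance) 3L else 11L
  structure(list(
    type = if (distance) "distance" else "animals",
    feature_obs = fidx,
    features_one_hot = one_hot,
    feedback = if (distance) distance_feedback_matrix() else feedback_matrix(),
    B_report = report_transitions(n_report),
    n_report = n_report,
    class = fm$class,
    labels = list(animals = .animals,
                  reports = if (distance) c("start", "yes", "no")
                            else c("start", .animals, "bird", "fish"))
  ), class = "generative_process")
}

# observation vector (one outcome index per modality) emitted by the process
observe <- function(gp, animal, report_state) {
  unname(c(gp$feature_obs[, animal], gp$feedback[animal, report_state]))
}

classify_report <- function(gp, report_state) {
  if (gp$type == "distance") {
    if (report_state == 1) return(list(type = "none"))
    return(list(type = "answer", answer = c("yes", "no")[report_state - 1]))
  }
  if (report_state == 1) return(list(type = "none"))
  if (report_state <= 9) return(list(type = "specific", index = report_state - 1L))
  list(type = "basic", class = if (report_state == 10) "bird" else "fish")
}

#' Build the agent's generative model for a task preset
#'
#' Assembles the full `genmdp`: three binary feature modalities and a feedback
#' modality over an 8-concept factor crossed with the report factor. Feature
#' mappings depend only on the concept factor (arrays are constant along the
#' report axis). Known concept columns carry concentration counts of
#' `known_scale` concentrated on the true features; naive slots start as flat
#' columns with slight Gaussian jitter. The feedback mapping — the task's
#' report semantics — is always precise. The concept factor's transitions are
#' the identity (the animal does not change within a trial); the report factor
#' is controlled. Preferences are nonzero only on the feedback modality.
#'
#' The model carries two policy sets: `learning` (stay only, so no reports can
#' be given and no feedback observed) and `reporting` (stay or move to any
#' report level).
#'
#' @param task a `task_spec` from [concept_task()].
#' @return A validated `genmdp` with the task spec attached.
#' @export
build_agent_model <- function(task = concept_task("full_knowledge")) {
  gp <- build_generative_process(task)
  fidx <- feature_index_matrix()
  n_report <- gp$n_report
  distance <- gp$type == "distance"
  known_p <- function(o_true, no) {
    p <- rep(task$known_eps / no, no)
    p[o_true] <- p[o_true] + (1 - task$known_eps)
    p
  }
  feature_arrays <- lapply(1:3, function(m) {
    arr <- array(0, c(2, 8, n_report))
    for (c1 in 1:8) {
      col <- if (task$clamped) {
        if (m %in% task$flatten) c(0.5, 0.5)
        else if (c1 %in% task$naive_cols)
          norm1(naive_column(2, task$naive_base, task$naive_jitter))
        else { p <- c(0, 0); p[fidx[m, c1]] <- 1; p }
      } else {
        if (m %in% task$flatten || c1 %in% task$naive_cols)
          naive_column(2, task$naive_base, task$naive_jitter)
        else task$known_scale * known_p(fidx[m, c1], 2)
      }
      arr[, c1, ] <- col
    }
    arr
  })
  fb <- gp$feedback
  n_fb <- if (distance) 3L else 4L
  fb_arr <- array(0, c(n_fb, 8, n_report))
  for (c1 in 1:8) {
    for (r in seq_len(n_report)) {
      fb_arr[, c1, r] <- if (task$clamped) {
        p <- rep(0, n_fb); p[fb[c1, r]] <- 1; p
      } else {
        task$known_scale * known_p(fb[c1, r], n_fb)
      }
    }
  }
  arrays <- c(feature_arrays, list(fb_arr))
  if (task$clamped) {
    A <- arrays
    a <- NULL
  } else {
    a <- arrays
    A <- lapply(a, normalize_counts)
  }
  B <- list(concept = array(diag(8), c(8, 8, 1)), report = gp$B_report)
  C_fb <- if (distance) {
    unname(task$preferences[c("null", "correct_specific", "incorrect")])
  } else {
    unname(task$preferences[c("null", "correct_basic", "correct_specific",
                              "incorrect")])
  }
  C <- list(rep(0, 2), rep(0, 2), rep(0, 2), C_fb)
  d0 <- rep(task$d0, 8)
  D <- list(concept = norm1(d0), report = c(1, rep(0, n_report - 1L)))
  d <- if (task$learn_d) list(d0, NULL) else NULL
  reporting <- cbind(rep(1L, n_report), seq_len(n_report))
  learning <- cbind(1L, 1L)
  model <- generative_model(
    A = A, B = B, C = C, D = D,
    policies = if (task$mode == "learning") learning else reporting,
    T = 2L, a = a, d = d, beta0 = task$beta0, eta = task$eta,
    learn_a = task$learn_a, learn_d = task$learn_d,
    labels = list(factors = list(.animals, gp$labels$reports),
                  modalities = list(.sizes, .colors, .species,
                                    if (distance) c("null", "correct", "incorrect")
                                    else .feedback_levels)),
    policy_sets = list(
      learning = array(learning, c(1, 1, 2)),
      reporting = array(reporting, c(n_report, 1, 2))),
    mode = task$mode)
  model$task <- task
  model$a_init <- a
  model$d_init <- d
  bad <- validate_model(model)
  if (length(bad) > 0) stop("invalid task model: ", paste(bad, collapse = "; "))
  model
}

#' Build the distance-question generalization variant
#'
#' Replaces the report factor by \{start, yes, no\} and the feedback semantics
#' by the distance rule (yes is correct only for large, colorful animals),
#' keeping the three feature modalities and the full 8-level concept factor.
#' One concept column is naive (the withheld animal) and learning is disabled,
#' so a correct answer on first exposure is one-shot generalization.
#'
#' @param variant which animal is withheld: `"parrot"` (true answer yes) or
#'   `"minnow"` (true answer no).
#' @param ... further arguments passed to [concept_task()].
#' @return List with the agent `model` and matching generative process `gp`.
#' @export
build_generalization_task <- function(variant = c("parrot", "minnow"), ...) {
  task <- concept_task("generalization", variant = match.arg(variant), ...)
  list(model = build_agent_model(task), gp = build_generative_process(task))
}

#' Sample a stimulus stream
#'
#' Either uniform random draws over the given animals or balanced blocks
#' (every animal exactly `per_animal` times, in randomized order).
#'
#' @param animals candidate animal indices.
#' @param n number of uniform draws (`kind = "uniform"`).
#' @param per_animal exposures per animal (`kind = "balanced"`).
#' @param kind schedule type.
#' @param seed optional seed (local RNG; the caller's stream is untouched).
#' @return Integer vector of animal indices.
#' @export
sample_stimulus_stream <- function(animals = 1:8, n = NULL, per_animal = NULL,
                                   kind = c("uniform", "balanced"),
                                   seed = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    if (kind == "uniform") {
      if (is.null(n)) stop("uniform schedule requires n")
      sample(animals, n, replace = TRUE)
    } else {
      if (is.null(per_animal)) stop("balanced schedule requires per_animal")
      sample(rep(animals, each = per_animal))
    }
  })
}
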