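# Configuration parsing, result serialization, and delimited-text round
# trips for model arrays.

.config_defaults <- function() list(
  preset = "expansion",
  n_new = 1, known = 7, prior_basic = TRUE, n_true = 5, precise_A = FALSE,
  variant = "parrot",
  trials = 2000, exposures = 250, familiar_trials = 80, novel_trials = 20,
  repeats = 8, probes_per_animal = 20, checkpoints = NULL,
  known_scale = 200, naive_base = 1, naive_jitter = 0.1, eta = 1,
  seed = 1, out_dir = NULL, verbose = FALSE)

#' Parse a run configuration
#'
#' Reads an experiment configuration from a YAML file and/or a named list of
#' overrides, applies the documented defaults, and validates it. Unknown keys
#' are rejected by name; counts must be positive.
#'
#' @param file optional path to a YAML config file.
#' @param flags optional named list of overrides (applied after the file).
#' @return A validated `run_config` list with all defaults resolved.
#' @export
parse_config <- function(file = NULL, flags = list()) {
  cfg <- .config_defaults()
  given <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    given <- yaml::read_yaml(file)
    if (is.null(given)) given <- list()
  }
  given[names(flags)] <- flags
  unknown <- setdiff(names(given), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(given)] <- given
  presets <- c("expansion", "duplication", "granularity", "reduction",
               "generalization", "full_knowledge", "basic_only")
  if (!cfg$preset %in% presets)
    stop("invalid preset '", cfg$preset, "'; one of: ",
         paste(presets, collapse = ", "))
  for (k in c("trials", "exposures", "repeats", "probes_per_animal",
              "known_scale", "naive_base", "eta")) {
    if (cfg[[k]] <= 0) stop("config key '", k, "' must be positive")
  }
  structure(cfg, class = "run_config")
}

#' Run the experiment named by a configuration
#'
#' Dispatches a parsed [parse_config()] object to the matching experiment
#' function.
#'
#' @param cfg a `run_config`.
#' @return A `concept_experiment`.
#' @export
run_experiment <- function(cfg) {
  switch(cfg$preset,
    expansion = exp_expansion(n_new = cfg$n_new, trials = cfg$trials,
                              repeats = cfg$repeats, seed = cfg$seed,
                              probes_per_animal = cfg$probes_per_animal,
                              checkpoints = cfg$checkpoints),
    duplication = exp_duplication(known = cfg$known,
                                  familiar_trials = cfg$familiar_trials,
                                  novel_trials = cfg$novel_trials,
                                  seed = cfg$seed),
    granularity = exp_granularity(prior_basic = cfg$prior_basic,
                                  trials = cfg$trials, repeats = cfg$repeats,
                                  seed = cfg$seed,
                                  probes_per_animal = cfg$probes_per_animal,
                                  checkpoints = cfg$checkpoints),
    reduction = exp_reduction(n_true = cfg$n_true, exposures = cfg$exposures,
                              repeats = cfg$repeats,
                              precise_A = cfg$precise_A, seed = cfg$seed),
    generalization = exp_generalization(variant = cfg$variant,
                                        probes = cfg$probes_per_animal,
                                        seed = cfg$seed),
    stop("no experiment runner for preset '", cfg$preset, "'"))
}

#' Write experiment results to a directory
#'
#' Writes the per-repeat table, an aggregate summary, the resolved
#' configuration, the seed ledger and a short log as delimited text / YAML /
#' JSON, and returns a manifest of the files written. Re-running with the
#' same inputs produces byte-identical tables.
#'
#' @param result a `concept_experiment`.
#' @param dir output directory (created if needed).
#' @param config optional `run_config` to store alongside the results.
#' @return Data frame manifest (file name, bytes).
#' @export
write_results <- function(result, dir, config = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wr <- function(name, fn) {
    path <- file.path(dir, name)
    fn(path)
    files <<- c(files, path)
  }
  wr("per_repeat.tsv", function(p)
    utils::write.table(result$per_repeat, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  wr("aggregate.json", function(p) {
    agg <- result$aggregate
    agg$name <- result$name
    jsonlite::write_json(agg, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  wr("config.yaml", function(p)
    yaml::write_yaml(if (is.null(config)) result$params else
      unclass(config), p))
  wr("seeds.txt", function(p)
    writeLines(as.character(result$seeds), p))
  wr("run.log", function(p)
    writeLines(c(paste("experiment:", result$name),
                 paste("repeats:", nrow(result$per_repeat))), p))
  data.frame(file = basename(files), bytes = file.size(files))
}

#' Serialize model arrays to delimited text
#'
#' Writes each likelihood / concentration array (one CSV per modality,
#' column-major over the joint hidden state, header row naming levels), the
#' transition arrays, preferences, priors and counts of a `genmdp` to a
#' directory, with a manifest for round-tripping via [read_model_arrays()].
#'
#' @param model a `genmdp`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_model_arrays <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- function(x) {
    d <- dim(x)
    df <- data.frame(matrix(x, nrow = d[1]))
    names(df) <- paste0("state_", seq_len(ncol(df)))
    df
  }
  meta <- list(factor_sizes = model$factor_sizes,
               modality_sizes = model$modality_sizes,
               T = model$T, beta0 = model$beta0, eta = model$eta,
               learn_a = model$learn_a, learn_d = model$learn_d,
               mode = model$mode,
               has_a = !is.null(model$a), has_d = !is.null(model$d),
               d_factors = if (!is.null(model$d))
                 which(!vapply(model$d, is.null, logical(1))) else integer(0))
  yaml::write_yaml(meta, file.path(dir, "model.yaml"))
  for (m in seq_len(model$n_modalities)) {
    utils::write.csv(flat(model$A[[m]]),
                     file.path(dir, sprintf("A_modality%d.csv", m)),
                     row.names = FALSE)
    if (!is.null(model$a))
      utils::write.csv(flat(model$a[[m]]),
                       file.path(dir, sprintf("a_modality%d.csv", m)),
                       row.names = FALSE)
    utils::write.csv(data.frame(C = model$C[[m]]),
                     file.path(dir, sprintf("C_modality%d.csv", m)),
                     row.names = FALSE)
  }
  for (f in seq_len(model$n_factors)) {
    utils::write.csv(flat(model$B[[f]]),
                     file.path(dir, sprintf("B_factor%d.csv", f)),
                     row.names = FALSE)
    utils::write.csv(data.frame(D = model$D[[f]],
                                d = if (!is.null(model$d) &&
                                        !is.null(model$d[[f]]))
                                  model$d[[f]] else NA_real_),
                     file.path(dir, sprintf("D_factor%d.csv", f)),
                     row.names = FALSE)
  }
  pol <- model$policies
  utils::write.csv(data.frame(matrix(pol, nrow = dim(pol)[1])),
                   file.path(dir, "policies.csv"), row.names = FALSE)
  invisible(file.path(dir, "model.yaml"))
}

#' Read model arrays back from delimited text
#'
#' Inverse of [write_model_arrays()]. Task metadata (policy sets, the task
#' spec) is not serialized; the numerical model round-trips exactly.
#'
#' @param dir directory written by [write_model_arrays()].
#' @return A `genmdp`.
#' @export
read_model_arrays <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  fs <- unlist(meta$factor_sizes)
  ms <- unlist(meta$modality_sizes)
  unflat <- function(df, d) array(as.matrix(df), d)
  A <- a <- C <- vector("list", length(ms))
  for (m in seq_along(ms)) {
    A[[m]] <- unflat(utils::read.csv(file.path(
      dir, sprintf("A_modality%d.csv", m))), c(ms[m], fs))
    if (isTRUE(meta$has_a))
      a[[m]] <- unflat(utils::read.csv(file.path(
        dir, sprintf("a_modality%d.csv", m))), c(ms[m], fs))
    C[[m]] <- utils::read.csv(file.path(
      dir, sprintf("C_modality%d.csv", m)))$C
  }
  B <- D <- d <- vector("list", length(fs))
  for (f in seq_along(fs)) {
    bdf <- utils::read.csv(file.path(dir, sprintf("B_factor%d.csv", f)))
    B[[f]] <- array(as.matrix(bdf), c(fs[f], fs[f], ncol(bdf) / fs[f]))
    ddf <- utils::read.csv(file.path(dir, sprintf("D_factor%d.csv", f)))
    D[[f]] <- ddf$D
    if (f %in% unlist(meta$d_factors)) d[[f]] <- ddf$d
  }
  if (!isTRUE(meta$has_d)) d <- NULL
  if (!isTRUE(meta$has_a)) a <- NULL
  pol <- as.matrix(utils::read.csv(file.path(dir, "policies.csv")))
  np <- nrow(pol)
  policies <- array(as.vector(pol), c(np, meta$T - 1, length(fs)))
  generative_model(A = A, B = B, C = C, D = D, policies = policies,
                   T = meta$T, a = a, d = d, beta0 = meta$beta0,
                   eta = meta$eta, learn_a = isTRUE(meta$learn_a),
                   learn_d = isTRUE(meta$learn_d), mode = meta$mode)
}
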