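# Batch pipeline: a validated chain of stages operating on shared state
# slots (posteriors, labels, metadata, model, report, split). The chain is
# type-checked before any stage runs, so a mis-ordered config fails fast.

STAGE_IO <- list(
  "simulate"      = list(needs = character(),
                         gives = c("posteriors", "labels", "metadata",
                                   "model", "train_prior")),
  "adjust-priors" = list(needs = "posteriors", gives = "posteriors"),
  "fuse-metadata" = list(needs = c("posteriors", "metadata"),
                         gives = "posteriors"),
  "pool"          = list(needs = character(), gives = "posteriors"),
  "evaluate"      = list(needs = c("posteriors", "labels"),
                         gives = "report"),
  "split"         = list(needs = "labels", gives = "split"))

#' Run a batch pipeline from a configuration
#'
#' Executes a chain of stages (`simulate`, `adjust-priors`,
#' `fuse-metadata`, `pool`, `evaluate`, `split`) in order. Each stage reads
#' its inputs from the accumulated pipeline state or from files named in
#' its parameters, and may write declared outputs. The stage chain is
#' validated before any work: a stage whose required inputs are neither in
#' the state accumulated so far nor supplied as file paths is a
#' configuration error. Identical config + seed gives identical outputs.
#'
#' @param config list (or path to a JSON file) with fields `seed` (integer)
#'   and `stages`: a list of `list(stage = "<name>", ...params)`. Common
#'   params: `out` (output file); see the CLI help for per-stage options.
#' @return list with `status` (0 on success), `log` (data.frame of stage,
#'   rows, seconds) and the final `state`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # pre-flight chain validation
  have <- character()
  for (st in stages) {
    name <- st$stage
    if (is.null(name) || !name %in% names(STAGE_IO))
      stop("configuration error: unknown stage '", name, "'")
    io <- STAGE_IO[[name]]
    file_inputs <- c(if (!is.null(st$posteriors)) "posteriors",
                     if (!is.null(st$metadata)) "metadata",
                     if (!is.null(st$labels) || !is.null(st$truth)) "labels",
                     if (!is.null(st$inputs)) "posteriors")
    missing <- setdiff(io$needs, c(have, file_inputs))
    if (length(missing))
      stop("configuration error: stage '", name, "' needs ",
           paste(missing, collapse = ", "), " but the chain provides only: ",
           if (length(have)) paste(have, collapse = ", ") else "(nothing)")
    have <- union(have, io$gives)
  }

  state <- list()
  log <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    state <- exec_stage(st, state, seed)
    rows <- if (!is.null(state$posteriors)) nrow(state$posteriors)
            else if (!is.null(state$labels)) length(state$labels)
            else NA_integer_
    log[[length(log) + 1L]] <- data.frame(
      stage = st$stage, rows = rows,
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  list(status = 0L,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(stage = character(), rows = integer(),
                             seconds = numeric()),
       state = state)
}

param <- function(st, name, default = NULL) {
  if (is.null(st[[name]])) default else st[[name]]
}

exec_stage <- function(st, state, seed) {
  switch(st$stage,
    "simulate" = {
      model <- build_model(
        K = param(st, "K", 50L), V = param(st, "V", 200L),
        metadata_cardinalities = c(
          habitat = param(st, "habitat_levels", 10L),
          substrate = param(st, "substrate_levels", 8L)),
        train_exponent = param(st, "train_exponent", 1.2),
        test_exponent = param(st, "test_exponent", 1.2),
        seed = seed)
      ds <- sample_dataset(model, N = param(st, "N", 10000L),
                           which_prior = param(st, "which_prior", "train"),
                           seed = seed + 1L,
                           temperature = param(st, "temperature", 1))
      state$model <- model
      state$posteriors <- ds$posteriors
      state$labels <- ds$labels
      state$metadata <- ds$metadata
      state$train_prior <- model$train_prior
      if (!is.null(st$out_dir)) {
        dir.create(st$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_posteriors(ds$posteriors,
                         file.path(st$out_dir, "posteriors.csv"))
        write_labels(ds$labels, file.path(st$out_dir, "labels.csv"),
                     rownames(ds$posteriors))
        write_metadata(ds$metadata, file.path(st$out_dir, "metadata.csv"))
        write_prior(model$train_prior,
                    file.path(st$out_dir, "train_prior.json"))
      }
      state
    },
    "adjust-priors" = {
      post <- if (!is.null(st$posteriors)) read_posteriors(st$posteriors)
              else state$posteriors
      space <- label_space(colnames(post))
      p <- if (!is.null(st$train_prior) && is.character(st$train_prior))
        read_prior(st$train_prior, space) else state$train_prior
      if (is.null(p)) stop("adjust-priors: no train prior available")
      out <- if (isTRUE(param(st, "uniform", FALSE)))
        adjust_to_uniform(post, p, space)
      else {
        pe <- read_prior(st$target_prior, space)
        adjust_posteriors(post, p, pe, space)
      }
      if (!is.null(st$out)) write_posteriors(out, st$out)
      state$posteriors <- out
      state
    },
    "fuse-metadata" = {
      post <- if (!is.null(st$posteriors)) read_posteriors(st$posteriors)
              else state$posteriors
      space <- label_space(colnames(post))
      md <- if (!is.null(st$metadata) && is.character(st$metadata))
        read_metadata(st$metadata) else state$metadata
      fm <- if (!is.null(st$model_file)) read_frequency_model(st$model_file)
      else {
        labels <- if (!is.null(st$train_labels))
          read_labels(st$train_labels)$species else state$labels
        fit_frequency_model(labels, md, space,
                            alpha = param(st, "alpha", 0))
      }
      types <- param(st, "types", METADATA_TYPES)
      out <- fuse(post, md, fm, types = unlist(types))
      if (!is.null(st$out)) write_posteriors(out, st$out)
      state$posteriors <- out
      state
    },
    "pool" = {
      stack <- if (!is.null(st$inputs))
        lapply(unlist(st$inputs), read_posteriors)
      else stop("pool: no inputs given")
      method <- match.arg(param(st, "method", "sum"), c("sum", "mode"))
      if (method == "sum") {
        out <- pool_sum(stack)
        if (!is.null(st$out)) write_posteriors(out, st$out)
        state$posteriors <- out
      } else {
        res <- pool_mode(stack)
        if (!is.null(st$out))
          write_labels(res$prediction, st$out, rownames(stack[[1L]]))
        state$predictions <- res
      }
      state
    },
    "evaluate" = {
      post <- if (!is.null(st$posteriors)) read_posteriors(st$posteriors)
              else state$posteriors
      truth <- if (!is.null(st$truth)) read_labels(st$truth)$species
               else state$labels
      space <- label_space(colnames(post))
      rep <- eval_report(post, truth, space,
                         ks = unlist(param(st, "ks", c(1, 3, 5))))
      if (!is.null(st$out)) write_eval_report(rep, st$out)
      state$report <- rep
      state
    },
    "split" = {
      truth <- if (!is.null(st$truth)) read_labels(st$truth)$species
               else state$labels
      sp <- species_split(truth, param(st, "fraction", 0.9), seed)
      if (!is.null(st$out_train))
        write_labels(truth[sp$train], st$out_train,
                     paste0("obs", sp$train))
      if (!is.null(st$out_test))
        write_labels(truth[sp$test], st$out_test, paste0("obs", sp$test))
      state$split <- sp
      state
    })
}
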