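#' Long-tailed power-law class prior
#'
#' Citizen-science species records are highly unbalanced: a few common
#' species dominate and most are rare. This prior emulates that shape with
#' a Zipf-like power law, p(rank r) proportional to r^(-exponent).
#'
#' @param space a [label_space()]; ranks follow its species order.
#' @param exponent positive power-law exponent; larger = heavier head.
#'   Values near 0 approach the uniform prior.
#' @return a [prior_vector()], monotone non-increasing in rank.
#' @export
longtail_priors <- function(space, exponent = 1) {
  space <- as_label_space(space)
  if (!is.numeric(exponent) || exponent <= 0)
    stop("exponent must be positive")
  w <- seq_len(space$K)^(-exponent)
  prior_vector(w / sum(w), space)
}

#' Build a discrete generative model of a citizen-science survey
#'
#' The simulator replaces images with a discrete "visual token": each
#' species emits one of V tokens from its own categorical distribution, and
#' each metadata field (habitat, substrate, month) from a separate
#' per-species categorical distribution. Visual token and metadata are
#' therefore conditionally independent given the species *by construction*
#' — exactly the assumption under which metadata fusion is exact — and all
#' posteriors are enumerable in closed form, giving exact oracles for the
#' prior-shift and fusion identities.
#'
#' Per-species channel distributions are drawn from symmetric Dirichlet
#' distributions: a small concentration yields peaked, informative channels
#' (species are easy to tell apart from that signal); a large concentration
#' yields near-uniform, uninformative ones. Train and test priors are
#' power-law long tails with their own exponents, so setting
#' `test_exponent != train_exponent` creates genuine label shift.
#'
#' @param K number of species (>= 2).
#' @param V number of visual tokens (>= 2).
#' @param metadata_cardinalities named integer vector: number of categories
#'   for habitat and substrate (month is fixed at 12).
#' @param concentration named list/vector of Dirichlet concentrations for
#'   "visual", "habitat", "substrate", "month".
#' @param train_exponent,test_exponent power-law exponents of the training
#'   and deployment priors.
#' @param seed integer seed; the model is reproducible from it.
#' @return object of class `generative_model` with fields `space`,
#'   `train_prior`, `test_prior`, `visual` (K x V), and `metadata`
#'   (list of K x C matrices).
#' @export
build_model <- function(K, V,
                        metadata_cardinalities = c(habitat = 10L,
                                                   substrate = 8L),
                        concentration = c(visual = 0.1, habitat = 0.5,
                                          substrate = 0.5, month = 0.5),
                        train_exponent = 1.2,
                        test_exponent = train_exponent,
                        seed = 1L) {
  if (K < 2L || V < 2L) stop("K and V must both be at least 2")
  cards <- c(habitat = as.integer(metadata_cardinalities[["habitat"]]),
             substrate = as.integer(metadata_cardinalities[["substrate"]]),
             month = 12L)
  if (any(cards < 2L)) stop("metadata cardinalities must be at least 2")
  concentration <- as.list(concentration)
  if (any(unlist(concentration) <= 0))
    stop("concentrations must be positive")

  space <- label_space(sprintf("sp%03d", seq_len(K)))
  cat_names <- list(habitat = sprintf("h%02d", seq_len(cards[["habitat"]])),
                    substrate = sprintf("s%02d", seq_len(cards[["substrate"]])),
                    month = as.character(1:12))
  with_seed(seed, {
    visual <- rdirichlet_rows(K, V, concentration[["visual"]])
    dimnames(visual) <- list(space$species, sprintf("v%03d", seq_len(V)))
    metadata <- lapply(METADATA_TYPES, function(type) {
      m <- rdirichlet_rows(K, cards[[type]], concentration[[type]])
      dimnames(m) <- list(space$species, cat_names[[type]])
      m
    })
    names(metadata) <- METADATA_TYPES
    structure(list(space = space,
                   train_prior = longtail_priors(space, train_exponent),
                   test_prior = longtail_priors(space, test_exponent),
                   visual = visual,
                   metadata = metadata,
                   seed = as.integer(seed)),
              class = "generative_model")
  })
}

# n rows from a symmetric Dirichlet(alpha) over d categories
rdirichlet_rows <- function(n, d, alpha) {
  g <- matrix(stats::rgamma(n * d, shape = alpha), n, d)
  # guard against an all-zero row at extreme small alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1
  g / rowSums(g)
}

#' Hand-build a generative model from explicit tables
#'
#' Constructor for tiny, fully specified models used in exact tests: all
#' channel distributions and priors are given directly instead of sampled.
#'
#' @param visual K x V matrix, rows = per-species token distributions.
#' @param metadata named list of K x C matrices (any subset of habitat,
#'   substrate, month); may be empty.
#' @param train_prior,test_prior length-K priors (default uniform).
#' @param species optional species ids (default sp001..).
#' @return a `generative_model`.
#' @export
manual_model <- function(visual, metadata = list(), train_prior = NULL,
                         test_prior = NULL, species = NULL) {
  visual <- as.matrix(visual)
  K <- nrow(visual)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(K))
  space <- label_space(species)
  rownames(visual) <- space$species
  if (is.null(colnames(visual)))
    colnames(visual) <- sprintf("v%03d", seq_len(ncol(visual)))
  stopifnot(all(abs(rowSums(visual) - 1) < 1e-9))
  metadata <- lapply(metadata, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == K, all(abs(rowSums(m) - 1) < 1e-9))
    rownames(m) <- space$species
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    m
  })
  tp <- if (is.null(train_prior)) uniform_prior(space)
        else prior_vector(train_prior, space)
  ep <- if (is.null(test_prior)) tp else prior_vector(test_prior, space)
  structure(list(space = space, train_prior = tp, test_prior = ep,
                 visual = visual, metadata = metadata, seed = NA_integer_),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat("generative_model:", x$space$K, "species,", ncol(x$visual),
      "visual tokens; metadata channels:",
      paste(sprintf("%s (%d)", names(x$metadata),
                    vapply(x$metadata, ncol, integer(1))), collapse = ", "),
      "\n")
  invisible(x)
}

model_prior <- function(model, prior = c("train", "test")) {
  prior <- match.arg(prior)
  if (prior == "train") model$train_prior else model$test_prior
}

#' Exact species posterior given a visual token
#'
#' Brute-force Bayes over the discrete model:
#' p(s | v) proportional to prior(s) * p(v | s), normalized by direct
#' enumeration over species. This is the independent oracle for the
#' prior-shift identity: the test-prior version of this posterior must
#' equal [adjust_posteriors()] applied to the train-prior version.
#'
#' @param model a [build_model()] or [manual_model()].
#' @param token visual token index (1..V) or column name.
#' @param prior "train" or "test".
#' @return named length-K probability vector.
#' @export
exact_posterior_visual <- function(model, token, prior = c("train", "test")) {
  stopifnot(inherits(model, "generative_model"))
  pr <- model_prior(model, prior)
  lik <- model$visual[, token]
  w <- as.numeric(pr) * lik
  if (sum(w) == 0)
    stop("degenerate token: no species emits token ", token,
         " under this prior")
  stats::setNames(w / sum(w), model$space$species)
}

#' Exact species posterior given a visual token and metadata values
#'
#' Brute-force Bayes including the metadata channels:
#' p(s | v, d1..dm) proportional to prior(s) * p(v | s) * prod_j p(dj | s).
#' The oracle for the fusion identity: [fuse()] applied to the exact visual
#' posterior, with frequency tables set to the model's implied p(s | d),
#' must reproduce this exactly.
#'
#' @inheritParams exact_posterior_visual
#' @param metadata_values named list/vector of metadata values (subset of
#'   habitat, substrate, month), as category names or indices.
#' @return named length-K probability vector.
#' @export
exact_posterior_full <- function(model, token, metadata_values,
                                 prior = c("train", "test")) {
  stopifnot(inherits(model, "generative_model"))
  pr <- model_prior(model, prior)
  w <- as.numeric(pr) * model$visual[, token]
  for (type in names(metadata_values)) {
    if (!type %in% names(model$metadata))
      stop("model has no metadata channel: ", type)
    w <- w * model$metadata[[type]][, metadata_values[[type]]]
  }
  if (sum(w) == 0)
    stop("degenerate token/metadata combination: zero total mass")
  stats::setNames(w / sum(w), model$space$species)
}

#' Implied species-given-metadata conditional of a generative model
#'
#' The population conditional p(s | d) that [fit_frequency_model()] should
#' recover from a large sample: by Bayes,
#' p(s | d) proportional to prior(s) * p(d | s).
#'
#' @inheritParams exact_posterior_visual
#' @param type metadata type.
#' @param value category name or index.
#' @return named length-K probability vector.
#' @export
implied_species_given_metadata <- function(model, type, value,
                                           prior = c("train", "test")) {
  stopifnot(inherits(model, "generative_model"))
  pr <- model_prior(model, prior)
  w <- as.numeric(pr) * model$metadata[[type]][, value]
  stats::setNames(w / sum(w), model$space$species)
}

#' Frequency model holding a generative model's true conditionals
#'
#' Builds a [fit_frequency_model()]-compatible object whose tables are the
#' model's exact implied p(s | d) under the training prior — the
#' "infinite-sample" frequency model used in oracle-equivalence tests.
#'
#' @param model a `generative_model`.
#' @return a `frequency_model`.
#' @export
true_frequency_model <- function(model) {
  stopifnot(inherits(model, "generative_model"))
  space <- model$space
  tables <- lapply(METADATA_TYPES, function(type) {
    ch <- model$metadata[[type]]
    if (is.null(ch)) return(NULL)
    tab <- t(vapply(colnames(ch), function(v)
      implied_species_given_metadata(model, type, v, "train"),
      numeric(space$K)))
    dimnames(tab) <- list(colnames(ch), space$species)
    tab
  })
  names(tables) <- METADATA_TYPES
  structure(list(tables = tables,
                 alpha = resolve_alpha(0),
                 train_prior = model$train_prior,
                 joint = NULL, min_joint_count = 0L,
                 space = space),
            class = "frequency_model")
}

#' Sample a synthetic citizen-science dataset
#'
#' Draws N observations from the model: species from the chosen prior,
#' visual token and metadata fields from the species' channels. The
#' simulated classifier output for each observation is the *exact
#' training-distribution posterior* given its token — i.e. the classifier
#' is Bayes-optimal under the training distribution, the premise of the
#' prior-shift correction. An optional temperature power-transforms each
#' posterior row (row^(1/temperature), renormalized) to emulate over-
#' (temperature < 1) or under-confident (> 1) classifiers; the default 1
#' keeps the classifier Bayes-exact so formula tests can assert equalities.
#'
#' @param model a `generative_model`.
#' @param N number of observations (>= 1).
#' @param which_prior "train" or "test": distribution the sample is drawn
#'   from (the classifier posterior always uses the train prior).
#' @param seed integer seed.
#' @param temperature positive posterior-degradation temperature.
#' @return object of class `synthetic_dataset`: list with `labels`,
#'   `visual_tokens`, `metadata` ([metadata_table()]), `posteriors`
#'   ([posterior_matrix()]), `model`, `seed`.
#' @export
sample_dataset <- function(model, N, which_prior = c("train", "test"),
                           seed = 1L, temperature = 1) {
  stopifnot(inherits(model, "generative_model"), N >= 1)
  which_prior <- match.arg(which_prior)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive")
  space <- model$space
  pr <- model_prior(model, which_prior)

  with_seed(seed, {
    sp_idx <- sample.int(space$K, N, replace = TRUE, prob = pr)
    tokens <- vapply(sp_idx, function(s)
      sample.int(ncol(model$visual), 1L, prob = model$visual[s, ]),
      integer(1))
    meta_draw <- lapply(METADATA_TYPES, function(type) {
      ch <- model$metadata[[type]]
      if (is.null(ch)) return(rep(NA_character_, N))
      colnames(ch)[vapply(sp_idx, function(s)
        sample.int(ncol(ch), 1L, prob = ch[s, ]), integer(1))]
    })
    names(meta_draw) <- METADATA_TYPES

    # posterior lookup table: one exact train-prior posterior per token
    post_by_token <- vapply(seq_len(ncol(model$visual)), function(v)
      exact_posterior_visual(model, v, "train"), numeric(space$K))
    post <- t(post_by_token)[tokens, , drop = FALSE]
    if (temperature != 1) {
      post <- post^(1 / temperature)
      post <- post / rowSums(post)
    }
    obs_ids <- sprintf("obs%06d", seq_len(N))
    structure(list(
      labels = space$species[sp_idx],
      visual_tokens = colnames(model$visual)[tokens],
      metadata = metadata_table(obs_ids,
                                habitat = meta_draw$habitat,
                                substrate = meta_draw$substrate,
                                month = meta_draw$month),
      posteriors = posterior_matrix(post, space, observation_ids = obs_ids),
      model = model,
      which_prior = which_prior,
      temperature = temperature,
      seed = as.integer(seed)),
      class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$labels), "observations,",
      x$model$space$K, "species (", x$which_prior, "prior, temperature",
      x$temperature, ")\n")
  invisible(x)
}
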