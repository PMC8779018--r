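#' fungifuse: posterior adjustment, metadata fusion and evaluation for
#' long-tailed species recognition
#'
#' Tools for the probability machinery that sits downstream of an image
#' classifier in a citizen-science species-recognition pipeline: class-prior
#' (label-shift) correction of classifier posteriors, Bayesian fusion of
#' posteriors with categorical observation metadata (habitat, substrate,
#' month), test-time-augmentation crop geometry with sum/mode pooling,
#' per-species stratified splitting, and evaluation metrics. A discrete
#' generative simulator with exact Bayes oracles verifies the identities.
#'
#' @keywords internal
"_PACKAGE"

# Tolerances used at module boundaries. Row sums of posterior matrices may
# drift by floating-point accumulation; drift below ROW_TOL is silently
# renormalized, larger drift is treated as a bug in the producing code.
ROW_TOL <- 1e-6
PRIOR_TOL <- 1e-9

METADATA_TYPES <- c("habitat", "substrate", "month")

#' Define an ordered species label space
#'
#' All posterior matrices, prior vectors and frequency tables in a run are
#' aligned against one `label_space`: column `j` of every matrix refers to
#' `species[j]`. Fixing the order once makes silent column misalignment
#' detectable at every module boundary.
#'
#' @param species character vector of unique, non-empty species identifiers.
#' @return An object of class `label_space` with fields `species` and `K`.
#' @examples
#' sp <- label_space(c("Amanita muscaria", "Boletus edulis"))
#' sp$K
#' @export
label_space <- function(species) {
  species <- as.character(species)
  if (length(species) < 2L)
    stop("label space needs at least 2 species, got ", length(species))
  if (anyNA(species) || any(!nzchar(species)))
    stop("species identifiers must be non-empty and non-missing")
  if (anyDuplicated(species))
    stop("duplicate species identifiers: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  structure(list(species = species, K = length(species)),
            class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  cat("label_space with", x$K, "species:",
      paste(utils::head(x$species, 3L), collapse = ", "),
      if (x$K > 3L) "..." else "", "\n")
  invisible(x)
}

as_label_space <- function(space) {
  if (inherits(space, "label_space")) return(space)
  label_space(space)
}

#' Construct a class-prior vector
#'
#' A categorical distribution over the species list: the training prior
#' p(s) or a deployment (target) prior. Entries must be non-negative and
#' sum to 1 within 1e-9; the stored vector is renormalized to sum exactly 1.
#'
#' @param values numeric vector of length K, optionally named by species.
#' @param space a [label_space()]; if `values` is named, names must match.
#' @return named numeric vector of class `prior_vector`.
#' @export
prior_vector <- function(values, space) {
  space <- as_label_space(space)
  values <- as.numeric(values)
  if (length(values) != space$K)
    stop("prior has length ", length(values), ", label space has K = ", space$K)
  if (anyNA(values) || any(values < 0))
    stop("prior entries must be non-negative and non-missing")
  s <- sum(values)
  if (abs(s - 1) > PRIOR_TOL)
    stop(sprintf("prior sums to %.12g, outside tolerance %g of 1", s, PRIOR_TOL))
  structure(values / s, names = space$species, class = "prior_vector")
}

#' Uniform prior over a label space
#' @param space a [label_space()].
#' @return a `prior_vector` with every entry 1/K.
#' @export
uniform_prior <- function(space) {
  space <- as_label_space(space)
  prior_vector(rep(1 / space$K, space$K), space)
}

#' Construct a posterior matrix
#'
#' An N x K matrix of per-observation species probabilities p(s | i):
#' rows are observations, columns follow the species order of `space`.
#' Entries must be non-negative; each row must sum to 1 within 1e-6 and is
#' silently renormalized to sum exactly 1 (larger drift errors).
#'
#' @param values numeric matrix (or object coercible to one), N x K.
#' @param space a [label_space()] giving the column order.
#' @param observation_ids optional character vector of row identifiers;
#'   defaults to existing rownames or `obs1..obsN`.
#' @return numeric matrix of class `posterior_matrix` with species colnames
#'   and observation rownames.
#' @export
posterior_matrix <- function(values, space, observation_ids = NULL) {
  space <- as_label_space(space)
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L) stop("posterior matrix needs at least one row")
  if (ncol(m) != space$K)
    stop("posterior matrix has ", ncol(m), " columns, label space has K = ",
         space$K)
  if (anyNA(m)) stop("posterior matrix contains missing values")
  if (any(m < 0)) stop("posterior matrix contains negative entries")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > ROW_TOL)
  if (length(bad))
    stop(sprintf("row %d sums to %.9g, outside tolerance %g of 1",
                 bad[1L], rs[bad[1L]], ROW_TOL))
  m <- m / rs
  if (is.null(observation_ids)) {
    observation_ids <- rownames(m)
    if (is.null(observation_ids))
      observation_ids <- paste0("obs", seq_len(nrow(m)))
  }
  if (length(observation_ids) != nrow(m))
    stop("observation_ids length does not match row count")
  if (anyDuplicated(observation_ids))
    stop("duplicate observation ids")
  dimnames(m) <- list(as.character(observation_ids), space$species)
  class(m) <- c("posterior_matrix", class(matrix()))
  m
}

#' @export
print.posterior_matrix <- function(x, ...) {
  cat("posterior_matrix:", nrow(x), "observations x", ncol(x), "species\n")
  print(utils::head(unclass(x), 4L), digits = 4)
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

# Accept a bare matrix where a posterior_matrix is expected; validates.
as_posterior_matrix <- function(post, space) {
  if (inherits(post, "posterior_matrix") &&
      identical(colnames(post), as_label_space(space)$species))
    return(post)
  posterior_matrix(post, space, observation_ids = rownames(post))
}

#' Normalize matrix rows to probability vectors
#'
#' Divides each row of a non-negative score matrix by its row sum, the
#' normalization implicit in every "proportional to" posterior formula.
#' Idempotent and invariant to positive rescaling of the input.
#'
#' @param scores non-negative numeric matrix with at least one strictly
#'   positive entry per row.
#' @param space optional [label_space()]; when given the result is a
#'   validated `posterior_matrix`.
#' @return matrix of the same shape with unit row sums.
#' @export
normalize_rows <- function(scores, space = NULL) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("scores contain missing values")
  if (any(m < 0)) stop("scores contain negative entries")
  rs <- rowSums(m)
  zero <- which(rs == 0)
  if (length(zero))
    stop("degenerate row ", zero[1L], ": all entries are zero")
  out <- m / rs
  if (!is.null(space)) out <- posterior_matrix(out, space, rownames(m))
  out
}

#' Validate a posterior matrix against a label space
#'
#' Report-based check used at pipeline boundaries: never throws, returns a
#' data frame of violations (empty iff all invariants hold).
#'
#' @param values numeric matrix to check.
#' @param space a [label_space()].
#' @param row_tol row-sum tolerance (default 1e-6).
#' @return data.frame with columns `violation`, `index`, `detail`.
#' @export
validate_posteriors <- function(values, space, row_tol = ROW_TOL) {
  space <- as_label_space(space)
  m <- as.matrix(values)
  viol <- list()
  add <- function(what, idx, detail)
    viol[[length(viol) + 1L]] <<- data.frame(
      violation = what, index = idx, detail = detail,
      stringsAsFactors = FALSE)
  if (ncol(m) != space$K)
    add("shape", NA_integer_,
        sprintf("%d columns, expected K = %d", ncol(m), space$K))
  neg <- which(apply(m, 1L, function(r) any(!is.na(r) & r < 0)))
  for (i in neg) add("negative", i, "row contains negative entries")
  if (ncol(m) == space$K) {
    rs <- rowSums(m)
    drift <- which(is.na(rs) | abs(rs - 1) > row_tol)
    for (i in drift)
      add("row_sum", i, sprintf("row sums to %.9g", rs[i]))
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(violation = character(), index = integer(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Construct a metadata table
#'
#' Per-observation categorical observation metadata: `habitat` and
#' `substrate` as free strings, `month` as an integer in 1..12. Missing
#' values are `NA` and are handled explicitly downstream (a missing field
#' simply contributes no fusion factor for that observation).
#'
#' @param observation_id character vector of observation identifiers.
#' @param habitat,substrate character vectors (or NULL for absent column).
#' @param month integer vector in 1..12 (or NULL).
#' @return data.frame of class `metadata_table`.
#' @export
metadata_table <- function(observation_id, habitat = NULL, substrate = NULL,
                           month = NULL) {
  n <- length(observation_id)
  norm_chr <- function(x) {
    if (is.null(x)) return(rep(NA_character_, n))
    x <- as.character(x)
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    if (length(x) != n) stop("metadata column length mismatch")
    x
  }
  month <- if (is.null(month)) rep(NA_integer_, n) else {
    mo <- suppressWarnings(as.integer(month))
    if (length(mo) != n) stop("metadata column length mismatch")
    bad <- which(!is.na(mo) & (mo < 1L | mo > 12L))
    if (length(bad))
      stop("month out of range 1..12 in row ", bad[1L], ": ", mo[bad[1L]])
    mo
  }
  df <- data.frame(observation_id = as.character(observation_id),
                   habitat = norm_chr(habitat),
                   substrate = norm_chr(substrate),
                   month = month,
                   stringsAsFactors = FALSE)
  class(df) <- c("metadata_table", "data.frame")
  df
}

as_metadata_table <- function(x) {
  if (inherits(x, "metadata_table")) return(x)
  if (!is.data.frame(x) || !"observation_id" %in% names(x))
    stop("metadata must be a data frame with an observation_id column")
  metadata_table(x$observation_id,
                 habitat = x[["habitat"]],
                 substrate = x[["substrate"]],
                 month = x[["month"]])
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
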