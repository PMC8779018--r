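#' Adjust classifier posteriors to new class priors
#'
#' A classifier trained by cross-entropy minimization estimates the
#' posterior p(s | x) under the *training* class prior p(s). When the
#' deployment prior pe(s) differs (label shift: the species distribution
#' changes with season, location, dataset construction, while appearance
#' given species does not), the corrected posterior is
#'
#'   pe(s | x) proportional to  p(s | x) * pe(s) / p(s),
#'
#' renormalized over species; the unknown evidence terms cancel. Computation
#' is done in log space so that thousands of tiny probabilities do not
#' underflow; exact zeros in the input stay exact zeros in the output.
#'
#' A species with p(s) = 0 is only permitted if no row places mass on it
#' (the class is dropped consistently); positive posterior mass on a
#' zero-prior species is an error, not a silent clamp, because the ratio is
#' undefined and clamping would hide a train/deploy mismatch.
#'
#' @param post a [posterior_matrix()] (or bare N x K matrix).
#' @param train_prior [prior_vector()] p(s) the classifier was trained under.
#' @param target_prior [prior_vector()] pe(s) of the deployment distribution.
#' @param space the [label_space()] aligning all three.
#' @return adjusted `posterior_matrix`, same shape and observation order.
#' @seealso [adjust_to_uniform()] for the uniform-target special case.
#' @examples
#' sp <- label_space(c("a", "b", "c"))
#' post <- posterior_matrix(matrix(c(0.6, 0.3, 0.1), 1), sp)
#' p <- prior_vector(c(0.5, 0.3, 0.2), sp)
#' adjust_posteriors(post, p, uniform_prior(sp), sp)
#' @export
adjust_posteriors <- function(post, train_prior, target_prior, space) {
  space <- as_label_space(space)
  post <- as_posterior_matrix(post, space)
  p <- prior_vector(train_prior, space)
  pe <- prior_vector(target_prior, space)
  unsupported <- which(p == 0 & colSums(post) > 0)
  if (length(unsupported))
    stop("train prior is zero for species with posterior mass: ",
         space$species[unsupported[1L]])
  lw <- log(unclass(post)) +
    rep(log(pe) - log(p), each = nrow(post))
  lw[unclass(post) == 0] <- -Inf  # exact zeros stay zero (0 * 0/0 cases)
  renormalize_log(lw, space, rownames(post))
}

# Stable row renormalization of log-weights; rows must have finite max.
renormalize_log <- function(lw, space, obs_ids) {
  mx <- apply(lw, 1L, max)
  bad <- which(!is.finite(mx))
  if (length(bad))
    stop("degenerate row ", bad[1L], ": no species retains support")
  w <- exp(lw - mx)
  posterior_matrix(w / rowSums(w), space, observation_ids = obs_ids)
}

#' Adjust posteriors to a uniform deployment prior
#'
#' The special case pe(s) = 1/K of [adjust_posteriors()]:
#' pe(s | x) proportional to p(s | x) / p(s). Appropriate for balanced
#' evaluation sets drawn with equal per-species probability.
#'
#' @inheritParams adjust_posteriors
#' @return adjusted `posterior_matrix`.
#' @export
adjust_to_uniform <- function(post, train_prior, space) {
  adjust_posteriors(post, train_prior, uniform_prior(space), space)
}

#' Estimate class priors from training labels
#'
#' Empirical species relative frequencies with optional additive smoothing:
#' p(s) = (count_s + pseudocount) / (N + K * pseudocount). The default
#' pseudocount 0 gives the raw empirical training distribution; smoothing is
#' opt-in for downstream uses that require strictly positive priors.
#'
#' @param labels character vector of species ids, one per training record.
#' @param space a [label_space()]; every label must belong to it.
#' @param pseudocount non-negative additive smoothing constant.
#' @return a [prior_vector()].
#' @export
estimate_class_priors <- function(labels, space, pseudocount = 0) {
  space <- as_label_space(space)
  labels <- as.character(labels)
  if (!length(labels)) stop("labels must be non-empty")
  unknown <- setdiff(labels, space$species)
  if (length(unknown))
    stop("unknown species in labels: ", unknown[1L])
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  counts <- table(factor(labels, levels = space$species))
  vals <- (as.numeric(counts) + pseudocount) /
    (length(labels) + space$K * pseudocount)
  prior_vector(vals, space)
}
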