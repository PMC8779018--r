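#' Fit species-given-metadata frequency tables
#'
#' For each metadata type (habitat, substrate, month) and each value d
#' observed in training, estimates the conditional species distribution as
#' the (optionally smoothed) relative frequency
#'
#'   p(s | d) = (count(s, d) + alpha) / (count(d) + K * alpha).
#'
#' Observations whose field is missing are excluded from that type's counts.
#' Values never seen in training have no stored table; lookups for them fall
#' back to the training prior p(s), which makes the corresponding fusion
#' factor uninformative rather than undefined.
#'
#' When `joint = TRUE` the model additionally stores relative frequencies of
#' species given the complete tuple of non-missing metadata values, used by
#' [fuse()] for tuples whose training count reaches `min_joint_count`; this
#' replaces the independence product with a direct joint estimate where data
#' suffice. Off by default: independence is the baseline.
#'
#' @param labels character vector of species ids, aligned with `metadata`.
#' @param metadata a [metadata_table()] with one record per label.
#' @param space a [label_space()].
#' @param alpha pseudocount(s): a single non-negative number, or a named
#'   vector/list with entries for "habitat", "substrate", "month".
#' @param joint also fit the joint species-given-tuple table.
#' @param min_joint_count minimum training count for a tuple's joint
#'   estimate to be used at fusion time.
#' @return object of class `frequency_model`.
#' @export
fit_frequency_model <- function(labels, metadata, space, alpha = 0,
                                joint = FALSE, min_joint_count = 10L) {
  space <- as_label_space(space)
  labels <- as.character(labels)
  metadata <- as_metadata_table(metadata)
  if (length(labels) != nrow(metadata))
    stop("alignment error: ", length(labels), " labels vs ",
         nrow(metadata), " metadata records")
  unknown <- setdiff(labels, space$species)
  if (length(unknown)) stop("unknown species in labels: ", unknown[1L])
  alpha <- resolve_alpha(alpha)

  f_lab <- factor(labels, levels = space$species)
  tables <- lapply(METADATA_TYPES, function(type) {
    vals <- as.character(metadata[[type]])
    keep <- !is.na(vals)
    if (!any(keep)) return(NULL)  # empty table: lookups fall back to prior
    counts <- table(factor(vals[keep]), f_lab[keep])  # values x species
    a <- alpha[[type]]
    tab <- (unclass(counts) + a) / (rowSums(counts) + space$K * a)
    dimnames(tab) <- list(rownames(counts), space$species)
    tab
  })
  names(tables) <- METADATA_TYPES

  joint_table <- NULL
  if (joint) {
    key <- joint_key(metadata)
    keep <- !is.na(key)
    if (any(keep)) {
      counts <- table(factor(key[keep]), f_lab[keep])
      cnt <- rowSums(counts)
      ok <- cnt >= min_joint_count
      if (any(ok)) {
        joint_table <- unclass(counts)[ok, , drop = FALSE] / cnt[ok]
        colnames(joint_table) <- space$species
      }
    }
  }

  structure(list(tables = tables, alpha = alpha,
                 train_prior = estimate_class_priors(labels, space),
                 joint = joint_table,
                 min_joint_count = as.integer(min_joint_count),
                 space = space),
            class = "frequency_model")
}

resolve_alpha <- function(alpha) {
  if (length(alpha) == 1L && is.null(names(alpha)))
    alpha <- stats::setNames(rep(as.numeric(alpha), 3L), METADATA_TYPES)
  alpha <- as.list(alpha)
  missing <- setdiff(METADATA_TYPES, names(alpha))
  alpha[missing] <- 0
  alpha <- alpha[METADATA_TYPES]
  if (any(unlist(alpha) < 0)) stop("alpha must be non-negative")
  alpha
}

# Tuple key over all three types; NA if every field is missing.
joint_key <- function(metadata) {
  parts <- lapply(METADATA_TYPES, function(t) {
    v <- as.character(metadata[[t]])
    ifelse(is.na(v), "<NA>", v)
  })
  key <- do.call(paste, c(parts, sep = "\r"))
  all_missing <- Reduce(`&`, lapply(METADATA_TYPES,
                                    function(t) is.na(metadata[[t]])))
  key[all_missing] <- NA_character_
  key
}

#' @export
print.frequency_model <- function(x, ...) {
  sizes <- vapply(x$tables, function(t) if (is.null(t)) 0L else nrow(t),
                  integer(1))
  cat("frequency_model over", x$space$K, "species;",
      paste(sprintf("%s: %d values", names(sizes), sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Look up the species distribution for one metadata value
#'
#' Returns the fitted p(s | d) for a metadata value observed in training,
#' or the training prior p(s) for an unseen value (the fallback that makes
#' the corresponding fusion factor a no-op).
#'
#' @param model a fitted [fit_frequency_model()].
#' @param type one of "habitat", "substrate", "month".
#' @param value the metadata value (month: integer 1..12).
#' @return named length-K probability vector.
#' @export
species_given_metadata <- function(model, type, value) {
  stopifnot(inherits(model, "frequency_model"))
  type <- match.arg(type, METADATA_TYPES)
  if (type == "month") {
    value <- suppressWarnings(as.integer(value))
    if (is.na(value) || value < 1L || value > 12L)
      stop("month must be an integer in 1..12")
  }
  tab <- model$tables[[type]]
  value <- as.character(value)
  if (is.null(tab) || !value %in% rownames(tab))
    return(stats::setNames(as.numeric(model$train_prior),
                           model$space$species))
  stats::setNames(tab[value, ], model$space$species)
}

#' Fuse image posteriors with observation metadata
#'
#' Combines the classifier posterior with the species-given-metadata
#' frequencies under the assumption that visual appearance is conditionally
#' independent of the metadata given the species:
#'
#'   p(s | i, d1..dm)  proportional to  p(s | i) * prod_j p(s | dj) / p(s)^m,
#'
#' where the product runs over the *selected, non-missing* metadata fields of
#' each observation and m is their count. An observation with every selected
#' field missing is returned unchanged; metadata values unseen in training
#' contribute p(s | d) = p(s), also a no-op. The product is accumulated in
#' log space (three factors over ~1600 species underflow in linear space);
#' zeros in the input posterior remain exact zeros.
#'
#' With `use_joint = TRUE` and a model fitted with `joint = TRUE`, an
#' observation whose full metadata tuple was frequent enough in training
#' uses the directly estimated p(s | d1..dm) as a single factor instead of
#' the independence product.
#'
#' @param post a [posterior_matrix()] of visual posteriors p(s | i).
#' @param metadata a [metadata_table()] aligned row-by-row with `post`.
#' @param model a fitted [fit_frequency_model()].
#' @param types metadata types to fuse (subset of habitat, substrate, month).
#' @param use_joint use the joint tuple table where available.
#' @return fused `posterior_matrix`.
#' @export
fuse <- function(post, metadata, model,
                 types = c("habitat", "substrate", "month"),
                 use_joint = FALSE) {
  stopifnot(inherits(model, "frequency_model"))
  space <- model$space
  post <- as_posterior_matrix(post, space)
  metadata <- as_metadata_table(metadata)
  types <- if (length(types)) match.arg(types, METADATA_TYPES,
                                        several.ok = TRUE) else character()
  if (nrow(metadata) != nrow(post))
    stop("alignment error: ", nrow(post), " posterior rows vs ",
         nrow(metadata), " metadata records")
  p <- model$train_prior
  unsupported <- which(p == 0 & colSums(post) > 0)
  if (length(unsupported))
    stop("train prior is zero for species with posterior mass: ",
         space$species[unsupported[1L]])

  lp <- log(as.numeric(p))
  lw <- log(unclass(post))
  touched <- rep(FALSE, nrow(post))

  if (use_joint && !is.null(model$joint)) {
    key <- joint_key(metadata)
    hit <- !is.na(key) & key %in% rownames(model$joint)
    if (any(hit)) {
      lw[hit, ] <- lw[hit, , drop = FALSE] +
        log(model$joint[key[hit], , drop = FALSE]) -
        rep(lp, each = sum(hit))
      touched <- touched | hit
    }
  } else {
    use_joint <- FALSE
  }

  for (type in types) {
    vals <- as.character(metadata[[type]])
    present <- !is.na(vals)
    if (use_joint) present <- present & !touched  # joint rows already done
    if (!any(present)) next
    for (v in unique(vals[present])) {
      rows <- which(present & vals == v)
      lpsd <- log(species_given_metadata(model, type, v))
      lw[rows, ] <- lw[rows, , drop = FALSE] +
        rep(lpsd - lp, each = length(rows))
    }
    touched[present] <- TRUE
  }

  if (!any(touched)) return(post)
  lw[unclass(post) == 0] <- -Inf  # exact zeros stay zero
  out <- renormalize_log(lw, space, rownames(post))
  out[!touched, ] <- post[!touched, ]  # all-missing rows pass through
  out
}
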