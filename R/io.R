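# Tabular/JSON interchange. CSV for matrices, labels and metadata; JSON for
# priors, frequency models, crop specs and reports. Numeric output uses 9
# significant digits: below the validation tolerance, above test tolerance.

FMT_DIGITS <- 9L

fmt_num <- function(x) formatC(x, digits = FMT_DIGITS, format = "g")

#' Write / read a posterior matrix as CSV
#'
#' Format: header `observation_id,<species...>` (species always in label
#' space order), one row per observation. Round-trips are lossless at the
#' 9-significant-digit output precision.
#'
#' @param post a [posterior_matrix()].
#' @param path file path.
#' @export
write_posteriors <- function(post, path) {
  stopifnot(inherits(post, "posterior_matrix"))
  header <- paste(c("observation_id", colnames(post)), collapse = ",")
  body <- vapply(seq_len(nrow(post)), function(i)
    paste(c(rownames(post)[i], fmt_num(post[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_posteriors
#' @param space optional [label_space()]; defaults to one defined by the
#'   file header (column order = species order).
#' @return `read_posteriors`: a [posterior_matrix()].
#' @export
read_posteriors <- function(path, space = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("posterior file has no data rows: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "observation_id")
    stop("parse error line 1: first column must be observation_id")
  species <- header[-1L]
  if (anyDuplicated(species))
    stop("parse error line 1: duplicated species column: ",
         species[duplicated(species)][1L])
  cells <- strsplit(lines[-1L], ",", fixed = TRUE)
  widths <- lengths(cells)
  bad <- which(widths != length(header))
  if (length(bad))
    stop(sprintf("parse error line %d: %d fields, expected %d",
                 bad[1L] + 1L, widths[bad[1L]], length(header)))
  obs <- vapply(cells, `[`, character(1), 1L)
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(cells, `[`, -1L))),
           nrow = length(cells), byrow = TRUE))
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1L, anyNA))[1L]
    stop("parse error line ", bad_row + 1L, ": non-numeric cell")
  }
  if (is.null(space)) space <- label_space(species)
  space <- as_label_space(space)
  if (!identical(species, space$species))
    stop("file species columns do not match the label space")
  posterior_matrix(vals, space, observation_ids = obs)
}

#' Write / read a prior vector as JSON
#'
#' JSON object mapping species identifier to probability.
#' @param prior a [prior_vector()].
#' @param path file path.
#' @export
write_prior <- function(prior, path) {
  jsonlite::write_json(as.list(unclass(prior)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prior
#' @param space optional [label_space()] fixing the species order.
#' @export
read_prior <- function(path, space = NULL) {
  x <- jsonlite::fromJSON(path)
  if (is.null(space)) space <- label_space(names(x))
  space <- as_label_space(space)
  miss <- setdiff(space$species, names(x))
  if (length(miss)) stop("prior file missing species: ", miss[1L])
  prior_vector(unlist(x)[space$species], space)
}

#' Write / read a metadata table as CSV
#'
#' Columns `observation_id,habitat,substrate,month`; empty cell = missing.
#' @param metadata a [metadata_table()].
#' @param path file path.
#' @export
write_metadata <- function(metadata, path) {
  metadata <- as_metadata_table(metadata)
  df <- as.data.frame(metadata)
  df[] <- lapply(df, function(col) ifelse(is.na(col), "", as.character(col)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"observation_id" %in% names(df))
    stop("metadata file must have an observation_id column")
  month <- df[["month"]]
  if (!is.null(month)) {
    month[!nzchar(month)] <- NA
    mo <- suppressWarnings(as.integer(month))
    bad <- which((!is.na(month) & is.na(mo)) |
                   (!is.na(mo) & (mo < 1L | mo > 12L)))
    if (length(bad))
      stop("invalid month in row ", bad[1L], ": ", month[bad[1L]])
    month <- mo
  }
  blank_na <- function(x) { if (is.null(x)) return(NULL)
    x[!nzchar(x)] <- NA; x }
  metadata_table(df$observation_id,
                 habitat = blank_na(df[["habitat"]]),
                 substrate = blank_na(df[["substrate"]]),
                 month = month)
}

#' Write / read labels as CSV (observation_id, species)
#' @param labels character vector of species ids.
#' @param path file path.
#' @param observation_ids optional ids (default obs1..).
#' @export
write_labels <- function(labels, path, observation_ids = NULL) {
  if (is.null(observation_ids))
    observation_ids <- paste0("obs", seq_along(labels))
  utils::write.csv(data.frame(observation_id = observation_ids,
                              species = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @return `read_labels`: data.frame with observation_id and species.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("observation_id", "species") %in% names(df)))
    stop("labels file must have observation_id and species columns")
  df
}

#' Serialize / load a frequency model as JSON
#'
#' Layout: `{train_prior: {species: p}, alpha: {...},
#' tables: {type: {value: {species: p}}}}`.
#' @param model a [fit_frequency_model()].
#' @param path file path.
#' @export
write_frequency_model <- function(model, path) {
  stopifnot(inherits(model, "frequency_model"))
  tabs <- lapply(model$tables, function(tab) {
    if (is.null(tab)) return(stats::setNames(list(), character()))
    lapply(stats::setNames(rownames(tab), rownames(tab)),
           function(v) as.list(tab[v, ]))
  })
  jsonlite::write_json(list(species = model$space$species,
                            train_prior = as.list(unclass(model$train_prior)),
                            alpha = model$alpha,
                            tables = tabs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frequency_model
#' @export
read_frequency_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  space <- label_space(unlist(x$species))
  tables <- lapply(METADATA_TYPES, function(type) {
    tt <- x$tables[[type]]
    if (is.null(tt) || !length(tt)) return(NULL)
    tab <- t(vapply(tt, function(row) unlist(row)[space$species],
                    numeric(space$K)))
    dimnames(tab) <- list(names(tt), space$species)
    tab
  })
  names(tables) <- METADATA_TYPES
  structure(list(tables = tables,
                 alpha = resolve_alpha(unlist(x$alpha)),
                 train_prior = prior_vector(unlist(x$train_prior)[space$species],
                                            space),
                 joint = NULL, min_joint_count = 0L,
                 space = space),
            class = "frequency_model")
}

#' Write crop specs as JSON
#' @param specs list of [crop_spec()] (default the 14-view scheme).
#' @param path file path.
#' @export
write_crop_specs <- function(specs, path) {
  jsonlite::write_json(lapply(specs, function(s)
    list(id = s$id, box = as.numeric(s$box), mirrored = s$mirrored)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an evaluation report as JSON
#' @param report an [eval_report()].
#' @param path file path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(list(topk = as.list(report$topk),
                            mean_class_accuracy = report$mean_class_accuracy,
                            rank_shares = as.list(report$rank_shares),
                            n = report$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
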