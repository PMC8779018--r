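#' Rank of the true species in each posterior row
#'
#' Rank 1 + (number of species with strictly higher probability), with ties
#' broken by species order. The same deterministic rule underlies
#' [topk_accuracy()] and [rank_shares()], keeping them mutually consistent.
#'
#' @param post a [posterior_matrix()].
#' @param truth character vector of true species ids, one per row.
#' @param space a [label_space()].
#' @return integer vector of ranks in 1..K.
#' @export
true_rank <- function(post, truth, space) {
  space <- as_label_space(space)
  post <- as_posterior_matrix(post, space)
  truth <- as.character(truth)
  if (length(truth) != nrow(post))
    stop("truth length does not match posterior rows")
  idx <- match(truth, space$species)
  if (anyNA(idx))
    stop("unknown species in truth: ", truth[which(is.na(idx))[1L]])
  vapply(seq_len(nrow(post)), function(i) {
    r <- post[i, ]
    pt <- r[idx[i]]
    1L + sum(r > pt) + sum(r == pt & seq_along(r) < idx[i])
  }, integer(1))
}

#' Top-k accuracy in percent
#'
#' Fraction of observations whose true species is among the k highest-
#' probability species, times 100. Ties at the k-th place are resolved by
#' species order (see [true_rank()]).
#'
#' @inheritParams true_rank
#' @param k positive integer, at most K.
#' @return accuracy in percent.
#' @export
topk_accuracy <- function(post, truth, k, space) {
  space <- as_label_space(space)
  k <- as.integer(k)
  if (k < 1L || k > space$K) stop("k must be in 1..K")
  mean(true_rank(post, truth, space) <= k) * 100
}

#' Mean per-class (macro-averaged) top-1 accuracy in percent
#'
#' Unweighted mean over species of the per-species top-1 accuracy. Unlike
#' plain accuracy, this is not dominated by the head of a long-tailed class
#' distribution. Species absent from `truth` are excluded rather than
#' scored zero.
#'
#' @inheritParams true_rank
#' @return mean per-class accuracy in percent.
#' @export
mean_class_accuracy <- function(post, truth, space) {
  truth <- as.character(truth)
  if (!length(truth)) stop("truth must be non-empty")
  hit <- true_rank(post, truth, space) == 1L
  mean(tapply(hit, truth, mean)) * 100
}

#' Shares of observations by true-species rank bin
#'
#' How often the true species is ranked 1st, 2nd, 3rd-5th, or worse by the
#' classifier — the statistic behind human-in-the-loop accuracy, where a
#' user picks from the top suggestions rather than trusting the arg-max.
#'
#' @inheritParams true_rank
#' @param bins list of rank intervals `c(lo, hi)` (hi may be `Inf`);
#'   default `[1,1], [2,2], [3,5], [6,Inf)`. Must not overlap.
#' @return named numeric vector of shares (fractions summing to at most 1;
#'   exactly 1 when the bins cover 1..K).
#' @export
rank_shares <- function(post, truth, space,
                        bins = list(c(1, 1), c(2, 2), c(3, 5), c(6, Inf))) {
  lo <- vapply(bins, `[`, numeric(1), 1L)
  hi <- vapply(bins, `[`, numeric(1), 2L)
  if (any(lo > hi)) stop("bin lower edge exceeds upper edge")
  o <- order(lo)
  if (any(lo[o][-1L] <= hi[o][-length(o)]))
    stop("configuration error: rank bins overlap")
  r <- true_rank(post, truth, space)
  shares <- vapply(seq_along(bins),
                   function(j) mean(r >= lo[j] & r <= hi[j]), numeric(1))
  names(shares) <- vapply(bins, function(b) {
    if (is.infinite(b[2])) sprintf("%d+", b[1])
    else if (b[1] == b[2]) sprintf("%d", b[1])
    else sprintf("%d-%d", b[1], b[2])
  }, character(1))
  shares
}

#' Full evaluation report
#'
#' Top-k accuracies, mean per-class accuracy, and rank shares in one
#' object, printed in percent with two decimals.
#'
#' @inheritParams true_rank
#' @param ks top-k values to report.
#' @return object of class `eval_report` with fields `topk` (named percent
#'   vector), `mean_class_accuracy`, `rank_shares`, `n`.
#' @export
eval_report <- function(post, truth, space, ks = c(1, 3, 5)) {
  space <- as_label_space(space)
  ks <- sort(unique(as.integer(ks)))
  r <- true_rank(post, truth, space)
  topk <- vapply(ks, function(k) mean(r <= k) * 100, numeric(1))
  names(topk) <- paste0("top", ks)
  structure(list(topk = topk,
                 mean_class_accuracy = mean_class_accuracy(post, truth, space),
                 rank_shares = rank_shares(post, truth, space),
                 n = length(r)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation over", x$n, "observations\n")
  for (nm in names(x$topk))
    cat(sprintf("  %-5s accuracy: %6.2f %%\n", nm, x$topk[[nm]]))
  cat(sprintf("  mean per-class accuracy: %6.2f %%\n",
              x$mean_class_accuracy))
  cat("  true-rank shares:",
      paste(sprintf("%s: %.3f", names(x$rank_shares), x$rank_shares),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-species stratified train/test split
#'
#' For every species with n observations, exactly `ceiling(train_fraction
#' * n)` are assigned to the training set (selection uniformly at random
#' under `seed`) and the remainder to the test set. With the default 0.9
#' this guarantees a per-species training fraction of at least 90%; note a
#' species needs n with ceiling(0.9 n) < n — i.e. more than a handful of
#' records — to contribute any test observation at all.
#'
#' @param truth character vector of species ids, one per observation.
#' @param train_fraction fraction in (0, 1] of each species kept for
#'   training (ceiling rule).
#' @param seed integer seed; the split is reproducible given the seed.
#' @return list with integer index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
species_split <- function(truth, train_fraction = 0.9, seed = 1L) {
  truth <- as.character(truth)
  if (!length(truth)) stop("truth must be non-empty")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  idx_by_sp <- split(seq_along(truth), truth)
  with_seed(seed, {
    train <- unlist(lapply(idx_by_sp, function(idx) {
      n_train <- ceiling(train_fraction * length(idx))
      if (n_train >= length(idx)) idx
      else sort(sample(idx, n_train))
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(truth), train))
  })
}

#' Relative error reduction between two accuracies
#'
#' Given old and new accuracies in percent, returns the relative reduction
#' of the top-1 error rate, (e_old - e_new) / e_old * 100 — the standard
#' way improvements of already-accurate systems are quoted.
#'
#' @param acc_old,acc_new accuracies in percent (0..100), new >= old for a
#'   positive reduction.
#' @return relative error reduction in percent.
#' @export
error_reduction <- function(acc_old, acc_new) {
  e_old <- 100 - acc_old
  if (e_old <= 0) stop("old system has zero error; reduction undefined")
  (e_old - (100 - acc_new)) / e_old * 100
}

#' Published benchmark accuracies of the Danish fungi recognition systems
#'
#' Loads the small table of published Top-1/Top-3 accuracies of the deployed
#' and candidate fungi-recognition systems shipped with the package
#' (plain-text JSON under `extdata`). Used for arithmetic-consistency
#' checks of the headline error-reduction figures; no claim in this package
#' depends on re-measuring them.
#'
#' @return nested list of published accuracy figures, in percent.
#' @export
reported_benchmarks <- function() {
  path <- system.file("extdata", "reported_benchmarks.json",
                      package = "fungifuse", mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
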