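test_that("longtail_priors matches the harmonic hand example and is monotone", {
  expect_equal(as.numeric(longtail_priors(sp3, 1)),
               c(6, 3, 2) / 11, tolerance = 1e-12)
  sp <- label_space(paste0("s", 1:40))
  pr <- longtail_priors(sp, 1.5)
  expect_true(all(diff(as.numeric(pr)) <= 0))
  expect_equal(sum(pr), 1)
  # tiny exponent approaches uniform
  expect_equal(as.numeric(longtail_priors(sp, 1e-9)), rep(1 / 40, 40),
               tolerance = 1e-6)
  expect_error(longtail_priors(sp, 0), "positive")
  expect_error(longtail_priors(sp, -1), "positive")
})

test_that("build_model is reproducible and validates inputs", {
  m1 <- build_model(K = 10, V = 20, seed = 99)
  m2 <- build_model(K = 10, V = 20, seed = 99)
  expect_identical(m1$visual, m2$visual)
  expect_identical(m1$metadata, m2$metadata)
  expect_false(identical(m1$visual, build_model(K = 10, V = 20,
                                                seed = 100)$visual))
  expect_equal(unname(rowSums(m1$visual)), rep(1, 10), tolerance = 1e-12)
  for (ch in m1$metadata)
    expect_equal(unname(rowSums(ch)), rep(1, 10), tolerance = 1e-12)
  expect_equal(ncol(m1$metadata$month), 12L)
  expect_error(build_model(K = 1, V = 5), "at least 2")
  expect_error(build_model(K = 5, V = 5,
                           concentration = c(visual = 0, habitat = 1,
                                             substrate = 1, month = 1)),
               "positive")
})

test_that("large concentration gives near-uniform (uninformative) channels", {
  m <- build_model(K = 8, V = 10, concentration = c(visual = 1e5,
                                                    habitat = 1e5,
                                                    substrate = 1e5,
                                                    month = 1e5),
                   seed = 5)
  expect_lt(max(abs(m$visual - 1 / 10)), 0.02)
  # uninformative channel: posterior equals prior for every token
  for (v in 1:10)
    expect_equal(exact_posterior_visual(m, v, "train"),
                 stats::setNames(as.numeric(m$train_prior),
                                 m$space$species),
                 tolerance = 0.05)
})

test_that("exact_posterior_visual reproduces hand Bayes on the 2-species model", {
  m <- hand_model2()
  # uniform prior, token 1: (0.45, 0.10) -> (9/11, 2/11)
  expect_equal(exact_posterior_visual(m, 1, "train"),
               c(A = 9 / 11, B = 2 / 11), tolerance = 1e-12)
  expect_equal(exact_posterior_visual(m, 2, "train"),
               c(A = 1 / 9, B = 8 / 9), tolerance = 1e-12)
  # degenerate token: no species ever emits token 2
  md <- manual_model(visual = rbind(c(1, 0), c(1, 0)),
                     species = c("A", "B"))
  expect_error(exact_posterior_visual(md, 2), "degenerate token")
})

test_that("exact_posterior_full reproduces hand Bayes with one metadata channel", {
  m <- hand_model2()
  # (0.5*0.9*0.3, 0.5*0.2*0.7) = (0.135, 0.070) -> (27/41, 14/41)
  expect_equal(exact_posterior_full(m, 1, list(habitat = 1)),
               c(A = 0.135, B = 0.070) / 0.205, tolerance = 1e-12)
  # uninformative metadata channel: equals the visual posterior
  mu <- manual_model(visual = rbind(c(0.9, 0.1), c(0.2, 0.8)),
                     metadata = list(habitat = rbind(c(0.5, 0.5),
                                                     c(0.5, 0.5))),
                     species = c("A", "B"))
  expect_equal(exact_posterior_full(mu, 1, list(habitat = 2)),
               exact_posterior_visual(mu, 1), tolerance = 1e-12)
})

test_that("oracle equivalence: prior shift equals exact test-prior Bayes (K=5, V=7)", {
  model <- build_model(K = 5, V = 7, train_exponent = 1.2,
                       test_exponent = 0.5, seed = 123)
  sp <- model$space
  for (v in seq_len(7)) {
    train_post <- posterior_matrix(
      matrix(exact_posterior_visual(model, v, "train"), 1), sp)
    adjusted <- adjust_posteriors(train_post, model$train_prior,
                                  model$test_prior, sp)
    expect_equal(as.numeric(adjusted),
                 as.numeric(exact_posterior_visual(model, v, "test")),
                 tolerance = 1e-9)
  }
})

test_that("oracle equivalence: fusion equals exact full Bayes over all combinations", {
  # Small model so the whole observable space is enumerable.
  model <- build_model(K = 5, V = 7,
                       metadata_cardinalities = c(habitat = 3,
                                                  substrate = 2),
                       seed = 321)
  sp <- model$space
  fm <- true_frequency_model(model)
  for (v in seq_len(7)) {
    visual <- posterior_matrix(
      matrix(exact_posterior_visual(model, v, "train"), 1), sp)
    for (h in colnames(model$metadata$habitat)) {
      for (s in colnames(model$metadata$substrate)) {
        md <- metadata_table("o1", habitat = h, substrate = s)
        fused <- fuse(visual, md, fm, types = c("habitat", "substrate"))
        exact <- exact_posterior_full(model, v,
                                      list(habitat = h, substrate = s))
        expect_equal(as.numeric(fused), as.numeric(exact),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("sample_dataset is deterministic and Bayes-exact per row", {
  model <- build_model(K = 8, V = 12, seed = 7)
  d1 <- sample_dataset(model, 500, seed = 42)
  d2 <- sample_dataset(model, 500, seed = 42)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$posteriors, d2$posteriors)
  expect_false(identical(d1$labels,
                         sample_dataset(model, 500, seed = 43)$labels))
  expect_equal(unname(rowSums(d1$posteriors)), rep(1, 500),
               tolerance = 1e-12)
  # each posterior row is exactly the train-prior posterior of its token
  for (i in c(1, 100, 500))
    expect_equal(as.numeric(d1$posteriors[i, ]),
                 as.numeric(exact_posterior_visual(model,
                                                   d1$visual_tokens[i],
                                                   "train")),
                 tolerance = 1e-12)
})

test_that("sampled label frequencies match the sampling prior (3 SE)", {
  model <- build_model(K = 12, V = 10, train_exponent = 1, seed = 17)
  N <- 100000
  ds <- sample_dataset(model, N, which_prior = "train", seed = 18)
  emp <- as.numeric(table(factor(ds$labels,
                                 levels = model$space$species))) / N
  p <- as.numeric(model$train_prior)
  se <- sqrt(p * (1 - p) / N)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
})

test_that("temperature degrades posteriors but keeps them valid", {
  model <- build_model(K = 6, V = 9, seed = 3)
  hot <- sample_dataset(model, 50, seed = 9, temperature = 2)
  exact <- sample_dataset(model, 50, seed = 9, temperature = 1)
  expect_identical(hot$labels, exact$labels)   # same draws, softer rows
  expect_equal(unname(rowSums(hot$posteriors)), rep(1, 50),
               tolerance = 1e-12)
  # temperature > 1 flattens: max entry can only shrink
  expect_true(all(apply(hot$posteriors, 1, max) <=
                    apply(exact$posteriors, 1, max) + 1e-12))
  expect_error(sample_dataset(model, 10, seed = 1, temperature = 0),
               "positive")
})

test_that("fit_frequency_model recovers the implied conditionals at N = 50,000", {
  model <- build_model(K = 10, V = 20, seed = 31)
  N <- 50000
  ds <- sample_dataset(model, N, which_prior = "train", seed = 32)
  fm <- fit_frequency_model(ds$labels, ds$metadata, model$space)
  z <- numeric()
  for (type in c("habitat", "substrate", "month")) {
    vals <- colnames(model$metadata[[type]])
    counts <- table(factor(ds$metadata[[type]], levels = vals))
    for (v in vals) {
      n_d <- as.numeric(counts[[v]])
      if (n_d < 50) next  # too few draws for a meaningful SE check
      est <- species_given_metadata(fm, type, v)
      truth <- implied_species_given_metadata(model, type, v, "train")
      se <- sqrt(truth * (1 - truth) / n_d)
      z <- c(z, abs(est - truth) / pmax(se, 1e-12))
    }
  }
  # ~300 cells: a per-cell hard 3-SE bound fails by multiplicity alone
  # (expected ~0.8 chance exceedances), so assert the 3-SE property in
  # aggregate plus a Bonferroni-corrected family-wise bound on the worst cell
  expect_gt(length(z), 200)
  expect_lt(mean(z > 3), 0.02)
  expect_lt(max(z), stats::qnorm(1 - 0.0005 / length(z)))
})

test_that("directional gains: prior adjustment and 3-type fusion help where they should", {
  model <- build_model(K = 50, V = 200, train_exponent = 1.2,
                       test_exponent = 0.3, seed = 71)
  sp <- model$space
  ds <- sample_dataset(model, 10000, which_prior = "test", seed = 72)
  base <- topk_accuracy(ds$posteriors, ds$labels, 1, sp)
  adj <- topk_accuracy(adjust_posteriors(ds$posteriors, model$train_prior,
                                         model$test_prior, sp),
                       ds$labels, 1, sp)
  expect_gte(adj, base)

  # fusion on a train-prior sample with informative metadata channels
  dtr <- sample_dataset(model, 10000, which_prior = "train", seed = 73)
  fm <- true_frequency_model(model)
  single <- vapply(c("habitat", "substrate", "month"), function(t)
    topk_accuracy(fuse(dtr$posteriors, dtr$metadata, fm, types = t),
                  dtr$labels, 1, sp), numeric(1))
  all3 <- topk_accuracy(fuse(dtr$posteriors, dtr$metadata, fm),
                        dtr$labels, 1, sp)
  visual_only <- topk_accuracy(dtr$posteriors, dtr$labels, 1, sp)
  expect_true(all(single >= visual_only))
  expect_gte(all3, max(single))
})

test_that("uninformative metadata leaves accuracy unchanged", {
  model <- build_model(K = 20, V = 40,
                       concentration = c(visual = 0.1, habitat = 1e6,
                                         substrate = 1e6, month = 1e6),
                       seed = 81)
  ds <- sample_dataset(model, 5000, seed = 82)
  fm <- true_frequency_model(model)
  fused <- fuse(ds$posteriors, ds$metadata, fm)
  a0 <- topk_accuracy(ds$posteriors, ds$labels, 1, model$space)
  a1 <- topk_accuracy(fused, ds$labels, 1, model$space)
  expect_equal(a1, a0, tolerance = 0.2)
})
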