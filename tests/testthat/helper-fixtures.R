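# Shared fixtures. Everything is built in code; no stored data.

sp3 <- label_space(c("a", "b", "c"))

row_post <- function(..., space = sp3) {
  posterior_matrix(matrix(c(...), nrow = 1, byrow = TRUE), space)
}

# A tiny hand-set 2-species model used by the exact-Bayes examples.
hand_model2 <- function(meta = TRUE) {
  manual_model(
    visual = rbind(c(0.9, 0.1), c(0.2, 0.8)),
    metadata = if (meta) list(habitat = rbind(c(0.3, 0.7), c(0.7, 0.3)))
               else list(),
    species = c("A", "B"))
}

# Small seeded random posterior matrix over a given space.
random_posteriors <- function(n, space, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n * space$K), n)
    normalize_rows(m, space)
  })
}
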