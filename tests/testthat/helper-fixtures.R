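# Small in-code fixtures shared across test files.

# A desk-scale simulated two-source study; cached per test run.
small_study <- local({
  cache <- NULL
  function(N = 1e5, n1 = 400, n2 = 4000, overlap = 0.5,
           target_p2 = 0.33, seed = 101, fresh = FALSE) {
    key <- paste(N, n1, n2, overlap, target_p2, seed)
    if (!fresh && !is.null(cache) && cache$key == key) return(cache$value)
    params <- generative_params(N = N, n1 = n1, n2 = n2, overlap = overlap,
                                target_p1 = 0.30, target_p2 = target_p2,
                                seed = seed)
    params <- prevpool:::resolve_params(params)
    pop <- draw_population(params)
    tab <- sample_sources(pop, params)
    value <- list(params = params, pop = pop, tab = tab)
    cache <<- list(key = key, value = value)
    value
  }
})

# A fully linked subject table built directly (no simulator), with both
# outcomes observed everywhere and unit weights; used by diagnostics tests.
linked_table <- function(n, y1, y2, seed = 1) {
  set.seed(seed)
  subject_table(data.frame(
    id = seq_len(n),
    x1 = rbinom(n, 1, 0.5), x2 = rnorm(n),
    u1 = rbinom(n, 1, 0.5), u2 = rnorm(n),
    y1 = y1, y2 = y2,
    pi1 = runif(n, 0.05, 0.95), pi2 = NA_real_,
    in_survey = TRUE, in_ehr = TRUE, linked = TRUE,
    w1 = 1, w2 = 1
  ))
}
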