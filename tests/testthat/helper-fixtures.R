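# Shared, lazily built fixtures. Expensive model fits are cached in a
# session-level environment so several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# study-replica synthetic dataset (37 couples, 12 weeks, default truth)
replica_study <- function(rep = 1L) {
  cached(paste0("study", rep),
         simulate_study(true_parameters(seed = 100L + rep)))
}

# fast state-space fit of a replica dataset (3 chains x 2000 iterations)
replica_fit <- function(rep = 1L) {
  cached(paste0("fit", rep), {
    st <- replica_study(rep)
    std <- standardize_measures(score_panel(st$panel),
                                c("WHS_occur", "PSS", "TICS"))
    suppressWarnings(
      fit_state_space(std, state_space_spec(n_iter = 2000L), seed = rep)
    )
  })
}

# small scored study for cheap scoring / psychometrics checks
small_scores <- function() {
  cached("small_scores", {
    st <- simulate_study(true_parameters(n_couples = 20, seed = 7))
    list(study = st, scores = score_panel(st$panel))
  })
}

default_loading_truth <- c(0.87, 0.91, 0.49, 0.53, 0.44, 0.47)
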