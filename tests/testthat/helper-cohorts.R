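# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small planted 4-group cohort with normalized/log2 views precomputed
small_cohort <- function() cached("small_cohort", {
  cfg <- simulation_config(n_genes = 400, n_normal = 20,
                           group_sizes = rep(15, 4), seed = 42)
  sim <- simulate_cohort(cfg)
  sim$config <- cfg
  sim$tumors <- sim$annotation$sample_id[sim$annotation$tissue == "tumor"]
  sim$normals <- sim$annotation$sample_id[sim$annotation$tissue == "normal"]
  sim$norm <- quantile_normalize(sim$expression)
  sim$logm <- to_log2(sim$norm, pseudo = 1)
  sim
})

# its integrated DEG result for the tumor-vs-normal contrast (B = 200)
small_cohort_deg <- function() cached("small_cohort_deg", {
  sc <- small_cohort()
  deg_test(sc$logm, sc$tumors, sc$normals, B = 200, seed = 42)
})

# random symmetric distance matrix on n items
random_distance <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
  d + t(d)
}

# adjusted Rand index between two labelings (used for planted recovery)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
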