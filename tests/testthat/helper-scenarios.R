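# shared fixtures and sampling helpers

balanced <- function(eps) example_scenario("balanced_quartet", epsilon = eps)

caterpillar <- function(eps, delta = 1/100)
  example_scenario("caterpillar_quartet", epsilon = eps, delta = delta)

# largest strength at which the dissimilarity is still a
# triplet-respecting metric (hypothesis window for the deeper verdicts)
tr_metric_cap <- function(sc)
  min(distance_threshold(sc), triplet_threshold(sc), metric_threshold(sc))

# deterministic stream of random scenarios cycling over placement families
sample_scenarios <- function(k, seed, n_range = 4:8, epsilon = 0.5,
                             targets = c("unconstrained", "cherry",
                                         "sibling_pairs", "root_tops",
                                         "pair_below_child", "split_pair")) {
  set.seed(seed)
  out <- list()
  i <- 0L
  while (length(out) < k) {
    i <- i + 1L
    n <- sample(n_range, 1L)
    tr <- random_equidistant_tree(n)
    tg <- targets[1L + (i %% length(targets))]
    sc <- tryCatch(random_scenario(tr, epsilon = epsilon, target = tg),
                   error = function(e) NULL)
    if (!is.null(sc)) out[[length(out) + 1L]] <- sc
    if (i > 20L * k) stop("scenario sampling starved")
  }
  out
}
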