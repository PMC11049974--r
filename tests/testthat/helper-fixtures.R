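# shared fixtures: published parameter anchors and random model draws

ref_rows <- function() {
  split(reference_parameters(), seq_len(12))
}

# random non-degenerate (pools, J, m) draw on realistic scales
draw_model_params <- function() {
  repeat {
    p <- exp(stats::runif(3, log(5), log(150)))
    ps <- try(pool_sizes(p[1], p[2], p[3]), silent = TRUE)
    if (!inherits(ps, "try-error") && pools_distinct(ps)) break
  }
  list(pools = ps,
       J = exp(stats::runif(1, log(1), log(60))),
       m = stats::runif(1, 0.5, 1))
}

# standard 0-50 min fitting grid at the default 0.5-min sampling interval
default_grid <- function() seq(0, 50, by = 0.5)
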