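# Shared fixtures: a compact five-network atlas (keeps simulation cheap in
# Monte-Carlo tests) and the full-size atlas used by the ICA suite.

tiny_atlas <- function() make_network_atlas(c(16L, 8L, 2L), n_networks = 5L)

full_atlas <- function() make_network_atlas(c(16L, 16L, 8L), n_networks = 5L)

# A PPG trace with Gaussian pulses at known beat times (ms).
synth_ppg <- function(beat_ms, dur_s = 310, rate_hz = 50, noise_sd = 0,
                      amplitude = 1) {
  n <- as.integer(dur_s * rate_hz)
  tms <- (seq_len(n) - 1) / rate_hz * 1000
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  x <- numeric(n)
  for (tb in beat_ms) x <- x + exp(-((tms - tb)^2) / (2 * sigma^2))
  x <- amplitude * x
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  structure(
    list(samples = x, rate_hz = rate_hz, start_time_s = 0),
    class = "ppg_trace"
  )
}

# Flood-fill connected components via igraph, as an independent oracle for
# label_clusters().
igraph_components <- function(mask, connectivity = 18) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, dim(mask))
  n <- length(idx)
  edges <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      d <- abs(co[i, ] - co[j, ])
      ok <- switch(as.character(connectivity),
        "6" = sum(d) == 1,
        "18" = max(d) <= 1 && sum(d != 0) <= 2,
        "26" = max(d) <= 1
      )
      if (ok) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$csize
}
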