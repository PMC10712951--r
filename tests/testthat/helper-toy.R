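# Shared fixtures: a miniature circuit with the full wiring but tiny
# layers, plus independent brute-force oracles used against the engine.

toy_config <- function(input_size = 6, ec_k = 2) {
  cfg <- default_architecture(input_size, ec_k)
  cfg$layers$DG$size <- 20
  cfg$layers$CA3$size <- 8
  cfg$layers$CA1$size <- 10
  cfg$layers$DG$k <- 2
  cfg$layers$CA3$k <- 2
  cfg$layers$CA1$k <- 3
  cfg
}

toy_network <- function(seed = 1, ...) build_network(toy_config(...), seed)

# Brute-force net input: elementwise triple loop over mask x weight x
# activity, independent of the matrix code path.
brute_net_input <- function(dst, net, state, phase = "test",
                            gate_override = NULL) {
  nd <- net$layers[[dst]]$size
  drive <- numeric(nd)
  for (key in names(net$projections)) {
    p <- net$projections[[key]]
    if (p$dst != dst) next
    g <- p$gates[[phase]]
    if (is.null(g)) g <- 1
    if (!is.null(gate_override) && key %in% names(gate_override))
      g <- gate_override[[key]]
    g <- g * p$strength
    a <- state[[p$src]]
    for (i in seq_len(nd))
      for (j in seq_along(a))
        if (p$mask[i, j] == 1)
          drive[i] <- drive[i] + g * p$We[i, j] * a[j] / p$norm
  }
  drive
}

# Brute-force CHL delta: scalar loop over the update formula.
brute_chl <- function(W, mask, pre_plus, post_plus, minus, lr) {
  d <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      if (mask[i, j] == 0) next
      cm <- mean(vapply(minus, function(m) m$post[i] * m$pre[j], 0))
      raw <- post_plus[i] * pre_plus[j] - cm
      d[i, j] <- lr * if (raw > 0) raw * (1 - W[i, j]) else raw * W[i, j]
    }
  }
  d
}

# Brute-force Pearson correlation matrix via the covariance formula.
brute_cor_matrix <- function(X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}
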