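# small model constructors shared across tests

# default-rate model (unit reaction volumes) at a given molecule number
preset_model <- function(N_T, ...) polarity_model(N_T = N_T, ...)

# fast-consolidating clan test system: critical number 10, so the membrane
# holds ~N_T - 10 molecules and neutral drift plays out in a few minutes
clan_model <- function(N_T = 60, k_fb = 0.9, ...) {
  polarity_model(N_T = N_T, k_fb = k_fb, k_on = 0, ...)
}

# random valid parameter draws for property-style tests
random_model <- function() {
  V <- stats::runif(1, 0.5, 4)
  polarity_model(k_off = stats::runif(1, 0.1, 20),
                 k_on = stats::runif(1, 0, 0.01),
                 k_fb = stats::runif(1, 1e-4, 1),
                 V = V,
                 V_on = stats::runif(1, 0.1, 1) * V,
                 V_fb = stats::runif(1, 0.1, 1) * V,
                 N_T = sample.int(5000, 1))
}

# dense generator matrix of the cytosolic-count chain (independent oracle)
generator_matrix <- function(m) {
  n <- m$N_T + 1L
  r <- transition_rates(0:m$N_T, m)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) G[i, i + 1] <- r$birth[i]
    if (i > 1) G[i, i - 1] <- r$death[i]
    G[i, i] <- -sum(G[i, ])
  }
  G
}
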