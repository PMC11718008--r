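# shared fixtures: everything is generated in code at test time

default_config <- radar_config()

# a short clean recording used by several files (60 s keeps tests quick)
quiet_profile <- function(seed = 1, ...) {
  physio_profile(breathing_rate = 15, mean_ibi = 0.857, ibi_sd = 40,
                 seed = seed, ...)
}

# portable LCG matching inst/reference/vmd_reference.py, used to build the
# fixtures on which the independent reference decomposition was run
lcg_uniform <- function(seed, n) {
  state <- seed
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- (1103515245 * state + 12345) %% 2147483648
    out[i] <- state / 2147483648
  }
  out
}

vmd_reference_fixture <- function(seed) {
  fs <- 20
  t <- (0:(60 * fs - 1)) / fs
  u <- lcg_uniform(seed, 3 + length(t))
  ph <- 2 * pi * u[1:3]
  noise <- 0.05 * (u[-(1:3)] - 0.5)
  list(x = sin(2 * pi * 1.1 * t + ph[1]) +
         0.7 * sin(2 * pi * 2.6 * t + ph[2]) +
         0.4 * sin(2 * pi * 4.3 * t + ph[3]) + noise,
       fs = fs)
}

# cluster an imf_set's mode powers by centre frequency (0.1 Hz linkage) and
# return the top components, mirroring the reference script's reporting
clustered_components <- function(imfs, tol = 0.1, top = 3) {
  ord <- order(imfs$center_frequencies)
  cf <- imfs$center_frequencies[ord]
  cl <- cumsum(c(1, diff(cf) > tol))
  out <- do.call(rbind, lapply(unique(cl), function(c0) {
    m <- ord[cl == c0]
    agg <- rowSums(imfs$modes[, m, drop = FALSE])
    p <- mean(agg^2)
    w <- imfs$powers[m]
    if (sum(w) == 0) return(NULL)
    data.frame(cf = sum(cf[cl == c0] * w) / sum(w), power = p)
  }))
  out <- head(out[order(-out$power), , drop = FALSE], top)
  out[order(out$cf), , drop = FALSE]
}
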