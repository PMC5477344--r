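# independent oracles, deliberately separate from the package's RK4 path

# brute-force fixed-step Euler integration of one movement + hold at a
# fine step, in plain R; mirrors the physical model definition only
euler_trial <- function(limb, robot, duration_ms, record_ms, start, target,
                        dt_ms = 0.05) {
  d2r <- pi / 180; r2d <- 180 / pi
  T <- duration_ms / 1000
  nsteps <- round(record_ms / dt_ms)
  keep <- round(1 / dt_ms) # record every 1 ms
  th <- numeric(record_ms); om <- numeric(record_ms)
  x <- start; v <- 0; engaged <- FALSE
  delta <- target - start
  for (i in seq_len(nsteps)) {
    t <- (i - 1) * dt_ms / 1000
    if ((i - 1) %% keep == 0) {
      j <- (i - 1) %/% keep + 1
      th[j] <- x; om[j] <- v
    }
    if (t <= T) {
      ph <- pi * t / T
      thc <- start + delta * (1 - cos(ph)) / 2
      omc <- delta * pi / (2 * T) * sin(ph)
      alc <- delta * pi^2 / (2 * T^2) * cos(ph)
      tau <- robot$kp * (thc - x) * d2r + robot$kd * (omc - v) * d2r +
        robot$inertia_estimate * alc * d2r
    } else {
      tau <- robot$hold_gain * (target - x)
    }
    tau <- max(min(tau, robot$torque_limit), -robot$torque_limit)
    if (limb$spastic_gain > 0 && t <= T &&
        abs(x - start) >= limb$catch_onset_excursion) engaged <- TRUE
    s <- if (!engaged) 0 else if (t <= T) 1 else
      exp(-(t - T) / limb$release_time_constant)
    tau <- tau - limb$passive_damping * v * d2r -
      limb$spastic_gain * s * v * d2r
    if (!is.na(limb$contracture_limit) && limb$contracture_stiffness > 0 &&
        x > limb$contracture_limit)
      tau <- tau - limb$contracture_stiffness * (x - limb$contracture_limit)
    a <- tau / limb$inertia * r2d
    x <- x + v * dt_ms / 1000
    v <- v + a * dt_ms / 1000
  }
  list(angle = th, velocity = om)
}

# brute-force midranks by counting, then the Pearson formula written out;
# independent of rank()/cor()
brute_spearman <- function(x, y) {
  n <- length(x)
  rk <- function(v) vapply(seq_len(n), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, 0)
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
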