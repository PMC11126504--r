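# Shared fixtures and independent one-line oracles for the metric formulas.
# Oracles are written directly from the definitions (distances, headings,
# turning angles) and never call the package's metric functions.

make_traj <- function(tx, ty, hx = tx, hy = ty + 0.5, fps = 25,
                      label = "unknown", ant_id = "fix") {
  trajectory(frame = seq_along(tx) - 1L, head_x = hx, head_y = hy,
             thorax_x = tx, thorax_y = ty, frame_rate = fps,
             label = label, ant_id = ant_id)
}

random_traj <- function(n, seed, scale = 1) {
  set.seed(seed)
  tx <- cumsum(rnorm(n, 0, scale))
  ty <- cumsum(rnorm(n, 0, scale))
  make_traj(tx, ty)
}

oracle_steps <- function(tx, ty) {
  dx <- diff(tx); dy <- diff(ty)
  len <- sqrt(dx^2 + dy^2)
  hd <- atan2(dy, dx)
  ta <- diff(hd)
  ta <- ((ta + pi) %% (2 * pi)) - pi
  ta[ta == -pi] <- pi
  list(length = len, turning_angle = ta)
}

oracle_sinuosity <- function(tx, ty) {
  st <- oracle_steps(tx, ty)
  p <- mean(st$length); c_ <- mean(cos(st$turning_angle))
  b <- sd(st$length) / p
  2 * (p * ((1 + c_) / (1 - c_) + b^2))^-0.5
}

oracle_emax <- function(tx, ty) {
  beta <- mean(cos(oracle_steps(tx, ty)$turning_angle))
  beta / (1 - beta)
}

oracle_straightness <- function(tx, ty) {
  n <- length(tx)
  sqrt((tx[n] - tx[1])^2 + (ty[n] - ty[1])^2) /
    sum(sqrt(diff(tx)^2 + diff(ty)^2))
}

oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# von Mises log-likelihood written from the density; for the numeric oracle
oracle_vm_loglik <- function(a_deg, mu_deg, kappa) {
  sum(kappa * cos((a_deg - mu_deg) * pi / 180)) -
    length(a_deg) * (log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) +
                       kappa)
}
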