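# Shared fixtures, built in code at test time.

# a four-channel montage with two symmetric pairs
tiny_montage <- function() {
  new_montage(
    "tiny4",
    tibble::tibble(channel = c("L1", "L2", "R1", "R2"),
                   emitter = c("l1", "l2", "r1", "r2"),
                   detector = c("dl", "dl", "dr", "dr"),
                   hemisphere = c("left", "left", "right", "right")),
    tibble::tibble(left_channel = c("L1", "L2"),
                   right_channel = c("R1", "R2")),
    fs_default = 15.6)
}

# silent noise specification for exact-recovery tests
quiet_noise <- function() noise_spec(0, 0, 0, 0, 0)

# hand-built schedule with a single motor-imagery trial
one_trial_schedule <- function(task = "mi_left", fs = 15.6,
                               prep = 2, dur = 15) {
  phases <- tibble::tibble(
    onset = c(0, prep, prep + dur, 2 * prep + dur),
    duration = c(prep, dur, prep, dur),
    label = c("prep_rest", "rest", "prep_task", task),
    block = 1L, trial = 1L)
  structure(list(phases = phases,
                 cues = tibble::tibble(onset = phases$onset[c(2, 4)],
                                       label = phases$label[c(2, 4)]),
                 fs = fs, duration = 2 * (prep + dur) + 40,
                 protocol = "clinical", session_id = 1L, day_index = 1L),
            class = "nirs_schedule")
}

# response table for a single subject on the tiny montage
tiny_responses <- function(values) {
  grid <- expand.grid(channel = c("L1", "L2", "R1", "R2"),
                      task = c("mi_left", "mi_right"),
                      chromophore = "HbO", stringsAsFactors = FALSE)
  grid$coefficient <- values
  tibble::as_tibble(grid)
}

# brute-force Benjamini-Yekutieli adjustment straight from the definition
by_adjust_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  # step-down monotonicity from the largest rank
  if (m >= 2)
    for (i in (m - 1):1)
      adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# exact two-sided signed-rank p by enumerating every sign assignment
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
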