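# Shared fixtures and independent oracles, built in code at test time.

# Short trapezoid for fast unit tests: 50/200/50 ms, 301 frames.
short_profile <- function(depth_mm = 1.4)
  indentation_profile(onset_ms = 50, hold_ms = 200, offset_ms = 50,
                      depth_mm = depth_mm)

quick_trial <- function(shape = "cone", size = 3, seed = 1,
                        noise_sd = 0, jitter_mm = 0,
                        profile = short_profile()) {
  generate_trial(stimulus_object(shape, size), profile,
                 noise_sd = noise_sd, jitter_mm = jitter_mm, seed = seed)
}

# Tiny noisy dataset (8 objects x n trials, short profile) for classifier
# tests that need realistic structure without the full 2.5 s trials.
quick_dataset <- function(n_trials = 3, master_seed = 1)
  generate_dataset(n_trials_per_object = n_trials,
                   profile = short_profile(), master_seed = master_seed)

# Brute-force Victor-Purpura oracle: enumerate every matching between the
# two trains (each spike either matched to one spike of the other train,
# order-preserving, or deleted/inserted) and take the minimal cost.
# Exponential; only for trains of <= ~6 spikes.
vp_bruteforce <- function(t1, t2, q) {
  n <- length(t1); m <- length(t2)
  if (n == 0) return(m)
  if (m == 0) return(n)
  best <- Inf
  rec <- function(i, j, cost) {
    if (cost >= best) return()
    if (i > n || j > m) {
      total <- cost + (n - i + 1) + (m - j + 1)
      if (total < best) best <<- total
      return()
    }
    rec(i + 1, j + 1, cost + q * abs(t1[i] - t2[j]))  # match i-j (shift)
    rec(i + 1, j, cost + 1)                           # delete t1[i]
    rec(i, j + 1, cost + 1)                           # insert t2[j]
  }
  rec(1L, 1L, 0)
  best
}

random_train <- function(n_max = 6, t_max = 500) {
  n <- sample(0:n_max, 1)
  sort(runif(n, 0, t_max))
}

# Stable RS rest potential: the relevant root of v^2/32 + (4 - b) v +
# 109.375 = 0, found independently with polyroot.
rs_rest_oracle <- function(b = 0.2) {
  r <- Re(polyroot(c(109.375, 4 - b, 1 / 32)))
  min(r)  # stable fixed point is the more negative root
}
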