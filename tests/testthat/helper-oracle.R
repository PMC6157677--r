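# Independent oracles for the season process, used only by tests.

# Plain-R re-implementation of a season under a *constant* hazard with
# f_b = 0, written event-by-event rather than step-by-step: foraging
# phases are jumped arithmetically, and each breeding attempt draws its
# failure time directly from the truncated geometric law. Shares no code
# path with the package's step loop.
oracle_season <- function(T, E_i, c, f_f, x, t_r, h) {
  threshold <- E_i + c * x * t_r
  E <- E_i
  t <- 0                       # last completed step
  successes <- 0L
  attempts <- 0L
  last_complete <- 0L
  repeat {
    forage_steps <- ceiling((threshold - E) / f_f)
    if (forage_steps > 0) {
      if (t + forage_steps >= T) break   # season ends while foraging
      E <- E + forage_steps * f_f
      t <- t + forage_steps
    }
    # attempt starts at step t + 1
    attempts <- attempts + 1L
    u <- stats::runif(1)
    q <- (1 - h)^t_r
    if (u < q) k <- t_r                       # success
    else {
      # failure step: inverse-cdf of the geometric truncated to 1..t_r
      k <- 1L
      acc <- h
      v <- stats::runif(1)                    # fresh draw for the tail
      v <- v * (1 - q)                        # conditional on failure
      while (acc < v && k < t_r) {
        k <- k + 1L
        acc <- acc + (1 - h)^(k - 1) * h
      }
    }
    if (t + k > T) {                          # truncated by season end
      t <- T
      break
    }
    t <- t + k
    E <- E - k * c * x
    last_complete <- t
    if (u < q) successes <- successes + 1L
  }
  list(n_successes = successes, fledglings = successes * c,
       n_attempts = attempts,
       excessive_reserve_time = if (last_complete > 0) T - last_complete else T)
}

# Exact distribution of the number of successes for constant hazard,
# f_b = 0 and integer recovery times (requires k*c*x/f_f integral).
# Recursion over attempt start steps with the geometric failure-time pmf.
enumerate_successes <- function(T, c, x, f_f, t_r, h, max_succ = 20) {
  stopifnot((c * x) %% f_f == 0)
  memo <- new.env(parent = emptyenv())
  dist_from <- function(s) {                # s = first breeding step
    if (s > T) return(c(1, numeric(max_succ)))
    key <- as.character(s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- numeric(max_succ + 1)
    m <- T - s + 1                          # steps left in the season
    kmax <- min(t_r, m)
    for (k in seq_len(kmax)) {
      if (k == t_r && m >= t_r) next        # k = t_r failure handled below
      p_k <- (1 - h)^(k - 1) * h
      out <- out + p_k * dist_from(s + k + k * c * x / f_f)
    }
    if (m >= t_r) {
      p_tr <- (1 - h)^(t_r - 1) * h         # failure on the final test
      out <- out + p_tr * dist_from(s + t_r + t_r * c * x / f_f)
      q <- (1 - h)^t_r
      nxt <- q * dist_from(s + t_r + c * x * t_r / f_f)
      out <- out + c(0, nxt[seq_len(max_succ)])   # shift by one success
    } else {
      out[1] <- out[1] + (1 - h)^m          # season ends mid-attempt
    }
    memo[[key]] <- out
    out
  }
  p <- dist_from(c * x * t_r / f_f + 1)
  names(p) <- 0:max_succ
  p
}
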