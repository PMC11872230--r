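# Brute-force transition oracle: searches all sample pairs (i, j) with
# t_j - t_i within the qualifying duration, greedily taking the earliest
# leading edge, resetting the anchor to the counted edge, and alternating
# direction. Independent of the package's extremum-tracking scan.
oracle_luminance_scan <- function(L, times, Q = 0.066, diff_cut = 20,
                                  dark_cut = 160, mc_cut = NULL) {
  res <- data.frame(time = numeric(), direction = numeric())
  start <- 1L; last_dir <- 0
  n <- length(L)
  repeat {
    found <- NULL
    if (start >= n) break
    for (j in (start + 1L):n) {
      best <- NULL
      for (i in start:(j - 1L)) {
        if (j - i > 1L && times[j] - times[i] > Q) next  # adjacent cut always qualifies
        d <- L[j] - L[i]
        dir <- sign(d)
        if (dir == 0 || dir == last_dir) next
        darker <- min(L[i], L[j]); mag <- abs(d)
        ok <- if (darker < dark_cut) mag >= diff_cut
              else if (!is.null(mc_cut)) mag / (L[i] + L[j]) >= mc_cut
              else FALSE
        if (ok && (is.null(best) || mag > best$mag))
          best <- list(dir = dir, mag = mag)
      }
      if (!is.null(best)) { found <- list(j = j, dir = best$dir); break }
    }
    if (is.null(found)) break
    res <- rbind(res, data.frame(time = times[found$j],
                                 direction = found$dir))
    start <- found$j; last_dir <- found$dir
  }
  res
}

# random luminance walk for property tests
random_waveform <- function(n, fps, sd = 25, seed) {
  set.seed(seed)
  L <- pmax(0, 80 + cumsum(rnorm(n, 0, sd)))
  list(L = L, times = (seq_len(n) - 1) / fps)
}

test_env_small <- function() fh_env(192, 108, px_angular_size = 0.1)
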