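# shared fixtures built in code

study_layout <- function() sampling_layout(3, 24, 2, 12)

# a small day layout where exhaustive permutation enumeration is feasible
tiny_layout <- function() sampling_layout(4, 24, 1, 12)

# naive O(M^2) evaluation of y_k = sum_n x_n exp(-i 2 pi k n / M)
brute_dft <- function(x) {
  M <- length(x)
  vapply(0:(M - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(M - 1)) / M)), complex(1))
}

# independent re-implementation of the cyclic score, written step by step
brute_cyclic_score <- function(x, layout, overlap = NULL) {
  M <- layout$points_per_day
  step <- if (is.null(overlap)) 1 else max(1, round(M * (1 - overlap)))
  starts <- seq(1, length(x) - M + 1, by = step)
  vals <- sapply(starts, function(s) {
    seg <- x[s:(s + M - 1)]
    seg <- seg - mean(seg)
    pw <- Mod(brute_dft(seg)[2:(M %/% 2 + 1)])^2
    (pw[1] - min(pw)) / (max(pw) - min(pw))
  })
  mean(vals)
}

# trapezoidal ROC integration as an independent AUC oracle
trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, sapply(thr, function(t) mean(scores[labels] >= t)), 1)
  fpr <- c(0, sapply(thr, function(t) mean(scores[!labels] >= t)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

toy_pwm <- function() pwm_from_consensus("ACGTCA", strength = 0.85)

# all permutations of 1..n as a list (n small)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# a planted motif long enough that a per-site p of 1e-05 is attainable
planted_pwm <- function() pwm_from_consensus("ACGTACGTC", strength = 0.9)
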