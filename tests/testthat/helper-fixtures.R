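# Shared fixture builders. Everything is generated in code at test time.

# A small uniform-HU volume for ROI arithmetic tests.
flat_volume <- function(hu = 40, dims = c(6, 32, 32), spacing = c(3, 2, 2)) {
  ct_volume(array(hu, dim = dims), spacing_mm = spacing)
}

# Default phantom + manifest at a given density/noise/seed.
make_phantom <- function(density = 130, noise = 0, seed = 1, ...) {
  generate_phantom_volume(phantom_spec(
    true_density_mgcc = density, noise_sd_hu = noise, seed = seed, ...))
}

# Independent pair-counting AUC oracle (positive = lower score).
auc_oracle <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (x in sp) tot <- tot + sum(x < sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden search oracle: best attained threshold for "score <= c",
# ties broken toward higher specificity, then smaller c.
youden_oracle <- function(scores, positive) {
  best <- list(j = -Inf, spec = -Inf, c = Inf)
  for (c in sort(unique(scores))) {
    sens <- mean(scores[positive] <= c)
    spec <- mean(scores[!positive] > c)
    j <- sens + spec - 1
    better <- j > best$j + 1e-12 ||
      (abs(j - best$j) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
            (abs(spec - best$spec) <= 1e-12 && c < best$c)))
    if (better) best <- list(j = j, spec = spec, c = c, sens = sens)
  }
  best
}

# Closed-form OLS/Pearson from raw sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = sxy / sqrt(sxx * syy))
}

# A valid cohort CSV on disk; returns the path.
write_cohort_fixture <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
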