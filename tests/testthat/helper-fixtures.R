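# Shared fixtures: small ground-truth kinetics and an independent quadrature
# oracle for the EMG (numeric convolution of a Gaussian with a one-sided
# exponential kernel).

default_times <- function() seq(0, 89, by = 1)

emg_truth <- function(params = c(150, 25, 5, 10), baseline = 15) {
  truth_params("EMG", params, baseline_level = baseline, arrival_time = 0)
}

gvf_truth <- function(peak = 150, shape = 3, ttp = 18, baseline = 15, arrival = 7) {
  b <- ttp / shape
  A <- peak / (ttp^shape * exp(-shape))
  truth_params("GVF", c(A, shape, b), baseline_level = baseline,
               arrival_time = arrival)
}

# EMG quadrature oracle: (a/d) * int_0^S exp(-s/d) exp(-(t-s-b)^2/(2 c^2)) ds.
# The integrand peaks near s = t - b; the domain is split there so adaptive
# quadrature cannot miss a narrow Gaussian bump.
emg_conv_oracle <- function(params, t) {
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  upper <- max(abs(t)) + abs(b) + 60 * d + 60 * cc
  vapply(t, function(tt) {
    f <- function(s) exp(-s / d - (tt - s - b)^2 / (2 * cc^2))
    cuts <- sort(unique(pmin(pmax(c(0, tt - b - 8 * cc, tt - b, tt - b + 8 * cc,
                                    upper), 0), upper)))
    total <- 0
    for (i in seq_len(length(cuts) - 1)) {
      if (cuts[i + 1] > cuts[i]) {
        total <- total + stats::integrate(f, cuts[i], cuts[i + 1],
                                          rel.tol = 1e-11,
                                          subdivisions = 2000L)$value
      }
    }
    (a / d) * total
  }, numeric(1))
}

# random EMG parameter draws spanning the generator ranges
random_emg_params <- function() {
  c(runif(1, 40, 200), runif(1, 15, 45), runif(1, 2, 8), runif(1, 5, 20))
}

random_gvf_params <- function() {
  shape <- runif(1, 1.5, 5)
  ttp <- runif(1, 8, 40)
  peak <- runif(1, 30, 200)
  c(peak / (ttp^shape * exp(-shape)), shape, ttp / shape)
}

# tiny four-patient cohort (2 per class) for fast structural tests
tiny_cohort <- function(seed = 5) {
  generate_cohort(4, 0.5, "well_separated", seed = seed,
                  voxels_benign = 5, voxels_malignant = 8,
                  frame_shape = c(8, 8))
}

patient_label_map <- function(cohort) {
  stats::setNames(vapply(cohort$patients, `[[`, "", "class_label"),
                  vapply(cohort$patients, `[[`, "", "patient_id"))
}
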