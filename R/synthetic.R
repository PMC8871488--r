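# Synthetic CEUS cohort generator with known ground-truth kinetics.
#
# The generator emulates what the pipeline consumes: per-voxel enhancement
# curves following an EMG or gamma variate bolus model, a flat pre-contrast
# baseline, additive zero-mean Gaussian noise clipped at zero, patient-level
# heterogeneity of the kinetic parameters, and a malignant class with
# faster/stronger enhancement than the benign class.

#' Ground-truth kinetics for one voxel
#'
#' @param model_kind `"EMG"` or `"GVF"`.
#' @param params numeric `(a,b,c,d)` (EMG) or `(A,a,b)` (GVF); positive
#'   except the EMG location `b`, which may be any real.
#' @param baseline_level pre-contrast intensity (arbitrary units, `>= 0`).
#' @param arrival_time bolus arrival (s, `>= 0`). EMG truths use 0 and encode
#'   the onset in `b` (a time shift of the EMG is exactly absorbed by `b`).
#' @return an object of class `truth_params`.
#' @export
truth_params <- function(model_kind = c("EMG", "GVF"), params,
                         baseline_level = 0, arrival_time = 0) {
  model_kind <- match.arg(model_kind)
  params <- if (model_kind == "EMG") check_emg_params(params) else check_gvf_params(params)
  if (model_kind == "EMG" && (params[1] <= 0 || params[4] <= 0)) {
    stop("EMG truth requires a > 0 and d > 0", call. = FALSE)
  }
  if (baseline_level < 0) stop("baseline_level must be >= 0", call. = FALSE)
  if (arrival_time < 0) stop("arrival_time must be >= 0", call. = FALSE)
  structure(list(model_kind = model_kind, params = unname(params),
                 baseline_level = baseline_level, arrival_time = arrival_time),
            class = "truth_params")
}

#' Simulate one voxel's enhancement curve
#'
#' `intensity(t) = baseline_level + model(t - arrival_time)` (model value 0
#' before arrival) plus independent zero-mean Gaussian noise of SD
#' `noise_sd`, clipped at 0. Uses the current R random-number state; set a
#' seed for reproducibility.
#'
#' @param truth a [truth_params()].
#' @param times strictly increasing acquisition times (s).
#' @param noise_sd noise standard deviation (intensity units, `>= 0`).
#' @return a [perfusion_curve()] (with `t0_index` unset).
#' @export
generate_voxel_curve <- function(truth, times, noise_sd = 0) {
  stopifnot(inherits(truth, "truth_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (truth$arrival_time >= times[length(times)]) {
    stop("arrival_time must precede the last frame time", call. = FALSE)
  }
  tl <- times - truth$arrival_time
  v <- numeric(length(times))
  on <- tl >= 0
  v[on] <- model_component(truth$model_kind, truth$params, tl[on])
  y <- truth$baseline_level + v
  if (noise_sd > 0) y <- pmax(y + stats::rnorm(length(y), 0, noise_sd), 0)
  perfusion_curve(times, y)
}

#' Scenario constants for the cohort generator
#'
#' Versioned class-conditional parameter distributions. Kinetic parameters
#' are drawn per patient from the class distribution (patient-level random
#' effect), then jittered per voxel. Malignant lesions enhance faster
#' (shorter time to peak) and stronger (larger amplitude, hence larger
#' wash-in and AUC) than benign ones.
#'
#' EMG rows give the amplitude `a` (mean, patient SD), location `b` range
#' (s), width `c` range (s) and decay `d` range (s). GVF rows give the peak
#' intensity (mean, patient SD), shape `a` range and time-to-peak (`a*b`)
#' range (s). Intensities are nominal 0-255 arbitrary units over a 0-89 s
#' loop at 1 s resolution with baseline level 15.
#'
#' @param scenario `"well_separated"`, `"overlapping"` or `"noisy"`.
#' @return a list of scenario constants (see source for the full table).
#' @export
scenario_config <- function(scenario = c("well_separated", "overlapping", "noisy")) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario,
    times = seq(0, 89, by = 1),
    baseline_level = 15,
    voxel_jitter = 0.05,       # per-voxel lognormal SD on all positive params
    arrival_range = c(5, 10),  # GVF per-patient arrival (s), snapped to frames
    emg = list(
      malignant = list(a = c(150, 15), b = c(22, 30), c = c(4, 6), d = c(8, 12)),
      benign    = list(a = c(60, 8),  b = c(36, 46), c = c(6, 8), d = c(14, 20))),
    gvf = list(
      malignant = list(peak = c(150, 15), shape = c(2, 3.5), ttp = c(14, 22)),
      benign    = list(peak = c(60, 8),  shape = c(2, 3.5), ttp = c(30, 42))),
    noise_sd = 4)
  if (scenario == "overlapping") {
    base$emg <- list(
      malignant = list(a = c(110, 25), b = c(26, 36), c = c(5, 8), d = c(10, 16)),
      benign    = list(a = c(85, 25),  b = c(30, 42), c = c(6, 9), d = c(12, 18)))
    base$gvf <- list(
      malignant = list(peak = c(110, 25), shape = c(2, 3.5), ttp = c(18, 30)),
      benign    = list(peak = c(85, 25),  shape = c(2, 3.5), ttp = c(24, 38)))
    base$noise_sd <- 10
  } else if (scenario == "noisy") {
    base$noise_sd <- 20
  }
  base
}

draw_patient_truth <- function(cfg, model_kind, class_label) {
  if (model_kind == "EMG") {
    d <- cfg$emg[[class_label]]
    list(a = max(stats::rnorm(1, d$a[1], d$a[2]), 10),
         b = stats::runif(1, d$b[1], d$b[2]),
         c = stats::runif(1, d$c[1], d$c[2]),
         d = stats::runif(1, d$d[1], d$d[2]))
  } else {
    d <- cfg$gvf[[class_label]]
    shape <- stats::runif(1, d$shape[1], d$shape[2])
    ttp <- stats::runif(1, d$ttp[1], d$ttp[2])
    peak <- max(stats::rnorm(1, d$peak[1], d$peak[2]), 10)
    list(peak = peak, shape = shape, ttp = ttp)
  }
}

voxel_truth_from_patient <- function(cfg, model_kind, pt, arrival) {
  j <- function(x) x * exp(stats::rnorm(1, 0, cfg$voxel_jitter))
  if (model_kind == "EMG") {
    truth_params("EMG", c(j(pt$a), j(pt$b), j(pt$c), j(pt$d)),
                 baseline_level = cfg$baseline_level, arrival_time = 0)
  } else {
    shape <- j(pt$shape); ttp <- j(pt$ttp); peak <- j(pt$peak)
    b <- ttp / shape
    A <- peak / (ttp^shape * exp(-shape))
    truth_params("GVF", c(A, shape, b),
                 baseline_level = cfg$baseline_level, arrival_time = arrival)
  }
}

# circular lesion mask of approximately n_voxels voxels centered in an
# h x w frame
disc_mask <- function(h, w, n_voxels) {
  r <- sqrt(n_voxels / pi)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  m <- outer(seq_len(h), seq_len(w), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
  m
}

#' Generate a synthetic patient cohort
#'
#' Builds `n_patients` cine loops with lesion masks and per-voxel
#' ground-truth kinetics. Malignant patients draw kinetics from a
#' fast/strong class distribution, benign from a slow/weak one (see
#' [scenario_config()]); a patient-level random effect sits on top of the
#' class means and a small lognormal jitter on top of that per voxel.
#' Malignant lesions are larger by default so that the voxel-level class
#' imbalance is about 3:1 malignant:benign at a 0.56 malignant patient
#' fraction. Deterministic given `seed`.
#'
#' @param n_patients number of patients (`>= 2`).
#' @param malignant_fraction fraction of malignant patients, in (0, 1)
#'   (default 0.56; at least one patient of each class is always produced).
#' @param scenario one of `"well_separated"`, `"overlapping"`, `"noisy"`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param model_kind ground-truth model for every voxel.
#' @param voxels_benign,voxels_malignant approximate lesion sizes in voxels.
#' @param frame_shape `(H, W)` of the generated frames.
#' @return an object of class `synthetic_cohort`: `patients` (list of
#'   `patient_id`, `class_label`, `loop`, `mask`, `truth` — a list of
#'   [truth_params()] named `"row,col"`), `scenario_name`, `seed`,
#'   `model_kind`, `config`.
#' @export
generate_cohort <- function(n_patients, malignant_fraction = 0.56,
                            scenario = c("well_separated", "overlapping", "noisy"),
                            seed = 1, model_kind = c("EMG", "GVF"),
                            voxels_benign = 50, voxels_malignant = 150,
                            frame_shape = c(24, 24)) {
  scenario <- match.arg(scenario)
  model_kind <- match.arg(model_kind)
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (malignant_fraction <= 0 || malignant_fraction >= 1) {
    stop("malignant_fraction must be in (0, 1)", call. = FALSE)
  }
  cfg <- scenario_config(scenario)
  n_mal <- min(max(round(n_patients * malignant_fraction), 1L), n_patients - 1L)
  labels <- c(rep("malignant", n_mal), rep("benign", n_patients - n_mal))
  h <- frame_shape[1]; w <- frame_shape[2]
  tt <- cfg$times
  nt <- length(tt)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    lab <- labels[i]
    pid <- sprintf("P%02d", i)
    nv <- if (lab == "malignant") voxels_malignant else voxels_benign
    m <- disc_mask(h, w, nv)
    pt <- draw_patient_truth(cfg, model_kind, lab)
    arrival <- if (model_kind == "GVF") {
      tt[which.min(abs(tt - stats::runif(1, cfg$arrival_range[1], cfg$arrival_range[2])))]
    } else 0
    frames <- array(0, dim = c(nt, h, w))
    # background: baseline + noise only
    frames[] <- pmax(cfg$baseline_level +
                       stats::rnorm(nt * h * w, 0, cfg$noise_sd), 0)
    idx <- which(m, arr.ind = TRUE)
    truth <- vector("list", nrow(idx))
    names(truth) <- paste(idx[, 1], idx[, 2], sep = ",")
    for (k in seq_len(nrow(idx))) {
      tr <- voxel_truth_from_patient(cfg, model_kind, pt, arrival)
      cur <- generate_voxel_curve(tr, tt, cfg$noise_sd)
      frames[, idx[k, 1], idx[k, 2]] <- cur$intensities
      truth[[k]] <- tr
    }
    patients[[i]] <- list(patient_id = pid, class_label = lab,
                          loop = cine_loop(frames, tt, "CEUS"),
                          mask = roi_mask(m, pid, lab),
                          truth = truth)
  }
  structure(list(patients = patients, scenario_name = scenario, seed = seed,
                 model_kind = model_kind, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labs <- vapply(x$patients, `[[`, "", "class_label")
  nv <- vapply(x$patients, function(p) sum(p$mask$mask), 0L)
  cat(sprintf("<synthetic_cohort> %s/%s: %d patients (%d malignant, %d benign), %d lesion voxels, seed %d\n",
              x$scenario_name, x$model_kind, length(labs),
              sum(labs == "malignant"), sum(labs == "benign"), sum(nv), x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Persists each patient's loop as a multi-frame grayscale TIFF and the mask
#' as a PNG, together with a CSV manifest (patient_id, label, file paths,
#' seed) and a JSON file of per-voxel ground-truth parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$patients, function(p) {
    loop_file <- file.path(dir, paste0(p$patient_id, "_loop.tif"))
    mask_file <- file.path(dir, paste0(p$patient_id, "_mask.png"))
    write_cineloop_tiff(p$loop, loop_file)
    png::writePNG(p$mask$mask * 1, mask_file)
    data.frame(patient_id = p$patient_id, class_label = p$class_label,
               loop_file = basename(loop_file), mask_file = basename(mask_file),
               seed = cohort$seed,
               times_s = paste(p$loop$times, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- lapply(cohort$patients, function(p) {
    lapply(p$truth, function(tr) {
      list(model_kind = tr$model_kind, params = tr$params,
           baseline_level = tr$baseline_level, arrival_time = tr$arrival_time)
    })
  })
  names(truth) <- vapply(cohort$patients, `[[`, "", "patient_id")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
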