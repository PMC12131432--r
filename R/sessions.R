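# Cold-challenge session simulation and cohort generation.
#
# Rewarming after the cold challenge is modelled as mono-exponential
# recovery towards a subject-specific ceiling: with basal value b, drop
# fraction d, recovery rate r (per minute) and ceiling fraction c,
#   value(t) = b * (c - (c - (1 - d)) * exp(-r * t)),   t = minutes post
# immersion, and value(basal) = b. Gaussian noise is added independently
# per finger and timepoint on the score / temperature scale. Patients (RP)
# differ from healthy controls (HC) in basal level, drop, recovery rate and
# ceiling; the colder season acts as an additive shift on basal values.

.finger_cols <- c(paste0("left_", c("index", "middle", "ring", "pinky")),
                  paste0("right_", c("index", "middle", "ring", "pinky")))

# Population-level defaults per group, on the ARTIX and thermal scales.
# Basal means refer to the warmer season (May-July); the September-December
# season subtracts `season_offset`.
.population_defaults <- list(
  RP = list(
    basal_redness = c(mean = 358, sd = 20),
    drop_fraction = c(mean = 0.10, sd = 0.02),
    recovery_rate = c(mean = 0.25, sd = 0.05),
    recovery_ceiling_fraction = c(mean = 1.015, sd = 0.02),
    basal_temp_C = c(mean = 28.5, sd = 2.0),
    thermal_drop_fraction = c(mean = 0.18, sd = 0.03),
    thermal_recovery_rate = c(mean = 0.25, sd = 0.05),
    thermal_ceiling_fraction = c(mean = 1.00, sd = 0.05)
  ),
  HC = list(
    basal_redness = c(mean = 390, sd = 20),
    drop_fraction = c(mean = 0.07, sd = 0.02),
    recovery_rate = c(mean = 0.45, sd = 0.08),
    recovery_ceiling_fraction = c(mean = 1.02, sd = 0.02),
    basal_temp_C = c(mean = 32.0, sd = 2.0),
    thermal_drop_fraction = c(mean = 0.20, sd = 0.03),
    thermal_recovery_rate = c(mean = 0.40, sd = 0.06),
    thermal_ceiling_fraction = c(mean = 1.02, sd = 0.05)
  )
)
.season_offset <- c(artix = -25, thermal = -2)
.default_noise <- c(artix = 6, thermal = 0.5)

#' Subject-level cold-challenge parameters
#'
#' Constructs the generative parameters of one subject's session. Defaults
#' are the population means of the subject's group (`RP` patients have a
#' lower basal level, larger immersion drop, slower recovery and lower
#' recovery ceiling than `HC`); the September--December season subtracts a
#' fixed offset from basal values (25 score units, 2 degC).
#'
#' @param group `"RP"` or `"HC"`.
#' @param season `"MayJul"` or `"SepDec"`.
#' @param basal_redness Basal ARTIX-scale value (score units).
#' @param drop_fraction Fractional drop at immersion, in \[0, 1\].
#' @param recovery_rate Rewarming rate, per minute.
#' @param recovery_ceiling_fraction Recovery asymptote as a fraction of
#'   basal.
#' @param basal_temp_C Basal temperature, degC.
#' @param thermal_drop_fraction,thermal_recovery_rate,thermal_ceiling_fraction
#'   Thermal analogues of the score parameters.
#' @param noise_sd Per-finger, per-timepoint Gaussian noise on the score
#'   scale.
#' @param thermal_noise_sd Same, on the temperature scale (degC).
#' @param covariates Named list of clinical covariates (sex, age,
#'   vasoactive_therapy, ACA, NVC_pattern, skin_subset, DU_history).
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(group = c("RP", "HC"),
                           season = c("MayJul", "SepDec"),
                           basal_redness = NULL,
                           drop_fraction = NULL,
                           recovery_rate = NULL,
                           recovery_ceiling_fraction = NULL,
                           basal_temp_C = NULL,
                           thermal_drop_fraction = NULL,
                           thermal_recovery_rate = NULL,
                           thermal_ceiling_fraction = NULL,
                           noise_sd = .default_noise[["artix"]],
                           thermal_noise_sd = .default_noise[["thermal"]],
                           covariates = list()) {
  group <- match.arg(group)
  season <- match.arg(season)
  pop <- .population_defaults[[group]]
  soff <- if (season == "SepDec") .season_offset else c(artix = 0, thermal = 0)
  p <- list(
    group = group, season = season,
    basal_redness = basal_redness %||%
      (pop$basal_redness[["mean"]] + soff[["artix"]]),
    drop_fraction = drop_fraction %||% pop$drop_fraction[["mean"]],
    recovery_rate = recovery_rate %||% pop$recovery_rate[["mean"]],
    recovery_ceiling_fraction = recovery_ceiling_fraction %||%
      pop$recovery_ceiling_fraction[["mean"]],
    basal_temp_C = basal_temp_C %||%
      (pop$basal_temp_C[["mean"]] + soff[["thermal"]]),
    thermal_drop_fraction = thermal_drop_fraction %||%
      pop$thermal_drop_fraction[["mean"]],
    thermal_recovery_rate = thermal_recovery_rate %||%
      pop$thermal_recovery_rate[["mean"]],
    thermal_ceiling_fraction = thermal_ceiling_fraction %||%
      pop$thermal_ceiling_fraction[["mean"]],
    noise_sd = noise_sd, thermal_noise_sd = thermal_noise_sd,
    covariates = covariates
  )
  for (fld in c("drop_fraction", "thermal_drop_fraction")) {
    if (p[[fld]] < 0 || p[[fld]] > 1) {
      artix_error("artix_bad_parameter",
                  sprintf("%s must lie in [0, 1]", fld))
    }
  }
  structure(p, class = "subject_params")
}

#' Draw one subject's parameters from the population model
#'
#' Samples subject-level parameters around the group/season population
#' means, including clinical covariates with marginals resembling a
#' secondary-RP-enriched clinic cohort, and additive covariate effects on
#' the basal values (vasoactive therapy and ACA positivity raise the basal
#' score; male sex raises both scales; late capillaroscopic pattern and
#' diffuse skin subset lower the score).
#'
#' @param group `"RP"` or `"HC"`.
#' @param season `"MayJul"` or `"SepDec"`.
#' @param seed Integer seed.
#' @return A `subject_params` object.
#' @export
sample_subject_params <- function(group, season, seed) {
  pop <- .population_defaults[[group]]
  with_seed(seed, {
    covs <- list(
      sex = sample(c("F", "M"), 1L, prob = c(0.9, 0.1)),
      age = round(clamp(stats::rnorm(1, if (group == "RP") 52.2 else 45.7,
                                     if (group == "RP") 16.7 else 13.5), 18, 85)),
      vasoactive_therapy = group == "RP" && stats::runif(1) < 0.555,
      ACA = group == "RP" && stats::runif(1) < 0.422,
      NVC_pattern = if (group == "RP")
        sample(c("early", "active", "late", "non-specific", "none"), 1L,
               prob = c(0.13, 0.07, 0.11, 0.16, 0.53)) else "none",
      skin_subset = if (group == "RP")
        sample(c("none", "lcSSc", "dcSSc"), 1L, prob = c(0.58, 0.31, 0.11))
        else "none",
      DU_history = group == "RP" && stats::runif(1) < 0.155
    )
    rn <- function(par) stats::rnorm(1, par[["mean"]], par[["sd"]])
    # additive covariate effects on the basal score, centred within group so
    # the expected basal equals the population mean and the group contrast
    # stays exactly the difference of the population defaults
    basal_shift <- 14 * isTRUE(covs$vasoactive_therapy) +
      20 * isTRUE(covs$ACA) +
      13 * (covs$sex == "M") -
      12 * (covs$NVC_pattern == "late") -
      15 * (covs$skin_subset == "dcSSc")
    basal_shift <- basal_shift - if (group == "RP") {
      14 * 0.555 + 20 * 0.422 + 13 * 0.1 - 12 * 0.11 - 15 * 0.11
    } else 13 * 0.1
    temp_shift <- 3 * (covs$sex == "M") - 3 * 0.1
    soff <- if (season == "SepDec") .season_offset else c(artix = 0, thermal = 0)
    subject_params(
      group = group, season = season,
      basal_redness = rn(pop$basal_redness) + soff[["artix"]] + basal_shift,
      drop_fraction = clamp(rn(pop$drop_fraction), 0.01, 0.5),
      recovery_rate = max(rn(pop$recovery_rate), 0.05),
      recovery_ceiling_fraction = rn(pop$recovery_ceiling_fraction),
      basal_temp_C = rn(pop$basal_temp_C) + soff[["thermal"]] + temp_shift,
      thermal_drop_fraction = clamp(rn(pop$thermal_drop_fraction), 0.01, 0.5),
      thermal_recovery_rate = max(rn(pop$thermal_recovery_rate), 0.02),
      thermal_ceiling_fraction = rn(pop$thermal_ceiling_fraction),
      covariates = covs
    )
  })
}

#' Noise-free expected session trajectory
#'
#' Evaluates the generative rewarming model of [simulate_challenge_session()]
#' without noise, returning the expected ARTIX and thermal value at each
#' scheduled timepoint.
#'
#' @param params A `subject_params`.
#' @param schedule A [protocol_schedule()].
#' @return List with named numeric vectors `artix` and `thermal`.
#' @export
expected_session_values <- function(params, schedule = protocol_schedule()) {
  stopifnot(inherits(params, "subject_params"))
  traj <- function(basal, drop, rate, ceiling) {
    vapply(schedule$minutes, function(t) {
      if (is.na(t)) basal
      else basal * (ceiling - (ceiling - (1 - drop)) * exp(-rate * t))
    }, numeric(1))
  }
  artix <- traj(params$basal_redness, params$drop_fraction,
                params$recovery_rate, params$recovery_ceiling_fraction)
  thermal <- traj(params$basal_temp_C, params$thermal_drop_fraction,
                  params$thermal_recovery_rate, params$thermal_ceiling_fraction)
  names(artix) <- names(thermal) <- schedule$label
  list(artix = artix, thermal = thermal)
}

#' Simulate one cold-challenge session
#'
#' Draws per-finger redness and temperature values for the eight scoring
#' digits (second to fifth finger, both hands) at each scheduled timepoint:
#' the expected trajectory of the rewarming model plus i.i.d. Gaussian
#' noise. In fast mode (default) the per-finger values are emitted
#' directly; with `render = TRUE` each timepoint additionally carries a
#' rendered left- and right-hand image whose digit colours encode the
#' simulated redness (red channel = redness / 2, so the default score
#' formula recovers the simulated value), plus a small thermal frame in
#' degC.
#'
#' @param params A [subject_params()].
#' @param schedule A [protocol_schedule()].
#' @param seed Integer seed.
#' @param render Render per-timepoint hand images and thermal frames.
#' @param image_size Frame side for rendered images.
#' @param subject_id Identifier stored in the session.
#' @return An object of class `challenge_session` with named 7-vectors
#'   `artix` and `thermal`, per-finger matrices, and (when rendered)
#'   `images` / `thermal_frames` lists indexed by timepoint label.
#' @export
simulate_challenge_session <- function(params,
                                       schedule = protocol_schedule(),
                                       seed = 1L,
                                       render = FALSE,
                                       image_size = 192L,
                                       subject_id = "S001") {
  stopifnot(inherits(params, "subject_params"))
  assert_schedule(schedule)
  exp_vals <- expected_session_values(params, schedule)
  nt <- nrow(schedule)

  noise <- with_seed(seed, list(
    artix = matrix(stats::rnorm(nt * 8L, 0, params$noise_sd), nt, 8L),
    thermal = matrix(stats::rnorm(nt * 8L, 0, params$thermal_noise_sd), nt, 8L)
  ))
  pf_artix <- sweep(noise$artix, 1L, exp_vals$artix, `+`)
  pf_thermal <- sweep(noise$thermal, 1L, exp_vals$thermal, `+`)
  dimnames(pf_artix) <- dimnames(pf_thermal) <-
    list(schedule$label, .finger_cols)

  session <- structure(list(
    subject_id = subject_id,
    group = params$group, season = params$season,
    covariates = params$covariates,
    schedule = schedule,
    artix = rowMeans(pf_artix),
    thermal = rowMeans(pf_thermal),
    per_finger_artix = pf_artix,
    per_finger_thermal = pf_thermal,
    images = NULL, thermal_frames = NULL,
    params = params
  ), class = "challenge_session")

  if (render) {
    session$images <- vector("list", nt)
    session$thermal_frames <- vector("list", nt)
    names(session$images) <- names(session$thermal_frames) <- schedule$label
    for (ti in seq_len(nt)) {
      hands <- list()
      for (h in c("left", "right")) {
        red <- pf_artix[ti, paste0(h, "_", c("index", "middle", "ring", "pinky"))]
        frgb <- rbind(c(clamp(exp_vals$artix[ti] / 2, 0, 255), 135, 125),
                      cbind(clamp(red / 2, 0, 255), 135, 125))
        spec <- hand_spec(image_size = image_size, handedness = h,
                          finger_rgb = frgb, noise_sd = 2,
                          seed = child_seed(seed, 977L * ti + (h == "left")))
        hands[[h]] <- generate_synthetic_hand(spec)
      }
      session$images[[ti]] <- hands
      session$thermal_frames[[ti]] <- render_thermal_frame(
        pf_thermal[ti, ], seed = child_seed(seed, 1667L * ti))
    }
  }
  session
}

#' Render a synthetic thermal frame
#'
#' Produces a small temperature matrix (degC) containing two hand
#' silhouettes whose digit pixels carry the given per-finger temperatures,
#' on a room-temperature background. Used as a stand-in for radiometric
#' thermal exports.
#'
#' @param finger_temps Named length-8 vector (left/right x index..pinky).
#' @param size Frame side in pixels per hand.
#' @param background_C Background temperature.
#' @param seed Seed for the small additive sensor noise.
#' @return H x (2W) numeric matrix of degC.
#' @export
render_thermal_frame <- function(finger_temps, size = 128L,
                                 background_C = 20, seed = 1L) {
  stopifnot(length(finger_temps) == 8L)
  halves <- lapply(c("left", "right"), function(h) {
    hand <- generate_synthetic_hand(hand_spec(image_size = size,
                                              handedness = h, noise_sd = 0,
                                              seed = 1L))
    temps <- finger_temps[paste0(h, "_", c("index", "middle", "ring", "pinky"))]
    fr <- matrix(background_C, size, size)
    fr[hand$mask] <- mean(temps) - 1  # palm slightly cooler than digits
    fr[hand$digit_truth == 1L] <- mean(temps) - 0.5
    for (i in 2:5) fr[hand$digit_truth == i] <- temps[i - 1L]
    fr
  })
  fr <- cbind(halves[[1]], halves[[2]])
  fr + with_seed(seed, matrix(stats::rnorm(length(fr), 0, 0.05),
                              nrow(fr), ncol(fr)))
}

#' Generate a synthetic cohort of cold-challenge sessions
#'
#' Draws `n_rp` patients and `n_hc` healthy controls with sampled clinical
#' covariates and subject-level rewarming parameters, simulates each
#' subject's seven-timepoint session, and assembles the assessment manifest
#' (one row per subject and timepoint). When `out_dir` is given, the
#' manifest is written as `manifest.csv` along with per-timepoint thermal
#' frames (headerless CSV matrices of degC) and, with `render = TRUE`,
#' per-timepoint hand photographs (PNG, both hands side by side) plus the
#' ground-truth landmark table `landmarks.csv` in combined-frame pixel
#' coordinates.
#'
#' @param n_rp,n_hc Numbers of patients and controls (>= 1).
#' @param seed Integer master seed; everything downstream is derived from
#'   it.
#' @param out_dir Optional output directory.
#' @param render Render and (when `out_dir` is set) write per-timepoint
#'   hand images.
#' @param write_thermal Write per-timepoint thermal frames when `out_dir`
#'   is set.
#' @param image_size Frame side for rendered images.
#' @return An object of class `artix_cohort`: list with `manifest` (data
#'   frame) and `sessions` (list of `challenge_session`).
#' @export
generate_cohort <- function(n_rp, n_hc, seed = 1L, out_dir = NULL,
                            render = FALSE, write_thermal = FALSE,
                            image_size = 192L) {
  stopifnot(n_rp >= 1L, n_hc >= 1L)
  schedule <- protocol_schedule()
  groups <- c(rep("RP", n_rp), rep("HC", n_hc))
  ids <- c(sprintf("RP%03d", seq_len(n_rp)), sprintf("HC%03d", seq_len(n_hc)))
  seasons <- with_seed(child_seed(seed, 1L),
                       sample(c("MayJul", "SepDec"), length(ids), replace = TRUE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (render) dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    if (write_thermal) dir.create(file.path(out_dir, "thermal"), showWarnings = FALSE)
  }

  sessions <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  lm_rows <- list()
  for (i in seq_along(ids)) {
    params <- sample_subject_params(groups[i], seasons[i],
                                    seed = child_seed(seed, 2L * i))
    sess <- simulate_challenge_session(params, schedule,
                                       seed = child_seed(seed, 2L * i + 1L),
                                       render = render,
                                       image_size = image_size,
                                       subject_id = ids[i])
    need_frames <- write_thermal && !is.null(out_dir) && !render
    if (need_frames) {
      sess$thermal_frames <- lapply(seq_len(nrow(schedule)), function(ti)
        render_thermal_frame(sess$per_finger_thermal[ti, ],
                             seed = child_seed(seed, 31L * i + ti)))
      names(sess$thermal_frames) <- schedule$label
    }
    img_paths <- rep(NA_character_, nrow(schedule))
    th_paths <- rep(NA_character_, nrow(schedule))
    if (!is.null(out_dir)) {
      for (ti in seq_len(nrow(schedule))) {
        tp <- schedule$label[ti]
        if (render) {
          img_paths[ti] <- file.path("images", sprintf("%s_%s.png", ids[i], tp))
          img <- sess$images[[ti]]
          combined <- array(0, dim = c(image_size, 2L * image_size, 3L))
          combined[, seq_len(image_size), ] <- img$left$image
          combined[, image_size + seq_len(image_size), ] <- img$right$image
          png::writePNG(combined / 255, file.path(out_dir, img_paths[ti]))
          # ground-truth landmarks in combined-frame coordinates
          for (h in c("left", "right")) {
            lm <- img[[h]]$landmarks
            lm_rows[[length(lm_rows) + 1L]] <- data.frame(
              subject_id = ids[i], timepoint_label = tp, hand = h,
              point_index = lm$point_index, point_name = lm$point_name,
              x = lm$x + if (h == "right") image_size else 0, y = lm$y,
              normalized_flag = FALSE, stringsAsFactors = FALSE)
          }
        }
        if (write_thermal) {
          th_paths[ti] <- file.path("thermal", sprintf("%s_%s.csv", ids[i], tp))
          utils::write.table(round(sess$thermal_frames[[ti]], 3),
                             file.path(out_dir, th_paths[ti]),
                             row.names = FALSE, col.names = FALSE, sep = ",")
        }
      }
    }
    covs <- params$covariates
    rows[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], season = seasons[i],
      sex = covs$sex, age = covs$age,
      vasoactive_therapy = covs$vasoactive_therapy, ACA = covs$ACA,
      NVC_pattern = covs$NVC_pattern, skin_subset = covs$skin_subset,
      DU_history = covs$DU_history,
      timepoint_label = schedule$label, minutes = schedule$minutes,
      image_path = img_paths, thermal_path = th_paths,
      stringsAsFactors = FALSE
    )
    sessions[[i]] <- sess
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    if (length(lm_rows) > 0L) {
      utils::write.csv(do.call(rbind, lm_rows),
                       file.path(out_dir, "landmarks.csv"), row.names = FALSE)
    }
  }
  names(sessions) <- ids
  structure(list(manifest = manifest, sessions = sessions),
            class = "artix_cohort")
}
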