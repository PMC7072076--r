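# Synthetic cytometry generator. Emulates what the assay measures --
# scatter-defined leukocyte populations, CD16/CD62L subset structure,
# Poisson bioparticle uptake, pH-dependent pHrodo fluorescence, and the two
# patient groups' opposite temporal acidification trajectories -- and
# returns per-event ground truth for every pipeline stage.

#' Generator configuration
#'
#' All study conditions are encoded here: population geometry in scatter
#' space, subset proportions and marker intensities, the uptake-rate
#' surface over incubation time and temperature, the pH response of the
#' pH-sensitive fluorochrome, and the group-by-day phagosomal pH
#' trajectory table (infection-group acidification elevated on days 0-3
#' then low-normal from day 6 on; no-infection group normal early and
#' elevated on days 6-15).
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_events Events per simulated sample.
#' @param populations Data frame of scatter populations (name, fraction,
#'   FSC/SSC mean and SD). Fractions must sum to 1.
#' @param eosinophil_frac Fraction of granulocytes that are CD16-negative
#'   eosinophils.
#' @param subsets Data frame of neutrophil subsets (name, fraction and
#'   log-normal CD16/CD62L parameters). Fractions must sum to 1.
#' @param marker_params Log-normal CD16/CD62L parameters for
#'   non-neutrophil populations and eosinophils.
#' @param lambda60 Expected bioparticle count per neutrophil after 60 min
#'   at the reference temperature.
#' @param tau_t Uptake saturation time constant (minutes).
#' @param ref_temp,q10 Temperature scaling of uptake:
#'   `lambda * q10^((T - ref_temp)/10)`, non-decreasing in T.
#' @param brightness_meanlog,brightness_sdlog Per-particle PF520
#'   brightness (log-normal, arbitrary units).
#' @param phrodo_scale Overall pHrodo gain relative to PF520.
#' @param ph_mid,ph_slope Logistic pH response of the pH-sensitive dye:
#'   `f(pH) = 1 / (1 + exp((pH - ph_mid)/ph_slope))`, strictly decreasing
#'   in pH (brighter at low pH).
#' @param ph_start Phagosomal pH at ingestion.
#' @param tau_ph Acidification time constant (minutes):
#'   `pH(t) = ph_start - (ph_start - ph_end) * (1 - exp(-t/tau_ph))`.
#' @param ph_end_table Data frame (group, day, ph_end): the steady-state
#'   phagosomal pH per group and study day that encodes the two groups'
#'   trajectories.
#' @param subset_ph_offset Named additive pH-end offsets per neutrophil
#'   subset (immature banded cells acidify best).
#' @param patient_ph_sd,day_ph_sd Between-patient and within-patient
#'   day-to-day SD of the pH end point.
#' @param autofluor_meanlog,autofluor_sdlog Log-normal autofluorescence
#'   background on PHRODO/PF520 for cells with no ingested particle.
#' @param noise_sdlog Multiplicative log-normal measurement noise applied
#'   per cell and channel.
#' @return A validated `SynthConfig` list.
#' @export
synth_config <- function(
    seed = 1L,
    n_events = 10000,
    populations = data.frame(
      name = c("debris", "lymphocyte", "monocyte", "granulocyte"),
      fraction = c(0.02, 0.30, 0.08, 0.60),
      fsc_mean = c(30, 250, 450, 480),
      fsc_sd = c(10, 25, 30, 40),
      ssc_mean = c(30, 80, 220, 500),
      ssc_sd = c(10, 20, 30, 45)
    ),
    eosinophil_frac = 0.05,
    subsets = data.frame(
      name = c("cd16dim_cd62lbright", "cd16bright_cd62lbright",
               "cd16bright_cd62ldim"),
      fraction = c(0.05, 0.85, 0.10),
      cd16_meanlog = c(5.6, 6.8, 6.8),
      cd16_sdlog = c(0.15, 0.15, 0.15),
      cd62l_meanlog = c(6.3, 6.3, 4.3),
      cd62l_sdlog = c(0.15, 0.15, 0.15)
    ),
    marker_params = list(
      debris = list(cd16 = c(2.0, 0.5), cd62l = c(2.0, 0.5)),
      lymphocyte = list(cd16 = c(2.2, 0.4), cd62l = c(6.0, 0.3)),
      monocyte = list(cd16 = c(3.5, 0.4), cd62l = c(5.8, 0.3)),
      eosinophil = list(cd16 = c(2.5, 0.35), cd62l = c(6.0, 0.2))
    ),
    lambda60 = 1.5, tau_t = 25, ref_temp = 30, q10 = 2,
    brightness_meanlog = 6.0, brightness_sdlog = 0.3,
    phrodo_scale = 1.0, ph_mid = 6.5, ph_slope = 0.35,
    ph_start = 7.3, tau_ph = 15,
    ph_end_table = data.frame(
      group = rep(c("healthy", "infection", "no_infection"), each = 5),
      day = rep(c(0, 3, 6, 10, 15), times = 3),
      ph_end = c(6.30, 6.30, 6.30, 6.30, 6.30,
                 5.60, 5.70, 6.55, 6.55, 6.50,
                 6.30, 6.25, 5.90, 5.85, 5.90)
    ),
    subset_ph_offset = c(cd16dim_cd62lbright = -0.25,
                         cd16bright_cd62lbright = 0,
                         cd16bright_cd62ldim = 0.05),
    patient_ph_sd = 0.08, day_ph_sd = 0.04,
    autofluor_meanlog = 3.0, autofluor_sdlog = 0.4,
    noise_sdlog = 0.1) {
  cfg <- structure(as.list(environment()), class = "SynthConfig")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$populations$fraction) - 1) > 1e-8) {
    stop("population fractions must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$subsets$fraction) - 1) > 1e-8) {
    stop("subset fractions must sum to 1", call. = FALSE)
  }
  if (cfg$eosinophil_frac < 0 || cfg$eosinophil_frac >= 1) {
    stop("eosinophil_frac must be in [0, 1)", call. = FALSE)
  }
  if (cfg$lambda60 < 0 || cfg$tau_t <= 0 || cfg$q10 < 1) {
    stop("uptake parameters invalid (lambda60 >= 0, tau_t > 0, q10 >= 1)",
         call. = FALSE)
  }
  if (cfg$ph_slope <= 0) {
    stop("ph_slope must be > 0 (f must be strictly decreasing in pH)",
         call. = FALSE)
  }
  if (cfg$n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Expected bioparticle uptake per neutrophil
#'
#' Saturating in incubation time, Q10-scaled in temperature; strictly
#' increasing in both over the assay range.
#'
#' @param t Incubation minutes.
#' @param temp Temperature (degrees C).
#' @param config A [synth_config()].
#' @return Expected particle count (Poisson rate).
#' @export
lambda_uptake <- function(t, temp, config = synth_config()) {
  time_part <- (1 - exp(-t / config$tau_t)) / (1 - exp(-60 / config$tau_t))
  config$lambda60 * time_part * config$q10^((temp - config$ref_temp) / 10)
}

#' pH response of the pH-sensitive fluorochrome
#'
#' Positive, bounded, strictly decreasing in pH (fluorescence rises as the
#' phagolysosome acidifies).
#'
#' @param ph Phagosomal pH.
#' @param config A [synth_config()].
#' @return Relative brightness in (0, 1).
#' @export
phrodo_response <- function(ph, config = synth_config()) {
  1 / (1 + exp((ph - config$ph_mid) / config$ph_slope))
}

#' Phagosomal pH at a given incubation time
#'
#' Exponential approach from the resting pH to the group- and day-specific
#' steady state.
#'
#' @param t Incubation minutes.
#' @param group,day Sample group and study day (looked up in the
#'   trajectory table).
#' @param config A [synth_config()].
#' @param ph_end_offset Additive offset on the steady state (patient,
#'   day and subset effects).
#' @return pH value, clamped to [4.5, 7.4].
#' @export
ph_trajectory <- function(t, group, day, config = synth_config(),
                          ph_end_offset = 0) {
  tab <- config$ph_end_table
  hit <- tab$group == group & tab$day == day
  if (!any(hit)) {
    stop("no pH trajectory entry for group '", group, "', day ", day,
         call. = FALSE)
  }
  ph_end <- tab$ph_end[hit][1] + ph_end_offset
  ph <- config$ph_start -
    (config$ph_start - ph_end) * (1 - exp(-t / config$tau_ph))
  pmin(pmax(ph, 4.5), 7.4)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate one acquired sample
#'
#' Draws population memberships, scatter and marker intensities, Poisson
#' bioparticle uptake and the two bioparticle channels. Each ingested
#' particle contributes one log-normal brightness to PF520; the same
#' particle's pHrodo contribution is that brightness times the pH response
#' at the sample's phagosomal pH, so the per-cell pHrodo/PF520 ratio
#' reflects acidification independently of particle count. Cells with no
#' ingested particle carry only autofluorescence background.
#'
#' @param config A [synth_config()].
#' @param meta Sample metadata list: `patient_id`, `group`, `day`,
#'   `incubation_min`, `temperature_c`, and optionally `ph_end_offset`
#'   (patient/day-level pH offset) and `seed` (overrides `config$seed`).
#' @return List with `table` (an [event_table()]) and `truth` (data frame
#'   with per-event `population`, `is_eosinophil`, `subset`, `k`).
#' @export
simulate_sample <- function(config = synth_config(), meta = list()) {
  validate_synth_config(config)
  meta <- utils::modifyList(
    list(patient_id = "SIM", group = "healthy", day = 0,
         incubation_min = 60, temperature_c = 30, ph_end_offset = 0),
    as.list(meta)
  )
  seed <- meta$seed %||% config$seed
  meta$seed <- NULL
  with_seed(seed, {
    n <- config$n_events
    pops <- config$populations
    if (n == 0) {
      m <- matrix(numeric(0), 0, 6, dimnames = list(NULL, PF_CHANNELS))
      return(list(
        table = event_table(m, meta = meta),
        truth = data.frame(population = character(0),
                           is_eosinophil = logical(0),
                           subset = character(0), k = integer(0))
      ))
    }
    counts <- as.vector(stats::rmultinom(1, n, pops$fraction))
    population <- rep(pops$name, counts)

    fsc <- ssc <- cd16 <- cd62l <- phrodo <- pf520 <- numeric(n)
    is_eos <- logical(n)
    subset <- rep(NA_character_, n)
    k <- integer(n)

    pos <- 0
    for (i in seq_len(nrow(pops))) {
      ni <- counts[i]
      if (ni == 0) next
      idx <- pos + seq_len(ni)
      pos <- pos + ni
      fsc[idx] <- pmax(0, stats::rnorm(ni, pops$fsc_mean[i], pops$fsc_sd[i]))
      ssc[idx] <- pmax(0, stats::rnorm(ni, pops$ssc_mean[i], pops$ssc_sd[i]))
    }

    draw_marker <- function(idx, par) {
      cd16[idx] <<- stats::rlnorm(length(idx), par$cd16[1], par$cd16[2])
      cd62l[idx] <<- stats::rlnorm(length(idx), par$cd62l[1], par$cd62l[2])
    }
    for (pn in c("debris", "lymphocyte", "monocyte")) {
      idx <- which(population == pn)
      if (length(idx)) draw_marker(idx, config$marker_params[[pn]])
    }

    gran_idx <- which(population == "granulocyte")
    n_gran <- length(gran_idx)
    neu_idx <- integer(0)
    if (n_gran > 0) {
      eos_flag <- stats::runif(n_gran) < config$eosinophil_frac
      eos_idx <- gran_idx[eos_flag]
      neu_idx <- gran_idx[!eos_flag]
      is_eos[eos_idx] <- TRUE
      if (length(eos_idx)) {
        draw_marker(eos_idx, config$marker_params$eosinophil)
      }
      if (length(neu_idx)) {
        subs <- config$subsets
        sub_draw <- sample(subs$name, length(neu_idx), replace = TRUE,
                           prob = subs$fraction)
        subset[neu_idx] <- sub_draw
        for (s in seq_len(nrow(subs))) {
          sidx <- neu_idx[sub_draw == subs$name[s]]
          if (length(sidx)) {
            cd16[sidx] <- stats::rlnorm(length(sidx), subs$cd16_meanlog[s],
                                        subs$cd16_sdlog[s])
            cd62l[sidx] <- stats::rlnorm(length(sidx), subs$cd62l_meanlog[s],
                                         subs$cd62l_sdlog[s])
          }
        }
      }
    }

    # bioparticle uptake: neutrophils only
    lam <- lambda_uptake(meta$incubation_min, meta$temperature_c, config)
    if (length(neu_idx)) {
      k[neu_idx] <- stats::rpois(length(neu_idx), lam)
    }

    # background for everything, overwritten where particles were ingested
    phrodo <- stats::rlnorm(n, config$autofluor_meanlog,
                            config$autofluor_sdlog)
    pf520 <- stats::rlnorm(n, config$autofluor_meanlog,
                           config$autofluor_sdlog)

    carrier <- which(k > 0)
    if (length(carrier)) {
      total_b <- vapply(k[carrier], function(ki) {
        sum(stats::rlnorm(ki, config$brightness_meanlog,
                          config$brightness_sdlog))
      }, 1.0)
      off <- meta$ph_end_offset +
        unname(config$subset_ph_offset[subset[carrier]])
      ph <- ph_trajectory(meta$incubation_min, meta$group, meta$day,
                          config, ph_end_offset = off)
      f <- phrodo_response(ph, config)
      noise1 <- stats::rlnorm(length(carrier), 0, config$noise_sdlog)
      noise2 <- stats::rlnorm(length(carrier), 0, config$noise_sdlog)
      pf520[carrier] <- total_b * noise1
      phrodo[carrier] <- total_b * config$phrodo_scale * f * noise2
    }

    exprs <- cbind(FSC = fsc, SSC = ssc, CD16 = cd16, CD62L = cd62l,
                   PHRODO = phrodo, PF520 = pf520)
    truth <- data.frame(
      population = ifelse(population == "monocyte", "other", population),
      is_eosinophil = is_eos,
      subset = subset,
      k = k,
      stringsAsFactors = FALSE
    )
    list(table = event_table(exprs, meta = meta), truth = truth)
  })
}

#' Simulate a full longitudinal cohort
#'
#' One sample per patient x study day x incubation time (healthy controls:
#' a single draw), with patient-level and day-level pH variation around the
#' configured group trajectories. Optionally writes the FCS files, the
#' sample sheet CSV and a truth JSON to `dir`.
#'
#' @param config A [synth_config()].
#' @param n_infection,n_no_infection,n_controls Group sizes (the study
#'   followed 6 patients with and 9 without infectious complications).
#' @param days Study days for patients.
#' @param times Incubation time points (minutes).
#' @param temperature Assay temperature (degrees C).
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @return List with `sheet` (sample-sheet data frame), `samples` (named
#'   list of `simulate_sample()` results, present when `dir` is `NULL`),
#'   `patient_offsets`, `config`, and `dir`.
#' @export
simulate_cohort <- function(config = synth_config(),
                            n_infection = 6, n_no_infection = 9,
                            n_controls = 10,
                            days = c(0, 3, 6, 10, 15),
                            times = c(10, 20, 40, 60),
                            temperature = 30,
                            dir = NULL) {
  validate_synth_config(config)
  if (n_infection < 1 || n_no_infection < 1) {
    stop("patient group sizes must be >= 1", call. = FALSE)
  }
  patients <- data.frame(
    patient_id = c(sprintf("INF%02d", seq_len(n_infection)),
                   sprintf("NOI%02d", seq_len(n_no_infection)),
                   if (n_controls > 0) sprintf("CTR%02d", seq_len(n_controls))),
    group = c(rep("infection", n_infection),
              rep("no_infection", n_no_infection),
              rep("healthy", n_controls)),
    stringsAsFactors = FALSE
  )
  offsets <- with_seed(config$seed, {
    stats::setNames(stats::rnorm(nrow(patients), 0, config$patient_ph_sd),
                    patients$patient_id)
  })

  write_files <- !is.null(dir)
  if (write_files && !dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  written <- character(0)
  rows <- list()
  samples <- list()
  counter <- 0L

  emit <- function(pid, group, day, tm) {
    counter <<- counter + 1L
    day_noise <- with_seed(config$seed + 100000L + counter * 13L,
                           stats::rnorm(1, 0, config$day_ph_sd))
    meta <- list(patient_id = pid, group = group, day = day,
                 incubation_min = tm, temperature_c = temperature,
                 ph_end_offset = unname(offsets[pid]) + day_noise,
                 seed = config$seed + counter)
    sim <- simulate_sample(config, meta)
    fname <- sprintf("%s_d%02d_t%02d.fcs", pid, day, tm)
    if (write_files) {
      path <- file.path(dir, fname)
      write_fcs(sim$table, path)
      written <<- c(written, path)
    } else {
      samples[[fname]] <<- sim
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      patient_id = pid, group = group, day = day, incubation_min = tm,
      temperature_c = temperature, fcs_path = fname,
      stringsAsFactors = FALSE
    )
  }

  result <- tryCatch({
    for (p in seq_len(nrow(patients))) {
      pid <- patients$patient_id[p]
      group <- patients$group[p]
      p_days <- if (group == "healthy") days[1] else days
      for (day in p_days) {
        for (tm in times) emit(pid, group, day, tm)
      }
    }
    sheet <- do.call(rbind, rows)
    if (write_files) {
      sheet_path <- file.path(dir, "sample_sheet.csv")
      utils::write.csv(sheet, sheet_path, row.names = FALSE)
      written <- c(written, sheet_path)
      truth_path <- file.path(dir, "truth.json")
      jsonlite::write_json(
        list(seed = config$seed,
             patient_offsets = as.list(offsets),
             ph_end_table = config$ph_end_table,
             lambda60 = config$lambda60,
             subset_fractions = stats::setNames(
               as.list(config$subsets$fraction), config$subsets$name)),
        truth_path, auto_unbox = TRUE, digits = NA
      )
      written <- c(written, truth_path)
    }
    list(sheet = sheet, samples = if (!write_files) samples,
         patient_offsets = offsets, config = config, dir = dir)
  }, error = function(e) {
    if (write_files && length(written)) unlink(written)
    stop(e)
  })
  result
}

#' Simulate metric-level longitudinal cohorts
#'
#' Generates a long-format cohort table directly at the per-patient metric
#' level (no cytometry events): a constant group effect plus an
#' exchangeable within-patient random effect and independent residual
#' noise. Used for calibration of the marginal-model fitter.
#'
#' @param delta Group effect (second group minus first).
#' @param rho Exchangeable within-patient correlation.
#' @param sigma Total residual SD.
#' @param n_per_group Patients per group.
#' @param days Study days (one observation per patient-day).
#' @param baseline Intercept.
#' @param groups Group labels (reference first).
#' @param metric Metric name written into the table.
#' @param seed Integer seed.
#' @return Cohort table data frame (`patient_id`, `group`, `day`,
#'   `metric`, `value`).
#' @export
simulate_metric_cohort <- function(delta = 0.5, rho = 0.3, sigma = 0.3,
                                   n_per_group = 8,
                                   days = c(0, 3, 6, 10, 15),
                                   baseline = 1,
                                   groups = c("no_infection", "infection"),
                                   metric = "mean_acid_ratio",
                                   seed = 1L) {
  with_seed(seed, {
    n_days <- length(days)
    rows <- list()
    for (g in 1:2) {
      for (i in seq_len(n_per_group)) {
        pid <- sprintf("%s_%02d", toupper(substr(groups[g], 1, 3)), i)
        b <- stats::rnorm(1, 0, sigma * sqrt(rho))
        e <- stats::rnorm(n_days, 0, sigma * sqrt(1 - rho))
        val <- baseline + delta * (g == 2) + b + e
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, group = groups[g], day = days,
          metric = metric, value = val, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
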