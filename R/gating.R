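# Gating: scatter populations -> CD16+ neutrophils -> CD16/CD62L subsets.
#
# The published assay gated by eye; this module is the standardized,
# reproducible version: a mixture model on scatter, density-valley cuts on
# the transformed marker channels, and a manual/replay mode so any emitted
# set of thresholds can be re-applied verbatim.

POPULATION_LEVELS <- c("debris", "lymphocyte", "other", "granulocyte")
SUBSET_LEVELS <- c("cd16dim_cd62lbright", "cd16bright_cd62lbright",
                   "cd16bright_cd62ldim", "unclassified")

#' Gating configuration
#'
#' @param mode `"auto"` (mixture fit + density-valley cuts) or `"manual"`
#'   (user-supplied scatter polygon and scalar cuts).
#' @param cofactors Named vector of asinh cofactors for the fluorescence
#'   channels; scatter is never transformed.
#' @param min_events Minimum events required to fit gates.
#' @param debris_quantile Events whose FSC falls below this quantile of the
#'   fitted lymphocyte component are labeled debris.
#' @param fallback_quantile Quantile cut used when a marker distribution has
#'   no detectable second mode.
#' @param min_peak_frac Mode-detection noise floor, see [find_density_cut()].
#' @param init_subset Number of quantile-spaced events used to initialise
#'   the scatter mixture (initialisation is deterministic).
#' @param polygon Manual FSC/SSC gate: matrix with columns (FSC, SSC).
#' @param cd16_positive_cut,cd16_bright_cut,cd62l_bright_cut Manual scalar
#'   cuts on transformed CD16/CD62L.
#' @return A `GateConfig` list.
#' @export
gate_config <- function(mode = c("auto", "manual"),
                        cofactors = c(CD16 = 150, CD62L = 150,
                                      PHRODO = 150, PF520 = 150),
                        min_events = 200,
                        debris_quantile = 0.001,
                        fallback_quantile = 0.05,
                        min_peak_frac = 0.01,
                        init_subset = 1500,
                        polygon = NULL,
                        cd16_positive_cut = NULL,
                        cd16_bright_cut = NULL,
                        cd62l_bright_cut = NULL) {
  mode <- match.arg(mode)
  if (any(cofactors <= 0)) stop("cofactors must be > 0", call. = FALSE)
  if (mode == "manual") {
    if (is.null(polygon) || is.null(cd16_positive_cut) ||
        is.null(cd16_bright_cut) || is.null(cd62l_bright_cut)) {
      stop("manual mode requires `polygon` and all three scalar cuts",
           call. = FALSE)
    }
  }
  structure(list(
    mode = mode, cofactors = cofactors, min_events = min_events,
    debris_quantile = debris_quantile,
    fallback_quantile = fallback_quantile,
    min_peak_frac = min_peak_frac, init_subset = init_subset,
    polygon = polygon, cd16_positive_cut = cd16_positive_cut,
    cd16_bright_cut = cd16_bright_cut,
    cd62l_bright_cut = cd62l_bright_cut
  ), class = "GateConfig")
}

transformed_channel <- function(table, role, config) {
  asinh_transform(table$exprs[, role],
                  cofactor = unname(config$cofactors[[role]]))
}

# deterministic quantile-spaced subset for mixture initialisation
init_indices <- function(n, k) {
  unique(round(seq(1, n, length.out = min(n, k))))
}

fit_scatter_mixture <- function(fsc, ssc, config) {
  dat <- cbind(FSC = fsc, SSC = ssc)
  sub <- init_indices(nrow(dat), config$init_subset)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(
      dat, G = 3, modelNames = "VVV",
      initialization = list(subset = sub), verbose = FALSE
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  fit$parameters
}

mixture_responsibilities <- function(fsc, ssc, params) {
  dat <- cbind(FSC = fsc, SSC = ssc)
  mclust::estepVVV(data = dat, parameters = params)$z
}

#' Gate scatter populations (debris / lymphocyte / other / granulocyte)
#'
#' In auto mode fits a 3-component bivariate Gaussian mixture to the
#' untransformed (FSC, SSC) plane and assigns the components, by ascending
#' SSC centre, to lymphocytes, other mononuclear cells and granulocytes;
#' events below a low FSC quantile of the fitted lymphocyte component are
#' labeled debris. In manual mode events inside the supplied polygon are
#' granulocytes.
#'
#' @param table An [event_table()].
#' @param config A [gate_config()].
#' @return List with `population` (factor over all events), `thresholds`
#'   (mixture parameters and debris FSC floor, for replay).
#' @export
gate_granulocytes <- function(table, config = gate_config()) {
  validate_event_table(table)
  n <- n_events(table)
  if (n == 0) {
    return(list(
      population = factor(character(0), levels = POPULATION_LEVELS),
      thresholds = list(mixture = NULL, debris_fsc_threshold = NA_real_)
    ))
  }
  if (n < config$min_events && config$mode == "auto") {
    stop("gating error: ", n, " events, fewer than the configured minimum (",
         config$min_events, ")", call. = FALSE)
  }
  fsc <- table$exprs[, "FSC"]
  ssc <- table$exprs[, "SSC"]

  if (config$mode == "manual") {
    inside <- points_in_polygon(fsc, ssc, config$polygon)
    population <- factor(ifelse(inside, "granulocyte", "other"),
                         levels = POPULATION_LEVELS)
    return(list(population = population,
                thresholds = list(mixture = NULL,
                                  debris_fsc_threshold = NA_real_)))
  }

  params <- fit_scatter_mixture(fsc, ssc, config)
  if (is.null(params)) {
    if (!is.null(config$polygon)) {
      warning("scatter mixture did not converge; using manual polygon")
      inside <- points_in_polygon(fsc, ssc, config$polygon)
      population <- factor(ifelse(inside, "granulocyte", "other"),
                           levels = POPULATION_LEVELS)
      return(list(population = population,
                  thresholds = list(mixture = NULL,
                                    debris_fsc_threshold = NA_real_)))
    }
    stop("gating error: scatter mixture did not converge and no manual ",
         "polygon was provided", call. = FALSE)
  }
  apply_scatter_gate(fsc, ssc, params, config$debris_quantile)
}

apply_scatter_gate <- function(fsc, ssc, params, debris_quantile) {
  z <- mixture_responsibilities(fsc, ssc, params)
  comp <- max.col(z)
  ord <- order(params$mean["SSC", ])  # ascending SSC centre
  comp_label <- character(3)
  comp_label[ord] <- c("lymphocyte", "other", "granulocyte")
  population <- comp_label[comp]

  lymph_comp <- ord[1]
  lymph_fsc_mean <- params$mean["FSC", lymph_comp]
  lymph_fsc_sd <- sqrt(params$variance$sigma["FSC", "FSC", lymph_comp])
  debris_thr <- stats::qnorm(debris_quantile, lymph_fsc_mean, lymph_fsc_sd)
  population[fsc < debris_thr] <- "debris"

  list(population = factor(population, levels = POPULATION_LEVELS),
       thresholds = list(mixture = params,
                         debris_fsc_threshold = unname(debris_thr)))
}

#' Flag CD16-positive granulocytes as neutrophils
#'
#' Sets the CD16-positive cut at the deepest density valley between the two
#' modes of the transformed CD16 distribution among granulocytes (excluding
#' CD16-negative eosinophils). Unimodal distributions fall back to a
#' quantile cut. Events exactly on the cut count as positive.
#'
#' @param table An [event_table()].
#' @param population Population factor from [gate_granulocytes()].
#' @param config A [gate_config()].
#' @param cut Optional pre-computed cut (replay); skips estimation.
#' @return List with `neutrophil` (logical over all events),
#'   `cd16_positive_cut`, `method`.
#' @export
gate_neutrophils <- function(table, population, config = gate_config(),
                             cut = NULL) {
  validate_event_table(table)
  gran <- population == "granulocyte"
  if (!any(gran)) stop("no granulocytes to gate neutrophils from",
                       call. = FALSE)
  t_cd16 <- transformed_channel(table, "CD16", config)
  method <- "manual"
  if (is.null(cut)) {
    if (config$mode == "manual") {
      cut <- config$cd16_positive_cut
    } else if (sum(gran) < config$min_events) {
      warning("only ", sum(gran), " granulocytes; using quantile fallback ",
              "for the CD16-positive cut")
      cut <- unname(stats::quantile(t_cd16[gran], config$fallback_quantile))
      method <- "quantile"
    } else {
      res <- find_density_cut(t_cd16[gran], config$fallback_quantile,
                              config$min_peak_frac)
      cut <- res$cut
      method <- res$method
    }
  }
  neutrophil <- gran & t_cd16 >= cut
  list(neutrophil = neutrophil, cd16_positive_cut = unname(cut),
       method = method)
}

#' Classify neutrophils into CD16/CD62L subsets
#'
#' Applies scalar dim/bright cuts on transformed CD16 and CD62L among
#' neutrophils (density valley with quantile fallback in auto mode, config
#' values in manual mode) and returns per-neutrophil quadrant labels plus
#' the three named subset percentages of all neutrophils. The
#' CD16dim/CD62Ldim quadrant is reported as `unclassified` and excluded
#' from the named subsets. Events exactly on a cut go to the bright side.
#'
#' @param table An [event_table()].
#' @param neutrophil Logical flags from [gate_neutrophils()].
#' @param config A [gate_config()].
#' @param cd16_cut,cd62l_cut Optional pre-computed cuts (replay).
#' @return List with `subset` (factor over all events, `NA` outside
#'   neutrophils), `percentages` (named, three subsets plus unclassified),
#'   `cd16_bright_cut`, `cd62l_bright_cut`, `undefined` (TRUE when there
#'   are no neutrophils, in which case percentages are `NA`, not zero).
#' @export
classify_subsets <- function(table, neutrophil, config = gate_config(),
                             cd16_cut = NULL, cd62l_cut = NULL) {
  validate_event_table(table)
  n <- n_events(table)
  subset <- factor(rep(NA_character_, n), levels = SUBSET_LEVELS)
  pct_names <- c(SUBSET_LEVELS[1:3], "unclassified")
  if (!any(neutrophil)) {
    return(list(subset = subset,
                percentages = stats::setNames(rep(NA_real_, 4), pct_names),
                cd16_bright_cut = NA_real_, cd62l_bright_cut = NA_real_,
                undefined = TRUE))
  }
  t_cd16 <- transformed_channel(table, "CD16", config)
  t_cd62l <- transformed_channel(table, "CD62L", config)
  auto_cut <- function(x) {
    find_density_cut(x, config$fallback_quantile, config$min_peak_frac)$cut
  }
  if (is.null(cd16_cut)) {
    cd16_cut <- if (config$mode == "manual") config$cd16_bright_cut
                else auto_cut(t_cd16[neutrophil])
  }
  if (is.null(cd62l_cut)) {
    cd62l_cut <- if (config$mode == "manual") config$cd62l_bright_cut
                 else auto_cut(t_cd62l[neutrophil])
  }
  bright16 <- t_cd16[neutrophil] >= cd16_cut
  bright62 <- t_cd62l[neutrophil] >= cd62l_cut
  lab <- ifelse(bright16 & bright62, "cd16bright_cd62lbright",
         ifelse(bright16 & !bright62, "cd16bright_cd62ldim",
         ifelse(!bright16 & bright62, "cd16dim_cd62lbright",
                "unclassified")))
  subset[neutrophil] <- lab
  tab <- table(factor(lab, levels = SUBSET_LEVELS))
  pct <- 100 * as.numeric(tab) / sum(neutrophil)
  list(subset = subset,
       percentages = stats::setNames(pct, SUBSET_LEVELS),
       cd16_bright_cut = unname(cd16_cut),
       cd62l_bright_cut = unname(cd62l_cut),
       undefined = FALSE)
}

#' Run the full gating chain on one sample
#'
#' Scatter populations, CD16-positive neutrophil flag, CD16/CD62L subsets.
#' Passing a previous result's `thresholds` replays that gating verbatim
#' (the replay reproduces the original labels exactly).
#'
#' @param table An [event_table()].
#' @param config A [gate_config()].
#' @param thresholds Optional `thresholds` element of a previous
#'   `GatingResult` to replay.
#' @return A `GatingResult`: list with `population`, `neutrophil`,
#'   `subset`, `percentages`, `thresholds` and counts `n`.
#' @export
gate_sample <- function(table, config = gate_config(), thresholds = NULL) {
  validate_event_table(table)
  n <- n_events(table)
  if (n == 0 || !is.null(thresholds)) {
    if (n == 0) {
      pop <- list(population = factor(character(0),
                                      levels = POPULATION_LEVELS),
                  thresholds = list(mixture = NULL,
                                    debris_fsc_threshold = NA_real_))
      res <- structure(list(
        population = pop$population,
        neutrophil = logical(0),
        subset = factor(character(0), levels = SUBSET_LEVELS),
        percentages = stats::setNames(rep(NA_real_, 4), SUBSET_LEVELS),
        thresholds = c(pop$thresholds,
                       list(cd16_positive_cut = NA_real_,
                            cd16_bright_cut = NA_real_,
                            cd62l_bright_cut = NA_real_)),
        n = c(events = 0L, granulocytes = 0L, neutrophils = 0L)
      ), class = "GatingResult")
      return(res)
    }
    # replay: apply stored mixture + scalar cuts, no re-estimation
    fsc <- table$exprs[, "FSC"]
    ssc <- table$exprs[, "SSC"]
    if (!is.null(thresholds$mixture)) {
      debris_q <- config$debris_quantile
      pop <- apply_scatter_gate(fsc, ssc, thresholds$mixture, debris_q)
      # keep the stored debris floor, not a re-derived one
      population <- pop$population
      population[as.character(population) != "debris" &
                   fsc < thresholds$debris_fsc_threshold] <- "debris"
      population[as.character(population) == "debris" &
                   fsc >= thresholds$debris_fsc_threshold] <- "lymphocyte"
      pop$population <- population
      pop$thresholds$debris_fsc_threshold <- thresholds$debris_fsc_threshold
    } else if (!is.null(config$polygon)) {
      inside <- points_in_polygon(fsc, ssc, config$polygon)
      pop <- list(population = factor(ifelse(inside, "granulocyte", "other"),
                                      levels = POPULATION_LEVELS),
                  thresholds = list(mixture = NULL,
                                    debris_fsc_threshold = NA_real_))
    } else {
      stop("replay thresholds carry no scatter gate and no polygon is ",
           "configured", call. = FALSE)
    }
    neu <- gate_neutrophils(table, pop$population, config,
                            cut = thresholds$cd16_positive_cut)
    sub <- classify_subsets(table, neu$neutrophil, config,
                            cd16_cut = thresholds$cd16_bright_cut,
                            cd62l_cut = thresholds$cd62l_bright_cut)
  } else {
    pop <- gate_granulocytes(table, config)
    neu <- gate_neutrophils(table, pop$population, config)
    sub <- classify_subsets(table, neu$neutrophil, config)
  }
  structure(list(
    population = pop$population,
    neutrophil = neu$neutrophil,
    subset = sub$subset,
    percentages = sub$percentages,
    thresholds = list(
      mixture = pop$thresholds$mixture,
      debris_fsc_threshold = pop$thresholds$debris_fsc_threshold,
      cd16_positive_cut = neu$cd16_positive_cut,
      cd16_bright_cut = sub$cd16_bright_cut,
      cd62l_bright_cut = sub$cd62l_bright_cut
    ),
    n = c(events = n,
          granulocytes = sum(pop$population == "granulocyte"),
          neutrophils = sum(neu$neutrophil))
  ), class = "GatingResult")
}

#' @export
print.GatingResult <- function(x, ...) {
  cat("GatingResult:", x$n[["events"]], "events,",
      x$n[["granulocytes"]], "granulocytes,",
      x$n[["neutrophils"]], "neutrophils\n")
  if (!all(is.na(x$percentages))) {
    cat("  subsets (% of neutrophils):",
        paste(sprintf("%s=%.1f", names(x$percentages), x$percentages),
              collapse = ", "), "\n")
  }
  invisible(x)
}
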