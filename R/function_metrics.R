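# Per-sample functional readouts: phagocytosis (% PF520-positive
# neutrophils), phagosomal acidification (mean per-cell pHrodo/PF520 ratio
# over PF520-positive neutrophils), channel MFIs, and the incubation-time
# kinetics series.

#' Metric configuration
#'
#' @param stat Summary used for MFIs and the acidification ratio: `"mean"`
#'   (primary) or `"median"`.
#' @param positive_denominator Denominator convention for MFIs:
#'   `"positive"` (PF520-positive neutrophils, default) or `"all"`
#'   (all neutrophils).
#' @param reference_quantile Quantile of the negative reference used for
#'   the PF520-positivity cut.
#' @return A `MetricConfig` list.
#' @export
metric_config <- function(stat = c("mean", "median"),
                          positive_denominator = c("positive", "all"),
                          reference_quantile = 0.995) {
  structure(list(stat = match.arg(stat),
                 positive_denominator = match.arg(positive_denominator),
                 reference_quantile = reference_quantile),
            class = "MetricConfig")
}

#' PF520-positivity threshold
#'
#' The cut separating bioparticle-carrying neutrophils from
#' autofluorescence. When a negative reference sample is available (an
#' on-ice or earliest-time acquisition), the cut is a high quantile
#' (default 99.5th) of its transformed PF520 signal among neutrophils;
#' otherwise the deepest density valley between the negative and positive
#' modes is used, with a quantile fallback.
#'
#' @param table An [event_table()].
#' @param neutrophil Logical neutrophil flags for `table`.
#' @param negative_reference Optional [event_table()] of a negative
#'   reference sample.
#' @param reference_neutrophil Optional neutrophil flags for the reference
#'   (all reference events are used when omitted).
#' @param config A [gate_config()] (for the PF520 cofactor and fallback
#'   settings).
#' @param metric_config A [metric_config()].
#' @return List with `cut` (transformed units), `method`.
#' @export
pf520_positive_threshold <- function(table, neutrophil,
                                     negative_reference = NULL,
                                     reference_neutrophil = NULL,
                                     config = gate_config(),
                                     metric_config = phagoflow::metric_config()) {
  validate_event_table(table)
  if (!is.null(negative_reference)) {
    validate_event_table(negative_reference)
    ref <- transformed_channel(negative_reference, "PF520", config)
    if (!is.null(reference_neutrophil)) ref <- ref[reference_neutrophil]
    if (length(ref) == 0) {
      warning("empty negative reference; falling back to density method")
    } else {
      q <- metric_config$reference_quantile
      return(list(cut = unname(stats::quantile(ref, q)),
                  method = "reference_quantile"))
    }
  }
  t_pf <- transformed_channel(table, "PF520", config)[neutrophil]
  res <- find_density_cut(t_pf, config$fallback_quantile,
                          config$min_peak_frac)
  list(cut = res$cut, method = res$method)
}

#' Phagocytosis fraction
#'
#' Percentage of neutrophils whose transformed PF520 signal exceeds the
#' positivity cut: `100 * #(PF520 > cut) / #neutrophils`.
#'
#' @param table An [event_table()].
#' @param neutrophil Logical neutrophil flags.
#' @param cut PF520-positivity cut in transformed units.
#' @param config A [gate_config()] (PF520 cofactor).
#' @return List with `pct` (0-100, `NA` when there are no neutrophils),
#'   `n_neutrophils`, `n_positive`, `undefined`.
#' @export
phagocytosis_fraction <- function(table, neutrophil, cut,
                                  config = gate_config()) {
  validate_event_table(table)
  n_neu <- sum(neutrophil)
  if (n_neu == 0) {
    return(list(pct = NA_real_, n_neutrophils = 0L, n_positive = 0L,
                undefined = TRUE))
  }
  t_pf <- transformed_channel(table, "PF520", config)
  pos <- neutrophil & t_pf > cut
  list(pct = 100 * sum(pos) / n_neu, n_neutrophils = n_neu,
       n_positive = sum(pos), undefined = FALSE)
}

#' Acidification ratio and MFI metrics for one sample
#'
#' For each PF520-positive neutrophil the acidification ratio is the
#' untransformed pHrodo intensity divided by the untransformed PF520
#' intensity; dividing by the pH-insensitive channel corrects the
#' pH-sensitive signal for the number of ingested bioparticles. The sample
#' summary is the arithmetic mean of the per-cell ratios over
#' PF520-positive neutrophils (a ratio is undefined for cells that have
#' ingested nothing), with a median option. MFIs of both channels are
#' summarised over the same cells (or all neutrophils, by configuration).
#'
#' @param table An [event_table()].
#' @param neutrophil Logical neutrophil flags.
#' @param cut PF520-positivity cut (transformed units).
#' @param gate_config A [gate_config()].
#' @param config A [metric_config()].
#' @param subset Optional per-event subset factor (from
#'   [classify_subsets()]); when given, per-subset mean ratios are added.
#' @return A `FunctionMetrics` list: `phagocytosis_pct`,
#'   `mean_acid_ratio`, `mfi_pf520`, `mfi_phrodo`, `n_neutrophils`,
#'   `n_pf520_positive`, `undefined` (TRUE when no cell is PF520-positive,
#'   in which case ratio and MFIs are `NA`), optional
#'   `subset_mean_ratio`, and the sample `meta`.
#' @export
acidification_metrics <- function(table, neutrophil, cut,
                                  gate_config = phagoflow::gate_config(),
                                  config = metric_config(),
                                  subset = NULL) {
  validate_event_table(table)
  frac <- phagocytosis_fraction(table, neutrophil, cut, gate_config)
  t_pf <- transformed_channel(table, "PF520", gate_config)
  pos <- neutrophil & t_pf > cut
  summ <- if (config$stat == "median") stats::median else mean

  out <- list(
    phagocytosis_pct = frac$pct,
    mean_acid_ratio = NA_real_,
    mfi_pf520 = NA_real_,
    mfi_phrodo = NA_real_,
    n_neutrophils = frac$n_neutrophils,
    n_pf520_positive = frac$n_positive,
    undefined = TRUE,
    meta = table$meta
  )
  if (frac$n_positive > 0) {
    pf <- table$exprs[pos, "PF520"]
    ph <- table$exprs[pos, "PHRODO"]
    ratio <- ph / pf
    denom <- if (config$positive_denominator == "all") neutrophil else pos
    out$mean_acid_ratio <- summ(ratio)
    out$mfi_pf520 <- summ(table$exprs[denom, "PF520"])
    out$mfi_phrodo <- summ(table$exprs[denom, "PHRODO"])
    out$undefined <- FALSE
    if (!is.null(subset)) {
      out$subset_mean_ratio <- tapply(ratio, subset[pos], summ)
    }
  }
  structure(out, class = "FunctionMetrics")
}

#' @export
print.FunctionMetrics <- function(x, ...) {
  cat(sprintf(
    "FunctionMetrics: %d neutrophils, %d PF520+ (%.1f%%), mean ratio %.3f\n",
    x$n_neutrophils, x$n_pf520_positive,
    ifelse(is.na(x$phagocytosis_pct), NaN, x$phagocytosis_pct),
    ifelse(is.na(x$mean_acid_ratio), NaN, x$mean_acid_ratio)))
  invisible(x)
}

#' Convert function metrics to a one-row data frame
#' @param x A `FunctionMetrics` object.
#' @param row.names,optional,... Passed over from the generic (unused).
#' @return One-row data frame (tidy export format).
#' @export
as.data.frame.FunctionMetrics <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  meta <- x$meta
  data.frame(
    patient_id = meta$patient_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    day = meta$day %||% NA_real_,
    incubation_min = meta$incubation_min %||% NA_real_,
    temperature_c = meta$temperature_c %||% NA_real_,
    n_neutrophils = x$n_neutrophils,
    n_pf520_positive = x$n_pf520_positive,
    phagocytosis_pct = x$phagocytosis_pct,
    mean_acid_ratio = x$mean_acid_ratio,
    mfi_pf520 = x$mfi_pf520,
    mfi_phrodo = x$mfi_phrodo,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Order one patient-day's metrics by incubation time
#'
#' The assay samples each blood draw after 10, 20, 40 and 60 minutes of
#' incubation with the bioparticles. This orders the per-time-point
#' metrics, flags missing design time points, and never interpolates.
#'
#' @param metrics_list List of `FunctionMetrics` for one patient-day.
#' @param design_times Expected incubation times (minutes).
#' @return List with `metrics` (ordered list), `times` (ordered vector),
#'   `missing` (design times absent from the input).
#' @export
kinetics_curve <- function(metrics_list, design_times = c(10, 20, 40, 60)) {
  if (length(metrics_list) < 1) {
    stop("at least one time point is required", call. = FALSE)
  }
  times <- vapply(metrics_list,
                  function(m) as.numeric(m$meta$incubation_min %||% NA),
                  1.0)
  if (anyNA(times)) {
    stop("every sample needs `incubation_min` metadata", call. = FALSE)
  }
  if (anyDuplicated(times)) {
    stop("duplicate incubation time point: ",
         times[duplicated(times)][1], " min", call. = FALSE)
  }
  ord <- order(times)
  list(metrics = metrics_list[ord], times = times[ord],
       missing = setdiff(design_times, times))
}
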