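#' Semantic channel roles used by the assay
#'
#' Every sample carries six channels: forward and side scatter, the two
#' neutrophil surface markers, and the two bioparticle fluorochromes
#' (pH-sensitive pHrodo Green and pH-insensitive PF520).
#'
#' @format Character vector of the six role names, in canonical column order.
#' @export
PF_CHANNELS <- c("FSC", "SSC", "CD16", "CD62L", "PHRODO", "PF520")

#' Construct an event table
#'
#' An `EventTable` holds the per-cell intensities of one acquired sample
#' (rows = cells, columns = the six semantic channels) together with its
#' sample metadata. Intensities are stored untransformed, in the arbitrary
#' fluorescence units of the instrument; negative values are truncated to
#' zero (a count of truncated values is kept, since ratio metrics require
#' non-negative signals).
#'
#' @param exprs Numeric matrix of intensities with one column per channel.
#'   Column names must be exactly the six roles in [PF_CHANNELS] (any
#'   order; columns are reordered to canonical order).
#' @param meta Named list of sample metadata. Recognised fields:
#'   `patient_id`, `group` (one of `"infection"`, `"no_infection"`,
#'   `"healthy"`), `day` (0, 3, 6, 10 or 15), `incubation_min`
#'   (10, 20, 40 or 60) and `temperature_c`.
#' @param truncate_negative Truncate negative intensities to 0 (default
#'   `TRUE`). If `FALSE`, negative values raise an error.
#'
#' @return An object of class `EventTable`: a list with elements `exprs`
#'   (the intensity matrix), `meta`, and `n_truncated` (number of values
#'   clamped to zero).
#' @export
#' @examples
#' m <- matrix(abs(rnorm(60)), ncol = 6, dimnames = list(NULL, PF_CHANNELS))
#' et <- event_table(m, meta = list(patient_id = "P1", day = 0))
#' n_events(et)
event_table <- function(exprs, meta = list(), truncate_negative = TRUE) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stop("`exprs` must be a numeric matrix", call. = FALSE)
  }
  cn <- colnames(exprs)
  if (is.null(cn) || !setequal(cn, PF_CHANNELS) || anyDuplicated(cn)) {
    stop("`exprs` must have exactly the channel columns: ",
         paste(PF_CHANNELS, collapse = ", "), call. = FALSE)
  }
  exprs <- exprs[, PF_CHANNELS, drop = FALSE]
  n_trunc <- 0L
  neg <- exprs < 0
  if (any(neg)) {
    if (!truncate_negative) {
      stop("negative intensities present and `truncate_negative = FALSE`",
           call. = FALSE)
    }
    n_trunc <- sum(neg)
    exprs[neg] <- 0
  }
  structure(
    list(exprs = exprs, meta = as.list(meta), n_truncated = n_trunc),
    class = "EventTable"
  )
}

#' Number of events in an event table
#' @param table An [event_table()].
#' @return Integer event count.
#' @export
n_events <- function(table) {
  stopifnot(inherits(table, "EventTable"))
  nrow(table$exprs)
}

#' @export
print.EventTable <- function(x, ...) {
  cat("EventTable:", nrow(x$exprs), "events x", ncol(x$exprs), "channels\n")
  if (length(x$meta)) {
    keep <- intersect(
      c("patient_id", "group", "day", "incubation_min", "temperature_c"),
      names(x$meta)
    )
    if (length(keep)) {
      cat("  meta:",
          paste(keep, unlist(x$meta[keep]), sep = "=", collapse = ", "),
          "\n")
    }
  }
  if (x$n_truncated > 0) {
    cat("  ", x$n_truncated, "negative value(s) truncated to 0\n")
  }
  invisible(x)
}

validate_event_table <- function(table) {
  if (!inherits(table, "EventTable")) stop("not an EventTable", call. = FALSE)
  if (!identical(colnames(table$exprs), PF_CHANNELS)) {
    stop("EventTable columns are not the canonical channel roles",
         call. = FALSE)
  }
  if (nrow(table$exprs) > 0 && any(table$exprs < 0)) {
    stop("EventTable contains negative intensities", call. = FALSE)
  }
  invisible(table)
}

#' Build a channel map from raw FCS parameter names to semantic roles
#'
#' The instrument's short parameter names (`$PnN`) are not standardised,
#' so the mapping to the six assay roles is supplied by the user, either
#' as a named character vector or as a `key=value` text file with one
#' `raw_name=ROLE` line per channel.
#'
#' @param x Named character vector (names = raw `$PnN` values, values =
#'   roles from [PF_CHANNELS]), or the path of a `key=value` file.
#' @return A validated named character vector of class `ChannelMap`.
#' @export
#' @examples
#' channel_map(c(FS = "FSC", SS = "SSC", FL2 = "CD16", FL3 = "CD62L",
#'               FL1 = "PHRODO", FL4 = "PF520"))
channel_map <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) {
      stop("malformed channel-map line: ", lines[bad][1], call. = FALSE)
    }
    x <- stats::setNames(trimws(vapply(kv, `[[`, "", 2)),
                         trimws(vapply(kv, `[[`, "", 1)))
  }
  if (!is.character(x) || is.null(names(x))) {
    stop("channel map must be a named character vector or a key=value file",
         call. = FALSE)
  }
  roles <- unname(x)
  if (!setequal(roles, PF_CHANNELS) || anyDuplicated(roles)) {
    missing <- setdiff(PF_CHANNELS, roles)
    stop("channel map must cover each role exactly once; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("channel map is not injective: duplicated raw names", call. = FALSE)
  }
  structure(x, class = "ChannelMap")
}
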