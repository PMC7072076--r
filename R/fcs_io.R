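# Minimal FCS 3.0/3.1 listmode reader/writer.
#
# Only the subset of the standard this assay needs: $MODE=L, $DATATYPE F, D
# or I (uniform $PnB of 16/32/64 bits), little- or big-endian $BYTEORD.
# Delimiter escaping (doubled delimiters inside values) is not supported;
# the writer never produces it.

FCS_HEADER_LEN <- 58L  # "FCS3.1" + 4 spaces + 6 right-justified 8-byte offsets

#' Read an FCS listmode file
#'
#' Parses an FCS 3.0 or 3.1 file and returns its data segment as an
#' [event_table()], with instrument parameter names mapped to the six
#' semantic assay roles through a [channel_map()]. Intensities are taken
#' from the stored data segment without transformation; events keep file
#' order; negative stored values are truncated to 0 and counted.
#'
#' @param path Path of the FCS file.
#' @param channel_map A [channel_map()], or `NULL` when the file's `$PnN`
#'   names already are the role names.
#' @param meta Sample metadata list attached to the returned table.
#' @return An [event_table()].
#' @export
read_fcs <- function(path, channel_map = NULL, meta = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = FCS_HEADER_LEN)
  if (length(hdr_raw) < FCS_HEADER_LEN) {
    stop("malformed FCS header: file shorter than ", FCS_HEADER_LEN,
         " bytes", call. = FALSE)
  }
  hdr <- rawToChar(hdr_raw)
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("malformed FCS header: unsupported version '", version, "'",
         call. = FALSE)
  }
  off <- function(i) {
    s <- trimws(substr(hdr, 11 + (i - 1) * 8, 10 + i * 8))
    if (!nzchar(s)) return(0) else as.numeric(s)
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)
  if (is.na(text_begin) || is.na(text_end) || text_end < text_begin) {
    stop("malformed FCS header: invalid TEXT segment offsets", call. = FALSE)
  }

  seek(con, text_begin)
  text <- rawToChar(readBin(con, "raw", n = text_end - text_begin + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("malformed FCS TEXT segment", call. = FALSE)
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- toupper(parts[seq(1, length(parts), by = 2)])
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, trimws(keys))
  get_kw <- function(k, required = TRUE) {
    v <- kw[[k]]
    if (is.null(v) && required) {
      stop("malformed FCS file: missing keyword ", k, call. = FALSE)
    }
    v
  }

  if (!identical(get_kw("$MODE"), "L")) {
    stop("only list-mode ($MODE=L) FCS files are supported", call. = FALSE)
  }
  datatype <- get_kw("$DATATYPE")
  byteord <- get_kw("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  if (data_begin == 0 || data_end == 0) {
    data_begin <- as.numeric(get_kw("$BEGINDATA"))
    data_end <- as.numeric(get_kw("$ENDDATA"))
  }

  p_names <- vapply(seq_len(n_par),
                    function(i) get_kw(paste0("$P", i, "N")), "")
  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(get_kw(paste0("$P", i, "B"))), 1L)
  if (length(unique(bits)) != 1) {
    stop("mixed per-parameter bit widths are not supported", call. = FALSE)
  }

  if (n_tot > 0) {
    seek(con, data_begin)
    n_val <- n_par * n_tot
    values <- switch(
      datatype,
      "F" = readBin(con, "numeric", n = n_val, size = 4, endian = endian),
      "D" = readBin(con, "numeric", n = n_val, size = 8, endian = endian),
      "I" = {
        b <- bits[1]
        if (b == 16) {
          as.numeric(readBin(con, "integer", n = n_val, size = 2,
                             signed = FALSE, endian = endian))
        } else if (b == 32) {
          v <- readBin(con, "integer", n = n_val, size = 4, endian = endian)
          v <- as.numeric(v)
          v[v < 0] <- v[v < 0] + 2^32  # stored as unsigned
          v
        } else {
          stop("unsupported $PnB for integer data: ", b, call. = FALSE)
        }
      },
      stop("unsupported $DATATYPE: ", datatype, call. = FALSE)
    )
    if (length(values) != n_val) {
      stop("malformed FCS file: data segment shorter than $PAR * $TOT",
           call. = FALSE)
    }
    exprs <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)
  } else {
    exprs <- matrix(numeric(0), nrow = 0, ncol = n_par)
  }
  colnames(exprs) <- p_names

  if (is.null(channel_map)) {
    if (!all(PF_CHANNELS %in% p_names)) {
      missing <- setdiff(PF_CHANNELS, p_names)
      stop("no channel map supplied and no parameter found for role(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    sel <- PF_CHANNELS
    roles <- PF_CHANNELS
  } else {
    channel_map <- channel_map(unclass(channel_map))
    missing_raw <- setdiff(names(channel_map), p_names)
    if (length(missing_raw)) {
      bad_roles <- unname(channel_map[missing_raw])
      stop("no FCS parameter found for role(s): ",
           paste(bad_roles, collapse = ", "),
           " (expected $PnN: ", paste(missing_raw, collapse = ", "), ")",
           call. = FALSE)
    }
    sel <- names(channel_map)
    roles <- unname(channel_map)
  }
  exprs <- exprs[, sel, drop = FALSE]
  colnames(exprs) <- roles
  event_table(exprs, meta = meta)
}

#' Write an event table as an FCS 3.1 file
#'
#' Emits a single-dataset FCS 3.1 file (list mode, 32-bit float, little
#' endian) whose `$PnN` names are the six semantic roles, readable by
#' [read_fcs()] with no channel map. `$TOT` equals the row count.
#'
#' @param table An [event_table()].
#' @param path Output path.
#' @param parameter_names `$PnN` names to store, in canonical channel
#'   order; defaults to the role names themselves. Override to emulate
#'   instrument naming (the file then needs a [channel_map()] to read).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path, parameter_names = PF_CHANNELS) {
  validate_event_table(table)
  stopifnot(length(parameter_names) == 6, !anyDuplicated(parameter_names))
  x <- table$exprs
  colnames(x) <- parameter_names
  n_par <- ncol(x)
  n_tot <- nrow(x)
  delim <- "/"

  ranges <- apply(x, 2, function(col) {
    if (length(col) == 0) 262144 else max(1024, ceiling(max(col)) + 1)
  })
  kv <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kv[paste0("$P", i, "N")] <- colnames(x)[i]
    kv[paste0("$P", i, "B")] <- "32"
    kv[paste0("$P", i, "E")] <- "0,0"
    kv[paste0("$P", i, "R")] <- as.character(ranges[i])
  }
  # Fixed-width data offsets so the TEXT length does not depend on them.
  kv["$BEGINDATA"] <- sprintf("%010d", 0)
  kv["$ENDDATA"] <- sprintf("%010d", 0)

  build_text <- function(kv) {
    paste0(delim, paste(rbind(names(kv), unname(kv)), collapse = delim),
           delim)
  }
  text <- build_text(kv)
  text_begin <- FCS_HEADER_LEN
  text_end <- text_begin + nchar(text) - 1L
  n_bytes <- 4L * n_par * n_tot
  if (n_tot > 0) {
    data_begin <- text_end + 1L
    data_end <- data_begin + n_bytes - 1L
  } else {
    data_begin <- 0L
    data_end <- 0L
  }
  kv["$BEGINDATA"] <- sprintf("%010d", data_begin)
  kv["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kv)
  stopifnot(nchar(text) == text_end - text_begin + 1L)

  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(hdr) == FCS_HEADER_LEN)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(text), con)
  if (n_tot > 0) {
    writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is the plain CSV that ties FCS files to their sample
#' metadata, with columns `patient_id`, `group`, `day`, `incubation_min`,
#' `temperature_c`, `fcs_path`.
#'
#' @param path CSV path.
#' @return A data frame with the columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "group", "day", "incubation_min",
           "temperature_c", "fcs_path")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("sample sheet missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
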