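#' Read and write trace files
#'
#' The canonical on-disk format is plain delimited text: `#`-prefixed
#' `key = value` header lines (`type`, `frame_interval`, `channels`, plus any
#' scalar metadata), then a tab-separated body with one row per frame:
#' `molecule_id`, `frame` (1-based, contiguous per molecule) and one column
#' per declared channel. Values are written to full precision, so
#' write-then-read round-trips losslessly.
#'
#' @param traces List of [intensity_trace()] or [fret_trace()] objects (all of
#'   the same type and frame interval).
#' @param path File path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list of trace objects (empty, with a warning, for a header-only file).
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, c("intensity_trace", "fret_trace")))
    traces <- list(traces)
  stopifnot(length(traces) >= 1)
  is_fret <- inherits(traces[[1]], "fret_trace")
  series_of <- function(tr) if (is_fret) tr$efficiencies else tr$channels
  chans <- names(series_of(traces[[1]]))
  fi <- trace_frame_interval_any(traces)
  header <- c("# slidefret trace v1",
              sprintf("# type = %s", if (is_fret) "fret" else "intensity"),
              sprintf("# frame_interval = %.17g", fi),
              sprintf("# channels = %s", paste(chans, collapse = ",")))
  body <- lapply(traces, function(tr) {
    s <- series_of(tr)
    nf <- length(s[[1]])
    cbind(molecule_id = rep(tr$molecule_id, nf), frame = seq_len(nf),
          vapply(s, function(v) sprintf("%.17g", v), character(nf)))
  })
  body <- do.call(rbind, body)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("molecule_id", "frame", chans), collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

trace_frame_interval_any <- function(traces) {
  fi <- unique(vapply(traces, `[[`, numeric(1), "frame_interval"))
  if (length(fi) > 1) stop("traces have differing frame intervals")
  fi
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_header(hdr)
  for (key in c("type", "frame_interval", "channels"))
    if (is.null(meta[[key]])) stop("malformed header: missing '", key, "'")
  chans <- strsplit(meta$channels, ",")[[1]]
  fi <- as.numeric(meta$frame_interval)
  body_lines <- lines[!grepl("^#", lines)]
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  if (length(body_lines) <= 1) {
    warning("trace file has no data rows")
    return(list())
  }
  df <- read.table(text = body_lines, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("molecule_id", "frame", chans) %in% names(df)))
    stop("declared channels missing from body: expected ",
         paste(chans, collapse = ", "))
  out <- lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$frame), ]
    if (anyDuplicated(sub$frame))
      stop("duplicate (molecule, frame) rows for ", sub$molecule_id[1])
    if (!identical(as.integer(sub$frame), seq_len(nrow(sub))))
      stop("frame indices not contiguous for ", sub$molecule_id[1])
    series <- lapply(sub[chans], as.numeric)
    if (meta$type == "fret")
      fret_trace(series, frame_interval = fi,
                 molecule_id = sub$molecule_id[1])
    else
      intensity_trace(series, frame_interval = fi,
                      molecule_id = sub$molecule_id[1])
  })
  out[order(match(names(out), unique(df$molecule_id)))]
}

parse_header <- function(hdr) {
  kv <- grep("=", hdr, value = TRUE)
  keys <- trimws(sub("^#\\s*([^=]+)=.*$", "\\1", kv))
  vals <- trimws(sub("^#[^=]+=\\s*(.*)$", "\\1", kv))
  setNames(as.list(vals), keys)
}

#' Serialize a calibration table
#'
#' Tab-separated long-format table (`d_um2`, `length`, `tau`, `se`, `n_reps`)
#' with the grid and fit window in `#` header metadata.
#'
#' @param table A `calibration_table`.
#' @param path File path.
#' @return `write_calibration_table` returns `path` invisibly;
#'   `read_calibration_table` returns a `calibration_table` (without the
#'   simulation config snapshot).
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slidefret calibration v1",
               sprintf("# d_grid = %s",
                       paste(sprintf("%.17g", table$d_grid), collapse = ",")),
               sprintf("# lengths = %s",
                       paste(table$lengths, collapse = ",")),
               sprintf("# duplex_length = %g", table$duplex_length),
               sprintf("# max_lag = %.17g", table$max_lag)), con)
  tab <- table$table
  for (col in c("d_um2", "tau", "se"))
    tab[[col]] <- sprintf("%.17g", tab[[col]])
  writeLines(paste(names(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(grep("^#", lines, value = TRUE))
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  structure(list(table = df,
                 d_grid = as.numeric(strsplit(meta$d_grid, ",")[[1]]),
                 lengths = as.numeric(strsplit(meta$lengths, ",")[[1]]),
                 config = NULL,
                 duplex_length = as.numeric(meta$duplex_length),
                 max_lag = as.numeric(meta$max_lag)),
            class = "calibration_table")
}

#' Serialize idealizations
#'
#' Tab-separated per-frame state paths (`molecule_id`, `frame`, `state`) with
#' the model state means and frame interval in header metadata.
#'
#' @param idealizations List of `idealization` objects.
#' @param path File path.
#' @return `write_idealizations` returns `path` invisibly;
#'   `read_idealizations` returns a list of `idealization` objects.
#' @export
write_idealizations <- function(idealizations, path) {
  if (inherits(idealizations, "idealization"))
    idealizations <- list(idealizations)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slidefret idealization v1",
               sprintf("# means = %s",
                       paste(sprintf("%.17g", idealizations[[1]]$means),
                             collapse = ",")),
               sprintf("# frame_interval = %.17g",
                       idealizations[[1]]$frame_interval)), con)
  writeLines("molecule_id\tframe\tstate", con)
  for (idl in idealizations)
    writeLines(sprintf("%s\t%d\t%d", idl$molecule_id,
                       seq_along(idl$states), idl$states), con)
  invisible(path)
}

#' @rdname write_idealizations
#' @export
read_idealizations <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(grep("^#", lines, value = TRUE))
  means <- as.numeric(strsplit(meta$means, ",")[[1]])
  fi <- as.numeric(meta$frame_interval)
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  lapply(split(df, df$molecule_id), function(sub) {
    sub <- sub[order(sub$frame), ]
    path_states <- as.integer(sub$state)
    r <- rle(path_states)
    ends <- cumsum(r$lengths)
    structure(list(states = path_states,
                   segments = data.frame(state = r$values,
                                         start = ends - r$lengths + 1L,
                                         length = r$lengths),
                   means = means, frame_interval = fi,
                   molecule_id = sub$molecule_id[1]),
              class = "idealization")
  })
}

#' Serialize a transition density plot
#'
#' Dense counts matrix as tab-separated text with the bin edges in header
#' metadata.
#'
#' @param tdp A `tdp` object.
#' @param path File path.
#' @return `write_tdp` returns `path` invisibly; `read_tdp` a `tdp`.
#' @export
write_tdp <- function(tdp, path) {
  stopifnot(inherits(tdp, "tdp"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# slidefret tdp v1",
               sprintf("# breaks = %s",
                       paste(sprintf("%.17g", tdp$breaks), collapse = ",")),
               sprintf("# axis = %s", tdp$axis),
               sprintf("# n_transitions = %d", tdp$n_transitions)), con)
  writeLines(apply(tdp$counts, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_tdp
#' @export
read_tdp <- function(path) {
  lines <- readLines(path)
  meta <- parse_header(grep("^#", lines, value = TRUE))
  counts <- as.matrix(read.table(text = lines[!grepl("^#", lines)],
                                 sep = "\t"))
  dimnames(counts) <- NULL
  structure(list(counts = counts,
                 breaks = as.numeric(strsplit(meta$breaks, ",")[[1]]),
                 n_transitions = as.integer(meta$n_transitions),
                 axis = meta$axis),
            class = "tdp")
}
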