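#' Write / read a multi-lead recording as CSV with a YAML sidecar
#'
#' The signal container is a plain CSV (one column per lead, samples in
#' rows, mV) accompanied by `<path>.yaml` carrying the sampling rate, lead
#' names and optional metadata. A recording without a declared sampling
#' rate is rejected on read -- never silently defaulted. Recordings at a
#' rate other than 1000 Hz are linearly resampled to 1000 Hz with a
#' warning.
#'
#' @param recording list with `signals` (T x L matrix), `fs`, `lead_names`
#'   (an `egm_recording` works).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  sig <- as.matrix(recording$signals)
  colnames(sig) <- recording$lead_names[seq_len(ncol(sig))]
  utils::write.csv(sig, path, row.names = FALSE)
  meta <- list(fs = recording$fs,
               lead_names = as.list(colnames(sig)),
               units = "mV")
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @param target_fs rate the signals are brought to, default 1000 Hz.
#' @export
read_recording <- function(path, target_fs = 1000) {
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar))
    stop("no sidecar '", sidecar, "': a declared sampling rate is required")
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs)) stop("sidecar declares no sampling rate (fs)")
  sig <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (meta$fs != target_fs) {
    warning("resampling recording from ", meta$fs, " to ", target_fs, " Hz")
    new_len <- round(nrow(sig) * target_fs / meta$fs)
    sig <- apply(sig, 2, interp_to_length, new_len = new_len)
  }
  structure(list(signals = sig, fs = target_fs,
                 lead_names = colnames(sig)),
            class = "egm_recording")
}

INTERVAL_CONVENTION <- list(index_base = 0, interval = "half-open",
                            units = "samples@1000Hz")

#' Write / read interval tables (JSON or CSV)
#'
#' Both dialects stamp the coordinate convention (0-based, half-open) in a
#' header field; files claiming a different convention are rejected rather
#' than silently reinterpreted. Sample and millisecond columns are both
#' emitted (identical at 1000 Hz).
#'
#' @param intervals an interval table.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path` invisibly (write) or an `egm_intervals` (read).
#' @export
write_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)[, c("kind", "onset", "offset", "lead")]
  df$onset_ms <- df$onset; df$offset_ms <- df$offset
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(convention = INTERVAL_CONVENTION,
                              frame = attr(intervals, "frame"),
                              intervals = df),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    header <- sprintf("# index_base=%d interval=%s units=%s frame=%s",
                      INTERVAL_CONVENTION$index_base,
                      INTERVAL_CONVENTION$interval,
                      INTERVAL_CONVENTION$units,
                      attr(intervals, "frame"))
    writeLines(header, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
  }
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    conv <- obj$convention
    if (!identical(as.integer(conv$index_base), 0L) ||
        !identical(conv$interval, "half-open"))
      stop("interval file declares an unsupported coordinate convention")
    df <- obj$intervals
    frame <- if (is.null(obj$frame)) NA_real_ else obj$frame
  } else {
    header <- readLines(path, n = 1)
    if (!grepl("index_base=0", header) || !grepl("interval=half-open", header))
      stop("interval file declares an unsupported coordinate convention")
    df <- utils::read.csv(path, skip = 1)
    fr <- sub(".*frame=([0-9NAna.]+).*", "\\1", header)
    frame <- suppressWarnings(as.numeric(fr))
  }
  if (is.null(df) || length(df) == 0 ||
      (is.data.frame(df) && nrow(df) == 0))
    return(egm_intervals(frame = frame))
  as_egm_intervals(df, frame)
}

#' Persist / load a segment bank as a directory of CSV files
#'
#' One CSV per kind (`LF.csv`, ...), each row one segment: the
#' `native_amplitude` followed by the normalized samples (ragged rows are
#' padded with `NA`), plus an `index.json` with counts and the morphology
#' configuration.
#'
#' @param pools a `segment_pools`.
#' @param dir directory (created if needed).
#' @return `dir` invisibly (write) or a `segment_pools` (read).
#' @export
write_segment_bank <- function(pools, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kind in names(pools)) {
    segs <- pools[[kind]]
    maxlen <- max(vapply(segs, function(s) length(s$samples), numeric(1)))
    m <- t(vapply(segs, function(s)
      c(s$native_amplitude, s$samples,
        rep(NA_real_, maxlen - length(s$samples))), numeric(maxlen + 1)))
    utils::write.csv(m, file.path(dir, paste0(kind, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(kinds = names(pools), counts = lengths(pools)),
                       file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_segment_bank
#' @export
read_segment_bank <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  pools <- lapply(idx$kinds, function(kind) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(kind, ".csv"))))
    lapply(seq_len(nrow(m)), function(i) {
      row <- m[i, ]
      samples <- unname(row[-1][!is.na(row[-1])])
      egm_segment(samples, kind, native_amplitude = unname(row[1]),
                  normalize = FALSE)
    })
  })
  names(pools) <- idx$kinds
  structure(pools, class = "segment_pools")
}

#' Serialize / restore a fitted segmentation model as JSON
#'
#' Stores the architecture configuration and every weight tensor in plain
#' text so checkpoints survive source-only distribution. A load hook
#' accepts externally trained weights whenever the layer shapes match.
#'
#' @param object an `egm_segmenter` or `egm_net`.
#' @param path JSON path.
#' @return `path` invisibly (write) or the restored object (read).
#' @export
write_model <- function(object, path) {
  net <- if (inherits(object, "egm_segmenter")) object$net else object
  weights <- flatten_params(net)
  jsonlite::write_json(list(
    config = unclass(net$config),
    weights = lapply(weights, function(w)
      list(dim = dim(w), values = as.numeric(w)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(net_config, obj$config[c("arch", "depth", "base_channels",
                                          "blocks_per_level", "kernel_size",
                                          "use_eca", "use_norm",
                                          "in_channels", "out_channels",
                                          "lrelu_slope", "dropout")])
  net <- build_model(cfg)
  load_weights(net, obj$weights)
}

#' @rdname write_model
#' @param net an `egm_net` to receive the weights.
#' @param weights named list of weight tensors (as stored by
#'   [write_model()], or any source whose shapes match).
#' @export
load_weights <- function(net, weights) {
  for (nm in names(weights)) {
    w <- weights[[nm]]
    vals <- if (is.list(w)) w$values else as.numeric(w)
    dm <- if (is.list(w)) w$dim else dim(w)
    parts <- strsplit(nm, "\\.")[[1]]
    i <- as.integer(sub("n", "", parts[1]))
    nd <- net$nodes[[i]]
    if (grepl("^W", parts[2])) {
      tap <- as.integer(sub("W", "", parts[2]))
      if (!all(dim(nd$W[[tap]]) == dm))
        stop("shape mismatch for ", nm, "; cannot load these weights")
      nd$W[[tap]] <- matrix(vals, dm[1], dm[2])
    } else if (parts[2] == "b") {
      if (length(nd$b) != length(vals)) stop("shape mismatch for ", nm)
      nd$b <- vals
    } else if (parts[2] == "w") {
      if (length(nd$w) != length(vals)) stop("shape mismatch for ", nm)
      nd$w <- vals
    } else if (parts[2] == "gamma") {
      if (length(nd$gamma) != length(vals)) stop("shape mismatch for ", nm)
      nd$gamma <- vals
    } else if (parts[2] == "beta") {
      if (length(nd$beta) != length(vals)) stop("shape mismatch for ", nm)
      nd$beta <- vals
    }
    net$nodes[[i]] <- nd
  }
  net
}

#' Write a run manifest
#'
#' Every CLI run directory carries a manifest sufficient to reproduce it:
#' configuration, seed and package version.
#'
#' @param dir run directory.
#' @param config named list of configuration values.
#' @param seed integer seed.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seed) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    package = "egmseg",
    version = as.character(utils::packageVersion("egmseg")),
    seed = seed, config = config,
    timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
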