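## Parameter-file and run-configuration loading, and the packaged protocol
## runners that write traces, features and JSON metadata sidecars.

.param_units <- c(voltage = "mV", time = "ms", conductance = "nS",
                  current = "pA", capacitance = "pF", concentration = "mM")

.gating_from_yaml <- function(x, where) {
  if (is.null(x)) return(NULL)
  extra <- setdiff(names(x), c("v_half", "slope", "tau"))
  if (length(extra))
    stop("unknown keys in ", where, ": ", paste(extra, collapse = ", "))
  gating_spec(x$v_half, x$slope, x$tau)
}

#' Load a cell parameter file
#'
#' Reads a structured (YAML) parameter file with one block per channel plus
#' `cell`, `glucose_map` and `sglt2` blocks, validates units and ranges, and
#' optionally logs the provenance note attached to each block.
#'
#' @param path Path to the parameter file.
#' @param verbose If `TRUE`, log provenance notes and defaulted fields.
#' @return An [cell_params()] object.
#' @export
load_cell_params <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("units", "cell", "glucose_map", "channels", "sglt2",
             "provenance")
  extra <- setdiff(names(y), known)
  if (length(extra))
    stop("unknown top-level keys in parameter file: ",
         paste(extra, collapse = ", "))
  if (!is.null(y$units)) {
    bad <- names(y$units)[unlist(y$units) !=
                            .param_units[names(y$units)]]
    if (length(bad))
      stop("unit mismatch for ", paste(bad, collapse = ", "),
           "; the model uses mV, ms, nS, pA, pF, mM")
  }
  chans <- lapply(names(y$channels), function(nm) {
    ch <- y$channels[[nm]]
    extra <- setdiff(names(ch), c("g_max", "v_rev", "activation",
                                  "inactivation", "activation_exponent"))
    if (length(extra))
      stop("unknown keys in channel ", nm, ": ",
           paste(extra, collapse = ", "))
    if (is.null(ch$g_max) || ch$g_max < 0)
      stop("channel ", nm, ": g_max missing or negative")
    channel_params(nm, ch$g_max, ch$v_rev,
                   activation = .gating_from_yaml(ch$activation,
                                                  paste0(nm, "$activation")),
                   inactivation = .gating_from_yaml(ch$inactivation,
                                                    paste0(nm, "$inactivation")),
                   activation_exponent = ch$activation_exponent %||% 1L)
  })
  names(chans) <- names(y$channels)
  sg <- y$sglt2
  gi <- sg$glucose_in
  if (identical(gi, "tied")) gi <- NULL
  sglt2 <- sglt2_params(rates = sg$rates, valences = unlist(sg$valences),
                        theta = sg$theta %||% 1,
                        n_transporters = sg$n_transporters,
                        na_out = sg$na_out %||% 140,
                        na_in = sg$na_in %||% 10,
                        glucose_in = gi,
                        na_stoichiometry = sg$na_stoichiometry %||% 1L,
                        temperature_c = sg$temperature_c %||% 37)
  cp <- y$cell
  gmap <- y$glucose_map %||% list()
  params <- cell_params(channels = chans, sglt2 = sglt2,
                        c_m = cp$c_m %||% 5,
                        v_k = cp$v_k %||% -75,
                        g_leak = cp$leak$g_max %||% 0,
                        v_leak = cp$leak$v_rev %||% -20,
                        g_katp_low = gmap$g_katp_low %||% 0.15,
                        g_katp_high = gmap$g_katp_high %||% 0.115,
                        glucose_low = gmap$glucose_low %||% 1,
                        glucose_high = gmap$glucose_high %||% 6)
  if (verbose && !is.null(y$provenance))
    for (nm in names(y$provenance))
      message("provenance [", nm, "]: ", y$provenance[[nm]])
  attr(params, "source") <- normalizePath(path)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged parameter sets
#'
#' Two reconstructed, calibration-derived parameter sets ship with the
#' package: `"default"` reproduces the glucose-step phenotype (suppression
#' of action-potential height by glucose and its reversal by SGLT2 block)
#' and `"subset-acell"` is a variant, representing a subset of A-cells, in
#' which action potentials survive 6 mM but fail at 11 mM glucose.
#'
#' @param set `"default"` or `"subset-acell"`.
#' @param verbose Passed to [load_cell_params()].
#' @return An [cell_params()] object.
#' @export
acell_default_params <- function(set = c("default", "subset-acell"),
                                 verbose = FALSE) {
  set <- match.arg(set)
  f <- c("default" = "params_default.yaml",
         "subset-acell" = "params_subset_acell.yaml")[[set]]
  load_cell_params(system.file("extdata", f, package = "acellsim",
                               mustWork = TRUE), verbose = verbose)
}

.config_defaults <- list(
  parameters = "default",
  solver = list(rtol = 1e-8, atol = 1e-10, sample_khz = 2,
                burn_in_s = 5, hmax = 1),
  protocol = list(segment_s = 10),
  analysis = list(min_prominence = 5),
  output = list(dir = ".")
)

#' Load and validate a run configuration
#'
#' Fills documented defaults for any omitted field (each defaulted field is
#' logged when `verbose`), resolves the parameter set, and validates ranges.
#'
#' @param path Path to a YAML run configuration, or `NULL` for an
#'   all-defaults configuration.
#' @param verbose Log defaulted fields and provenance notes.
#' @return A validated configuration list of class `acell_config` with a
#'   `params` element holding the loaded [cell_params()].
#' @export
load_config <- function(path = NULL, verbose = FALSE) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  extra <- setdiff(names(y), names(.config_defaults))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  cfg <- .config_defaults
  for (k in names(y)) {
    if (is.list(cfg[[k]]) && is.list(y[[k]])) {
      extra <- setdiff(names(y[[k]]), names(cfg[[k]]))
      if (length(extra))
        stop("unknown keys in '", k, "': ", paste(extra, collapse = ", "))
      cfg[[k]][names(y[[k]])] <- y[[k]]
    } else cfg[[k]] <- y[[k]]
  }
  if (verbose)
    for (k in names(.config_defaults))
      if (!k %in% names(y)) message("config: using default '", k, "'")
  with(cfg$solver, stopifnot(rtol > 0, atol > 0, sample_khz > 0,
                             burn_in_s >= 0, hmax > 0))
  stopifnot(cfg$protocol$segment_s > 0)
  cfg$params <- if (cfg$parameters %in% c("default", "subset-acell"))
    acell_default_params(cfg$parameters, verbose = verbose)
  else load_cell_params(cfg$parameters, verbose = verbose)
  class(cfg) <- "acell_config"
  cfg
}

#' Serialize a run configuration back to YAML
#'
#' @param config An `acell_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$params <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# stable content hash of a parameter set (used in metadata sidecars)
params_hash <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(rapply(unclass(params), function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace")), tf)
  unname(tools::md5sum(tf))
}

write_sidecar <- function(path, params, cfg, extra = list()) {
  meta <- c(list(parameter_hash = params_hash(params),
                 solver = cfg$solver,
                 package_version = as.character(
                   utils::packageVersion("acellsim"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the glucose-step / dapagliflozin protocol and write outputs
#'
#' Executes the four-segment protocol (1, 6, 11 mM glucose, then 11 mM with
#' dapagliflozin), writes the full trace, per-segment action-potential
#' features and a JSON metadata sidecar. The pipeline is deterministic:
#' repeated runs produce identical CSVs.
#'
#' @param config An `acell_config` (default: all-defaults configuration).
#' @param out_dir Output directory (created if needed).
#' @param analysis_window_s Portion of each segment analysed for AP
#'   features, taken from the segment end (s).
#' @return Invisibly, a list with the trace, the per-segment features table
#'   and the written file paths.
#' @export
run_figure2 <- function(config = load_config(), out_dir = ".",
                        analysis_window_s = NULL) {
  stopifnot(inherits(config, "acell_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proto <- figure2_protocol(segment_s = config$protocol$segment_s)
  sv <- config$solver
  tr <- simulate_protocol(config$params, proto, burn_in_s = sv$burn_in_s,
                          sample_khz = sv$sample_khz, rtol = sv$rtol,
                          atol = sv$atol, hmax = sv$hmax)
  feats <- segment_features(tr, window_s = analysis_window_s,
                            min_prominence = config$analysis$min_prominence)
  trace_path <- file.path(out_dir, "figure2_trace.csv")
  feat_path <- file.path(out_dir, "figure2_features.csv")
  keep <- c("time", "segment", "glucose", "dapagliflozin", "v",
            .acell_current_names)
  utils::write.csv(as.data.frame(tr)[, keep], trace_path, row.names = FALSE)
  utils::write.csv(feats, feat_path, row.names = FALSE)
  side <- write_sidecar(file.path(out_dir, "figure2_meta.json"),
                        config$params, config,
                        list(protocol = "figure2",
                             segments = as.list(proto$label)))
  invisible(list(trace = tr, features = feats,
                 files = c(trace_path, feat_path, side)))
}

#' Per-segment action-potential features of a trace
#'
#' @param trace An `acell_trace`.
#' @param window_s Analysis window at the end of each segment (s);
#'   `NULL` analyses everything after the first 20% of the segment.
#' @param min_prominence Passed to [detect_aps()].
#' @return Data frame, one row per segment.
#' @export
segment_features <- function(trace, window_s = NULL, min_prominence = 5) {
  segs <- unique(trace$segment)
  rows <- lapply(segs, function(s) {
    sub <- trace[trace$segment == s, ]
    t1 <- max(sub$time)
    t0 <- if (is.null(window_s)) min(sub$time) + 0.2 * (t1 - min(sub$time))
          else t1 - window_s
    sub <- sub[sub$time >= t0, ]
    f <- suppressWarnings(detect_aps(sub, min_prominence = min_prominence))
    inter <- mean_interap_sglt2(sub, f)
    data.frame(segment = s, glucose = sub$glucose[1],
               dapagliflozin = sub$dapagliflozin[1], ap_count = f$count,
               frequency_hz = f$frequency,
               mean_amplitude_mv = f$mean_amplitude,
               mean_peak_mv = f$mean_peak_v,
               mean_trough_mv = f$mean_trough_v,
               interap_i_sglt2_pa = inter)
  })
  do.call(rbind, rows)
}

# mean SGLT2 current over the sub-threshold (between-AP) part of a segment
mean_interap_sglt2 <- function(sub, feats) {
  if (!"i_sglt2" %in% names(sub)) return(NA_real_)
  thr <- feats$threshold
  idx <- sub$v < thr
  if (!any(idx)) return(NA_real_)
  mean(sub$i_sglt2[idx])
}

#' Extract aligned per-current action-potential snapshots
#'
#' Simulates the low-glucose, high-glucose and high-glucose-plus-
#' dapagliflozin conditions, extracts one representative action potential
#' per condition (the last complete AP of the analysed window) and writes
#' one aligned per-current CSV per condition. Conditions without detectable
#' APs produce a labelled empty file rather than an error.
#'
#' @inheritParams run_figure2
#' @param window_ms Half-width of the extracted snapshot around the AP
#'   peak (ms).
#' @return Invisibly, a list of per-condition data frames and file paths.
#' @export
run_figure3 <- function(config = load_config(), out_dir = ".",
                        window_ms = 100) {
  stopifnot(inherits(config, "acell_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- list(low = list(glucose = 1, dapa = FALSE),
                high = list(glucose = 11, dapa = FALSE),
                high_dapa = list(glucose = 11, dapa = TRUE))
  sv <- config$solver
  out <- list()
  files <- character(0)
  for (nm in names(conds)) {
    cd <- conds[[nm]]
    pr <- protocol(glucose = cd$glucose, duration = config$protocol$segment_s,
                   dapagliflozin = cd$dapa)
    tr <- simulate_protocol(config$params, pr, burn_in_s = sv$burn_in_s,
                            sample_khz = sv$sample_khz, rtol = sv$rtol,
                            atol = sv$atol, hmax = sv$hmax)
    f <- suppressWarnings(detect_aps(tr))
    path <- file.path(out_dir, paste0("figure3_", nm, ".csv"))
    if (f$count == 0) {
      snap <- data.frame(time_ms = numeric(0), v = numeric(0))
      utils::write.csv(snap, path, row.names = FALSE)
    } else {
      pk <- f$peak_time[max(1L, f$count - 1L)]
      sel <- tr$time >= pk - window_ms / 1000 & tr$time <= pk + window_ms / 1000
      snap <- as.data.frame(tr)[sel, c("time", "v", .acell_current_names)]
      snap$time_ms <- (snap$time - pk) * 1000
      snap$time <- NULL
      snap <- snap[, c("time_ms", "v", .acell_current_names)]
      utils::write.csv(snap, path, row.names = FALSE)
    }
    out[[nm]] <- snap
    files <- c(files, path)
  }
  side <- write_sidecar(file.path(out_dir, "figure3_meta.json"),
                        config$params, config,
                        list(protocol = "figure3"))
  invisible(list(snapshots = out, files = c(files, side)))
}
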