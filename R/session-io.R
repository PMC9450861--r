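# Session plumbing: cycle time-normalization, run summaries, configuration
# round-tripping and flat-file I/O (CSV sensor/stimulation logs, JSON-lines
# event records).

#' Time-normalize one gait cycle to a 0-100% grid
#'
#' Linear interpolation of a cycle's signal onto the canonical 0, 1, ..., 100
#' percent grid (101 samples), the standard representation for averaging gait
#' cycles of different durations.
#'
#' @param x Signal values over one cycle (numeric vector, or data frame whose
#'   first non-`t` column is used).
#' @param t Optional sample times; defaults to an equally spaced grid.
#' @return Data frame `percent` (0:100), `value`, of class `normalized_cycle`.
#' @export
time_normalize <- function(x, t = NULL) {
  if (is.data.frame(x)) {
    if (is.null(t) && "t" %in% names(x)) t <- x$t
    val_cols <- setdiff(names(x), "t")
    x <- x[[val_cols[1L]]]
  }
  n <- length(x)
  if (n < 2L) stop("a cycle needs at least 2 samples", call. = FALSE)
  if (is.null(t)) t <- seq_len(n)
  if (length(t) != n || any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing and match `x`", call. = FALSE)
  }
  u <- (t - t[1L]) / (t[n] - t[1L])
  grid <- seq(0, 1, length.out = 101L)
  structure(data.frame(percent = 0:100,
                       value = stats::approx(u, x, xout = grid)$y),
            class = c("normalized_cycle", "data.frame"))
}

#' Summarize a closed-loop run
#'
#' Deterministic per-channel and per-speed-level aggregation of the
#' adaptation log: mean stimulation time, final parameter values, number of
#' parameter changes, and cycles spent saturated at a parameter bound.
#'
#' @param run An [closed_loop_run()] result (`fes_run`).
#' @return A list of class `fes_run_summary`: `by_channel` (one row per
#'   `side.muscle`), `by_level` (one row per visited speed level, when the
#'   session carried a speed schedule).
#' @export
summarize_session <- function(run) {
  stopifnot(inherits(run, "fes_run"))
  ad <- run$adaptation
  if (!nrow(ad)) {
    return(structure(list(by_channel = ad, by_level = ad),
                     class = "fes_run_summary"))
  }
  st <- run$state
  key <- paste(ad$side, ad$muscle, sep = ".")
  by_channel <- do.call(rbind, lapply(unique(key), function(k) {
    rows <- ad[key == k, ]
    is_lg <- rows$muscle[1L] == "LG"
    data.frame(
      channel = k,
      n_cycles = nrow(rows),
      mean_t_s = mean(rows$t_s),
      tau_final = rows$tau[nrow(rows)],
      tau_changes = sum(diff(rows$tau) != 0),
      tau_saturated = sum(rows$tau <= st$tau_bounds[1] |
                            rows$tau >= st$tau_bounds[2]),
      pw_final = if (is_lg) rows$pw[nrow(rows)] else NA_real_,
      pw_changes = if (is_lg) sum(diff(rows$pw) != 0) else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  rownames(by_channel) <- NULL

  by_level <- NULL
  if (any(is.finite(ad$speed))) {
    # A visited level is a maximal run of constant speed in cycle order.
    one <- ad[ad$side == ad$side[1L] & ad$muscle == ad$muscle[1L], ]
    one <- one[order(one$cycle), ]
    lvl_id <- cumsum(c(1L, diff(one$speed) != 0))
    lvl_of_cycle <- stats::setNames(lvl_id, one$cycle)
    ad$level <- lvl_of_cycle[as.character(ad$cycle)]
    by_level <- do.call(rbind, lapply(sort(unique(ad$level)), function(l) {
      rows <- ad[ad$level == l, ]
      data.frame(level = l, speed = rows$speed[1L],
                 n_cycles = length(unique(rows$cycle)),
                 mean_t_s = mean(rows$t_s),
                 mean_tau = mean(rows$tau),
                 mean_pw = mean(rows$pw[rows$muscle == "LG"]),
                 stringsAsFactors = FALSE)
    }))
    rownames(by_level) <- NULL
  }
  structure(list(by_channel = by_channel, by_level = by_level),
            class = "fes_run_summary")
}

#' @export
print.fes_run_summary <- function(x, ...) {
  cat("Per-channel summary:\n")
  print(x$by_channel, digits = 4)
  if (!is.null(x$by_level)) {
    cat("\nPer-speed-level summary:\n")
    print(x$by_level, digits = 4)
  }
  invisible(x)
}

#' Assemble and round-trip a session configuration
#'
#' Bundles every tunable of the pipeline with the printed defaults of the
#' control laws (learning steps `L = 0.01`, `L_PW = 20` us, dead zones 0.04 s
#' and 2 degrees, `tau` in `[0.01, 1]` s, pulse width in `[250, 500]` us).
#'
#' @param sample_rate Hz.
#' @param fsm An [fsm_config()].
#' @param protocol A [speed_protocol()].
#' @param ilc Named list of iterative-learning constants (any of `L`, `L_pw`,
#'   `dt_threshold`, `dphi_threshold`, `tau_bounds`, `pw_bounds`,
#'   `flip_tau_sign`).
#' @param seed Integer seed.
#' @return A list of class `session_config`.
#' @export
session_config <- function(sample_rate = 100, fsm = fsm_config(),
                           protocol = speed_protocol(), ilc = list(),
                           seed = 1L) {
  defaults <- list(L = 0.01, L_pw = 20, dt_threshold = 0.04,
                   dphi_threshold = 2, tau_bounds = c(0.01, 1),
                   pw_bounds = c(250, 500), flip_tau_sign = FALSE)
  ilc <- utils::modifyList(defaults, ilc)
  structure(list(sample_rate = sample_rate, fsm = unclass(fsm),
                 protocol = unclass(protocol)[c("start", "stop", "step",
                                                "cycles_per_level")],
                 ilc = ilc, seed = as.integer(seed)),
            class = "session_config")
}

#' @rdname session_config
#' @param path YAML file path.
#' @export
write_session_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname session_config
#' @param config A `session_config`.
#' @export
read_session_config <- function(path) {
  y <- yaml::read_yaml(path)
  session_config(sample_rate = y$sample_rate,
                 fsm = do.call(fsm_config, y$fsm),
                 protocol = do.call(speed_protocol, y$protocol),
                 ilc = y$ilc, seed = y$seed)
}

#' Write / read gait event records as JSON lines
#'
#' One JSON object per line: `{"t": <seconds>, "kind": "<event>"}` plus any
#' further columns present (e.g. `side`).
#'
#' @param events Data frame with at least `t` and `kind`.
#' @param path File path.
#' @export
write_events_jsonl <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("t", "kind") %in% names(events)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(t = numeric(0), kind = character(0))
  }
  out
}

#' Write a sensor or stimulation table as flat CSV
#'
#' UTF-8, `.` decimal separator, times rounded to microseconds so files diff
#' cleanly across platforms.
#'
#' @param x Data frame with a `t` column.
#' @param path File path.
#' @export
write_signals_csv <- function(x, path) {
  x$t <- round(x$t, 6)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
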