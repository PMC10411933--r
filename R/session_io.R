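#' Write a session to a plain-text file
#'
#' Sessions are stored as a single inspectable text file with a versioned
#' header and tab-separated sections (`[header]`, `[trials]`, `[samples]`,
#' `[events]`, `[ground_truth]`). The format is lossless for round-tripping
#' simulated sessions; the study's deposited raw data would be ingested
#' through an adapter mapping onto the same layout (see
#' [read_osf_session()]).
#'
#' @param session An `aimkin_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  hdr <- session$header
  hdr$scene <- NULL
  fmt <- function(v) format(v, digits = 17, scientific = FALSE)
  lines <- c(
    "# aimkin session file",
    "[header]",
    unlist(lapply(names(hdr), function(k) {
      if (is.null(hdr[[k]])) character() else sprintf("%s\t%s", k, fmt(hdr[[k]]))
    })),
    unlist(lapply(names(session$header$scene), function(k) {
      sprintf("scene.%s\t%s", k, fmt(session$header$scene[[k]]))
    }))
  )
  for (name in c("trials", "samples", "events", "ground_truth")) {
    df <- session[[name]]
    if (is.null(df)) next
    body <- readr::format_tsv(df)
    lines <- c(lines, sprintf("[%s]", name),
               strsplit(body, "\n", fixed = TRUE)[[1]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a session file
#'
#' Parses and validates a [write_session()] file. Validation enforces the
#' format invariants: per-trial sample and event times strictly sorted,
#' cumulative deltas reproducing the recorded cursor positions to within
#' 1e-9 au, and every successful trial's click lying inside a target-entry
#' interval. Violations raise errors naming the offending trial.
#'
#' @param path Session file path.
#' @param validate Run the invariant checks (default `TRUE`).
#' @return An `aimkin_session`.
#' @export
read_session <- function(path, validate = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  sec_at <- grep("^\\[[a-z_]+\\]$", lines)
  if (length(sec_at) == 0 || lines[sec_at[1]] != "[header]") {
    abort("not a session file: missing [header] section")
  }
  sec_names <- gsub("\\[|\\]", "", lines[sec_at])
  bounds <- c(sec_at, length(lines) + 1)
  chunks <- purrr::map(seq_along(sec_at), function(i) {
    lines[(sec_at[i] + 1):(bounds[i + 1] - 1)]
  })
  names(chunks) <- sec_names

  hdr_kv <- strsplit(chunks$header[nzchar(chunks$header)], "\t", fixed = TRUE)
  header <- list(scene = list())
  for (kv in hdr_kv) {
    key <- kv[1]; val <- kv[2]
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val == "NULL") NULL else val
    if (startsWith(key, "scene.")) {
      header$scene[[sub("^scene\\.", "", key)]] <- parsed
    } else {
      header[[key]] <- parsed
    }
  }

  col_overrides <- list(
    trials = readr::cols(time_limit = readr::col_double(),
                         success = readr::col_logical(),
                         context = readr::col_character(),
                         staircase = readr::col_character()),
    events = readr::cols(event = readr::col_character())
  )
  read_chunk <- function(name) {
    txt <- chunks[[name]]
    if (is.null(txt) || !length(txt[nzchar(txt)])) return(NULL)
    spec <- col_overrides[[name]] %||% readr::cols()
    header_cols <- strsplit(txt[1], "\t", fixed = TRUE)[[1]]
    spec$cols <- spec$cols[intersect(names(spec$cols), header_cols)]
    readr::read_tsv(I(paste(txt, collapse = "\n")), col_types = spec,
                    progress = FALSE)
  }
  session <- structure(
    list(header = header, trials = read_chunk("trials"),
         samples = read_chunk("samples"), events = read_chunk("events"),
         ground_truth = read_chunk("ground_truth")),
    class = "aimkin_session"
  )
  if (validate) validate_session(session)
  session
}

#' Validate session invariants
#'
#' @param session An `aimkin_session`.
#' @param tol Tolerance for delta/position consistency, au.
#' @return `session`, invisibly; errors name the offending trial.
#' @export
validate_session <- function(session, tol = 1e-9) {
  if (is.null(session$trials)) return(invisible(session))
  sm_by <- if (!is.null(session$samples)) {
    split(session$samples, session$samples$trial)
  } else list()
  ev_by <- if (!is.null(session$events)) {
    split(session$events, session$events$trial)
  } else list()
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    id <- as.character(tr$trial)
    sm <- sm_by[[id]]
    if (!is.null(sm)) {
      if (is.unsorted(sm$t_ms, strictly = TRUE)) {
        abort(sprintf("trial %s: sample timestamps not strictly increasing",
                      id))
      }
      sx <- tr$start_x %||% 0
      sy <- tr$start_y %||% 0
      if (max(abs(sx + cumsum(sm$dx) - sm$x),
              abs(sy + cumsum(sm$dy) - sm$y)) > tol) {
        abort(sprintf("trial %s: cumulative deltas do not reproduce cursor positions", id))
      }
    }
    ev <- ev_by[[id]]
    if (!is.null(ev) && is.unsorted(ev$t_ms)) {
      abort(sprintf("trial %s: event timestamps not sorted", id))
    }
    if (isTRUE(tr$success) && !is.null(ev) && !is.null(sm)) {
      click_t <- max(ev$t_ms[ev$event == "click"])
      ent <- target_entries(sm, c(tr$target_x, tr$target_y),
                            (session$header$scene$target_diameter %||% 0.2) / 2)
      ok <- nrow(ent) > 0 && any(
        ent$entry_t <= click_t + tol &
          (is.na(ent$exit_t) | ent$exit_t >= click_t - tol)
      )
      if (!ok) {
        abort(sprintf("trial %s: successful click outside any target-entry interval", id))
      }
    }
  }
  invisible(session)
}

#' Read/write an analysis configuration
#'
#' A YAML configuration fully determines the scene geometry, performer
#' parameters, segmentation constants and screening thresholds; defaults
#' reproduce the task constants (0.5 au/s onset threshold, 30 ms staircase
#' step, 300/1,500 ms starts, 0.4/0.6/0.8 au distances, the 45-degree angle
#' grid, 1 au workspace cap, 95% ellipse coverage, 3 MADs with constant
#' 1.4826, 30/10 fps screening rules).
#'
#' @param path YAML file path.
#' @return For `read_config()`, a list with elements `scene`, `performer`,
#'   `segmentation`, `screening` (missing elements filled with defaults).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_config()
  out <- defaults
  for (grp in names(defaults)) {
    if (!is.null(raw[[grp]])) out[[grp]][names(raw[[grp]])] <- raw[[grp]]
  }
  out
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    scene = unclass(scene_config()),
    performer = unclass(performer_params())[
      setdiff(names(performer_params()), "bias_table")],
    segmentation = list(threshold = 0.5, min_frac = 0.5, window = 3),
    screening = list(min_fps = 30, max_fps_diff = 10, stabilization_tol = 0.10,
                     mad_k = 3, mad_constant = 1.4826),
    task = list(staircase_step = 30, staircase_starts = c(300, 1500),
                exp1_distance = 1, exp2_distances = c(0.4, 0.6, 0.8),
                angles = seq(0, 315, by = 45), max_radius = 1,
                ellipse_coverage = 0.95)
  )
}

#' Adapter stub for the public study deposit
#'
#' The study's raw data are publicly deposited (OSF) in a schema that is not
#' mirrored here. This stub documents where an ingest adapter would plug in:
#' a mapping from the deposited per-trial logs onto the session layout used
#' by this package (trials/samples/events tables in plane coordinates).
#'
#' @param path Path to a downloaded deposit.
#' @return Never returns; raises a not-implemented error.
#' @export
read_osf_session <- function(path) {
  abort(paste(
    "ingest of the deposited raw data is not implemented:",
    "map the deposit's per-trial logs onto the session layout",
    "(trials/samples/events) and call validate_session()"
  ))
}
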