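#' Specimen metadata
#'
#' Identity, geometry and rupture status of one tissue specimen. The
#' undeformed cross-sectional area S0 (mm^2) defaults to thickness x width;
#' the gauge length l0 (mm) is the initial clamp-to-clamp distance. Optional
#' `ultimate_strain` / `ultimate_stress` carry values measured at rupture.
#'
#' @param id specimen identifier (single string).
#' @param status `"ruptured"`, `"unruptured"` or `"not_applicable"` (e.g. a
#'   healthy artery control).
#' @param thickness,width specimen thickness and width in mm (> 0).
#' @param cross_section_area S0 in mm^2 (> 0); default `thickness * width`.
#' @param gauge_length_l0 gauge length l0 in mm (> 0).
#' @param ultimate_strain,ultimate_stress optional rupture-point values
#'   (dimensionless; MPa).
#' @return an object of class `specimen_meta`.
#' @export
specimen_meta <- function(id, status = c("ruptured", "unruptured", "not_applicable"),
                          thickness, width,
                          cross_section_area = thickness * width,
                          gauge_length_l0,
                          ultimate_strain = NA_real_,
                          ultimate_stress = NA_real_) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort_validation("`id` must be a non-empty string")
  }
  status <- match.arg(status)
  check_number(thickness, "thickness", lower = 0, strict = TRUE)
  check_number(width, "width", lower = 0, strict = TRUE)
  check_number(cross_section_area, "cross_section_area", lower = 0, strict = TRUE)
  check_number(gauge_length_l0, "gauge_length_l0", lower = 0, strict = TRUE)
  structure(list(id = id, status = status, thickness = thickness,
                 width = width, cross_section_area = cross_section_area,
                 gauge_length_l0 = gauge_length_l0,
                 ultimate_strain = as.numeric(ultimate_strain),
                 ultimate_stress = as.numeric(ultimate_stress)),
            class = "specimen_meta")
}

#' Raw tensile-machine record
#'
#' One specimen's machine record: rows of (force \[N\], crosshead
#' displacement \[mm\], programmed stage index), plus the specimen metadata.
#'
#' @param force,displacement numeric vectors (N; mm), equal length, finite.
#' @param stage integer stage indices, non-negative and non-decreasing in
#'   file order, or `NULL` when the machine wrote no stage column.
#' @param meta a [specimen_meta()].
#' @return an object of class `raw_test`.
#' @export
raw_test <- function(force, displacement, stage = NULL, meta) {
  if (!inherits(meta, "specimen_meta")) abort_validation("`meta` must be specimen_meta()")
  force <- as.numeric(force); displacement <- as.numeric(displacement)
  n <- length(force)
  if (n == 0L) abort_validation("raw test must have at least one row")
  if (length(displacement) != n) abort_validation("force/displacement length mismatch")
  if (any(!is.finite(displacement)) || any(!is.finite(force))) {
    abort_validation("force and displacement must be finite")
  }
  if (!is.null(stage)) {
    stage <- as.integer(stage)
    if (length(stage) != n) abort_validation("stage length mismatch")
    if (any(is.na(stage)) || any(stage < 0L)) {
      abort_validation("stage indices must be non-negative integers")
    }
    if (is.unsorted(stage)) {
      abort_validation("stage indices must be non-decreasing in file order")
    }
  }
  structure(list(force = force, displacement = displacement,
                 stage = stage, meta = meta),
            class = "raw_test")
}

#' @export
print.raw_test <- function(x, ...) {
  cat(sprintf("<raw_test> specimen %s: %d rows, %s\n", x$meta$id,
              length(x$force),
              if (is.null(x$stage)) "no stage column"
              else sprintf("%d stage(s)", length(unique(x$stage)))))
  invisible(x)
}

#' Stress-stretch curve
#'
#' Paired stretch ratio lambda = l/l0 and nominal stress sigma = F/S0 (MPa)
#' for one loading stage, sorted by strictly increasing lambda >= 1.
#'
#' @param stretch,stress equal-length numeric vectors; `stretch` must be
#'   finite, >= 1 and strictly increasing, `stress` finite.
#' @param specimen_id specimen identifier.
#' @param stage integer stage index.
#' @return an object of class `tensile_curve`.
#' @export
tensile_curve <- function(stretch, stress, specimen_id = "specimen", stage = 1L) {
  stretch <- as.numeric(stretch); stress <- as.numeric(stress)
  n <- length(stretch)
  if (n < 1L || length(stress) != n) {
    abort_validation("stretch and stress must be non-empty and equal length")
  }
  if (any(!is.finite(stretch)) || any(stretch < 1)) {
    abort_validation("stretch must be finite and >= 1")
  }
  if (n > 1L && any(diff(stretch) <= 0)) {
    abort_validation("stretch must be strictly increasing")
  }
  if (any(!is.finite(stress))) abort_validation("stress must be finite")
  structure(list(stretch = stretch, stress = stress,
                 specimen_id = as.character(specimen_id),
                 stage = as.integer(stage)),
            class = "tensile_curve")
}

#' @export
print.tensile_curve <- function(x, ...) {
  cat(sprintf("<tensile_curve> %s stage %d: %d points, lambda [%.4f, %.4f], sigma max %.4g MPa\n",
              x$specimen_id, x$stage, length(x$stretch),
              min(x$stretch), max(x$stretch), max(x$stress)))
  invisible(x)
}

#' @export
as.data.frame.tensile_curve <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id, stage = x$stage,
             lambda = x$stretch, stress_MPa = x$stress)
}

#' Read a raw tensile-machine CSV
#'
#' Reads a UTF-8 CSV with a header row into a [raw_test()]. Column names
#' are configurable; the stage column is optional (its absence means the
#' record is treated as a single programmed stage by [segment_stages()]).
#'
#' @param path path to the CSV file.
#' @param meta a [specimen_meta()] for the specimen the file belongs to.
#' @param columns named character vector mapping roles to header names;
#'   defaults `c(force = "force_N", displacement = "displacement_mm",
#'   stage = "stage")`.
#' @return a [raw_test()] with one row per data line, in file order.
#' @export
load_raw_csv <- function(path, meta,
                         columns = c(force = "force_N",
                                     displacement = "displacement_mm",
                                     stage = "stage")) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (role in c("force", "displacement")) {
    if (!(columns[[role]] %in% names(df))) {
      abort_format(sprintf("column '%s' (%s) missing in %s",
                           columns[[role]], role, path))
    }
  }
  parse_col <- function(role) {
    raw <- df[[columns[[role]]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      abort_parse(sprintf(
        "non-numeric value '%s' in column '%s' at line %d of %s",
        raw[bad[1]], columns[[role]], bad[1], path))
    }
    val
  }
  force <- parse_col("force")
  displacement <- parse_col("displacement")
  stage <- NULL
  if (!is.na(columns["stage"]) && columns[["stage"]] %in% names(df)) {
    stage <- parse_col("stage")
  }
  raw_test(force, displacement, stage, meta)
}

#' Read the specimen metadata sidecar CSV
#'
#' One record per specimen with columns `id, status, thickness_mm, width_mm,
#' area_mm2, gauge_length_mm` and optional `ultimate_strain,
#' ultimate_stress_MPa`. An empty `area_mm2` defaults to thickness x width.
#'
#' @param path path to the metadata CSV.
#' @return a named list of [specimen_meta()] objects, keyed by id.
#' @export
load_metadata_csv <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "status", "thickness_mm", "width_mm", "gauge_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_format(sprintf("metadata %s lacks column(s): %s", path,
                         paste(miss, collapse = ", ")))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    area <- if ("area_mm2" %in% names(df) && is.finite(df$area_mm2[i])) {
      df$area_mm2[i]
    } else {
      df$thickness_mm[i] * df$width_mm[i]
    }
    specimen_meta(
      id = as.character(df$id[i]), status = df$status[i],
      thickness = df$thickness_mm[i], width = df$width_mm[i],
      cross_section_area = area, gauge_length_l0 = df$gauge_length_mm[i],
      ultimate_strain = if ("ultimate_strain" %in% names(df))
        df$ultimate_strain[i] else NA_real_,
      ultimate_stress = if ("ultimate_stress_MPa" %in% names(df))
        df$ultimate_stress_MPa[i] else NA_real_)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Convert a raw record to a stress-stretch curve
#'
#' Applies sigma_i = F_i / S0 (N/mm^2 = MPa) and lambda_i = 1 + d_i / l0.
#' Rows with lambda < 1 (slack take-up at clamp engagement) are dropped
#' (their count is attached as attribute `n_dropped`); the result is sorted
#' by lambda with duplicate lambda values collapsed by averaging sigma.
#'
#' @param raw a [raw_test()] (typically one stage segment).
#' @return a [tensile_curve()].
#' @export
to_curve <- function(raw) {
  stopifnot(inherits(raw, "raw_test"))
  meta <- raw$meta
  lam <- 1 + raw$displacement / meta$gauge_length_l0
  sig <- raw$force / meta$cross_section_area
  keep <- lam >= 1
  n_dropped <- sum(!keep)
  lam <- lam[keep]; sig <- sig[keep]
  if (length(lam) == 0L) {
    abort_validation(sprintf(
      "specimen %s: all rows dropped (every lambda < 1)", meta$id))
  }
  o <- order(lam)
  lam <- lam[o]; sig <- sig[o]
  grp <- cumsum(c(TRUE, diff(lam) > 0))
  lam_u <- as.numeric(tapply(lam, grp, `[`, 1L))
  sig_u <- as.numeric(tapply(sig, grp, mean))
  stage <- if (is.null(raw$stage)) 1L else raw$stage[which(keep)[1L]]
  out <- tensile_curve(lam_u, sig_u, specimen_id = meta$id, stage = stage)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Split a raw record into programmed loading stages
#'
#' Splits on the stage column when the record has one; otherwise a new stage
#' begins wherever the displacement returns below `return_fraction` of the
#' maximum displacement seen in the stage so far (the clamps going back to
#' the programmed origin). Every input row is assigned to exactly one stage;
#' a single stage is a valid result.
#'
#' @param raw a [raw_test()].
#' @param return_fraction return-to-origin tolerance as a fraction of the
#'   preceding stage maximum (default 0.02, robust to machine noise).
#' @return a list of [raw_test()] objects, one per stage, in order.
#' @export
segment_stages <- function(raw, return_fraction = 0.02) {
  stopifnot(inherits(raw, "raw_test"))
  check_number(return_fraction, "return_fraction", lower = 0)
  n <- length(raw$force)
  if (!is.null(raw$stage)) {
    ids <- raw$stage
  } else {
    ids <- integer(n)
    cur <- 0L
    run_max <- -Inf
    prev <- -Inf
    for (i in seq_len(n)) {
      d <- raw$displacement[i]
      if (is.finite(run_max) && run_max > 0 &&
          d <= return_fraction * run_max && d < prev) {
        cur <- cur + 1L
        run_max <- -Inf
      }
      ids[i] <- cur
      run_max <- max(run_max, d)
      prev <- d
    }
  }
  unname(lapply(split(seq_len(n), ids), function(ix) {
    raw_test(raw$force[ix], raw$displacement[ix],
             if (is.null(raw$stage)) NULL else raw$stage[ix], raw$meta)
  }))
}

# Split the rows of one stage into loading cycles: a new cycle starts where
# displacement falls back at/below the return fraction of the cycle maximum.
split_cycles <- function(raw, return_fraction = 0.02) {
  n <- length(raw$force)
  ids <- integer(n)
  cur <- 0L
  run_max <- -Inf
  prev <- -Inf
  for (i in seq_len(n)) {
    d <- raw$displacement[i]
    if (is.finite(run_max) && run_max > 0 &&
        d <= return_fraction * run_max && d < prev) {
      cur <- cur + 1L
      run_max <- -Inf
    }
    ids[i] <- cur
    run_max <- max(run_max, d)
    prev <- d
  }
  unname(lapply(split(seq_len(n), ids), function(ix) {
    raw_test(raw$force[ix], raw$displacement[ix],
             if (is.null(raw$stage)) NULL else raw$stage[ix], raw$meta)
  }))
}

#' Discard preconditioning cycles
#'
#' Biological tissue softens over the first loading cycles of each
#' programmed elongation step; only the last (repeatable) cycle of a step is
#' informative. Within each step the first `min(n_cycles, available - 1)`
#' cycles are discarded and the last cycle is always kept.
#'
#' The input may be either a list of [raw_test()] stage segments (each
#' possibly containing several cycles, split internally at displacement
#' resets) or a list of [tensile_curve()] cycles (grouped into steps by
#' equal target stretch, consecutive curves whose maximum stretch agrees
#' within `target_tol` relative).
#'
#' @param stages list of [raw_test()] or of [tensile_curve()] objects.
#' @param n_cycles number of preconditioning cycles to drop per step
#'   (default 2; at most two are needed in practice).
#' @param target_tol relative tolerance for grouping curves by target
#'   stretch.
#' @return a list of the same type as the input, preconditioning removed.
#' @export
drop_preconditioning <- function(stages, n_cycles = 2L, target_tol = 0.01) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 0) {
    abort_validation("`n_cycles` must be a single number >= 0")
  }
  n_cycles <- as.integer(n_cycles)
  if (length(stages) == 0L) return(stages)
  if (all(vapply(stages, inherits, TRUE, "raw_test"))) {
    lapply(stages, function(stg) {
      cycles <- split_cycles(stg)
      k <- length(cycles)
      drop_n <- min(n_cycles, k - 1L)
      kept <- cycles[(drop_n + 1L):k]
      # re-join the kept cycles of the step into one record
      raw_test(unlist(lapply(kept, `[[`, "force")),
               unlist(lapply(kept, `[[`, "displacement")),
               if (is.null(stg$stage)) NULL
               else unlist(lapply(kept, `[[`, "stage")),
               stg$meta)
    })
  } else if (all(vapply(stages, inherits, TRUE, "tensile_curve"))) {
    targets <- vapply(stages, function(cv) max(cv$stretch), 0)
    grp <- cumsum(c(TRUE, abs(diff(targets)) >
                      target_tol * pmax(abs(targets[-length(targets)]), 1)))
    kept <- unlist(lapply(split(seq_along(stages), grp), function(ix) {
      k <- length(ix)
      ix[(min(n_cycles, k - 1L) + 1L):k]
    }), use.names = FALSE)
    stages[sort(kept)]
  } else {
    abort_validation("`stages` must be a list of raw_test or tensile_curve objects")
  }
}

#' Truncate a curve at the onset of the plasticity plateau
#'
#' Hyperelastic models are only meaningful up to the plateau after which
#' plasticity starts. The local slope d sigma / d lambda is estimated as the
#' secant over a centered window of `window` points (half-width
#' `h = floor(window / 2)`); at the first index where that slope falls below
#' `slope_fraction` times the maximum slope seen so far, the curve is cut at
#' the window's left edge (index `i - h`), which centers the cut on the knee
#' instead of lagging it by the half-width. If the slope never falls below
#' the threshold the curve is returned unchanged.
#'
#' @param curve a [tensile_curve()] with at least `2 * window` points.
#' @param slope_fraction slope-collapse threshold relative to the running
#'   maximum slope (default 0.1; 0 disables truncation).
#' @param window moving-window length in points (default 5).
#' @return a non-empty prefix of `curve`.
#' @export
truncate_at_plateau <- function(curve, slope_fraction = 0.1, window = 5L) {
  stopifnot(inherits(curve, "tensile_curve"))
  check_number(slope_fraction, "slope_fraction", lower = 0)
  n <- length(curve$stretch)
  window <- as.integer(window)
  if (window < 2L) abort_validation("`window` must be >= 2")
  if (n < 2L * window) {
    abort_validation(sprintf(
      "curve has %d points; plateau detection needs at least %d (2 * window)",
      n, 2L * window))
  }
  if (slope_fraction == 0) return(curve)
  h <- window %/% 2L
  max_slope <- -Inf
  for (i in (1L + h):(n - h)) {
    sl <- (curve$stress[i + h] - curve$stress[i - h]) /
      (curve$stretch[i + h] - curve$stretch[i - h])
    if (is.finite(max_slope) && max_slope > 0 &&
        sl < slope_fraction * max_slope) {
      cut <- max(i - h, 2L)
      return(tensile_curve(curve$stretch[1:cut], curve$stress[1:cut],
                           curve$specimen_id, curve$stage))
    }
    max_slope <- max(max_slope, sl)
  }
  curve
}

#' Tidy export of curves
#'
#' @param curves a list of [tensile_curve()] objects.
#' @param path output CSV path with columns
#'   `specimen_id, stage, lambda, stress_MPa`.
#' @return the written data frame, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
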