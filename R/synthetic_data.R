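# Seeded RNG scoping: run `expr` under a local seed without disturbing the
# caller's RNG stream. A NULL seed leaves the global stream in use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic tensile-test generator configuration
#'
#' States the world the generator emulates: a model-governed elastic
#' response up to an optional cut stretch, a plateau tail beyond it,
#' additive Gaussian measurement noise on stress, a multi-stage loading
#' programme with up to a few preconditioning cycles per stage, and
#' specimen geometry for the force/displacement encoding.
#'
#' @param coeffs a [coefficient_set()] governing the elastic response.
#' @param lambda_max maximum stretch of the programme (> 1).
#' @param n_points number of points on the uniform stretch grid (>= 2).
#' @param noise_sd additive Gaussian noise on stress, MPa (>= 0).
#' @param plateau_at optional stretch lambda_c at which the elastic response
#'   gives way to a plateau; `NULL` for none.
#' @param plateau_slope slope (MPa per unit stretch) of the plateau tail.
#' @param stages number of programmed elongation steps (>= 1).
#' @param preconditioning_cycles preconditioning cycles per step (0..5).
#' @param softening first-cycle stress inflation factor (default 0.2 =
#'   20%), decaying geometrically by `softening_decay` per cycle and exactly
#'   1 on the kept (last) cycle.
#' @param softening_decay geometric decay of the softening per cycle.
#' @param gauge_length_l0,cross_section_area specimen geometry (mm; mm^2)
#'   used to encode curves as force/displacement records.
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(coeffs,
                             lambda_max = 2.2,
                             n_points = 200L,
                             noise_sd = 0,
                             plateau_at = NULL,
                             plateau_slope = 0,
                             stages = 1L,
                             preconditioning_cycles = 0L,
                             softening = 0.2,
                             softening_decay = 0.5,
                             gauge_length_l0 = 10,
                             cross_section_area = 0.66,
                             seed = NULL) {
  if (!inherits(coeffs, "coefficient_set")) {
    abort_validation("`coeffs` must be a coefficient_set()")
  }
  problems <- character(0)
  if (!is.numeric(lambda_max) || lambda_max <= 1) problems <- c(problems, "lambda_max must be > 1")
  if (!is.numeric(n_points) || n_points < 2) problems <- c(problems, "n_points must be >= 2")
  if (!is.numeric(noise_sd) || noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (!is.null(plateau_at) &&
      (!is.numeric(plateau_at) || plateau_at <= 1 || plateau_at >= lambda_max)) {
    problems <- c(problems, "plateau_at must lie in (1, lambda_max)")
  }
  if (!is.numeric(stages) || stages < 1) problems <- c(problems, "stages must be >= 1")
  if (!is.numeric(preconditioning_cycles) || preconditioning_cycles < 0 ||
      preconditioning_cycles > 5) {
    problems <- c(problems, "preconditioning_cycles must be in 0..5")
  }
  if (!is.numeric(gauge_length_l0) || gauge_length_l0 <= 0) problems <- c(problems, "gauge_length_l0 must be > 0")
  if (!is.numeric(cross_section_area) || cross_section_area <= 0) problems <- c(problems, "cross_section_area must be > 0")
  if (length(problems)) {
    abort_validation(paste0("invalid generator config: ",
                            paste(problems, collapse = "; ")))
  }
  structure(list(coeffs = coeffs, lambda_max = lambda_max,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 plateau_at = plateau_at, plateau_slope = plateau_slope,
                 stages = as.integer(stages),
                 preconditioning_cycles = as.integer(preconditioning_cycles),
                 softening = softening, softening_decay = softening_decay,
                 gauge_length_l0 = gauge_length_l0,
                 cross_section_area = cross_section_area,
                 seed = seed),
            class = "generator_config")
}

# Noise-free mean stress response of a config at given stretches.
model_response <- function(config, lam) {
  sig <- uniaxial_stress(config$coeffs, lam)
  if (!is.null(config$plateau_at)) {
    cut <- lam > config$plateau_at
    if (any(cut)) {
      sig_c <- uniaxial_stress(config$coeffs, config$plateau_at)
      sig[cut] <- sig_c + config$plateau_slope * (lam[cut] - config$plateau_at)
    }
  }
  sig
}

#' Generate a synthetic stress-stretch curve
#'
#' Evaluates the configured model on a uniform stretch grid over
#' `[1, lambda_max]`, continues it with the plateau tail beyond
#' `plateau_at` (continuous at the knee), adds `N(0, noise_sd)` measurement
#' noise clipped at zero stress, and returns a [tensile_curve()].
#' Bit-reproducible for a fixed `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @param specimen_id,stage identity stamped on the output curve.
#' @return a [tensile_curve()] of length `n_points`.
#' @export
generate_curve <- function(config, specimen_id = "synthetic", stage = 1L) {
  stopifnot(inherits(config, "generator_config"))
  lam <- seq(1, config$lambda_max, length.out = config$n_points)
  sig <- model_response(config, lam)
  if (config$noise_sd > 0) {
    sig <- with_seed(config$seed,
                     pmax(sig + stats::rnorm(length(sig), 0, config$noise_sd), 0))
  }
  tensile_curve(lam, sig, specimen_id = specimen_id, stage = stage)
}

#' Generate a full multi-stage machine record
#'
#' Emits force/displacement/stage rows for `stages` programmed elongation
#' steps with increasing targets (step s reaches
#' `1 + s (lambda_max - 1) / stages`). Each step is preceded by
#' `preconditioning_cycles` repeat loadings to the same target whose stress
#' is inflated by the softening factor (first cycle `1 + softening`,
#' decaying geometrically, exactly 1 on the kept last cycle); the clamps
#' return to the origin between cycles, so each cycle's displacement ramp
#' restarts at 0. The encoding is the exact inverse of [to_curve()]:
#' `force = sigma * S0`, `displacement = (lambda - 1) * l0`.
#'
#' @param config a [generator_config()].
#' @param meta optional [specimen_meta()]; default is built from the
#'   config's geometry with status `"not_applicable"`.
#' @return a [raw_test()] with a stage column.
#' @export
generate_specimen_series <- function(config, meta = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(meta)) {
    meta <- specimen_meta(id = "synthetic", status = "not_applicable",
                          thickness = 1, width = config$cross_section_area,
                          cross_section_area = config$cross_section_area,
                          gauge_length_l0 = config$gauge_length_l0)
  }
  n_per_stage <- max(2L, ceiling(config$n_points / config$stages))
  build <- function() {
    force <- displacement <- numeric(0)
    stage_ix <- integer(0)
    n_pre <- config$preconditioning_cycles
    for (s in seq_len(config$stages)) {
      lam_target <- 1 + s * (config$lambda_max - 1) / config$stages
      lam <- seq(1, lam_target, length.out = n_per_stage)
      base <- model_response(config, lam)
      for (cyc in seq_len(n_pre + 1L)) {
        factor <- if (cyc <= n_pre) {
          1 + config$softening * config$softening_decay^(cyc - 1L)
        } else 1
        sig <- base * factor
        if (config$noise_sd > 0) {
          sig <- pmax(sig + stats::rnorm(length(sig), 0, config$noise_sd), 0)
        }
        force <- c(force, sig * meta$cross_section_area)
        displacement <- c(displacement, (lam - 1) * meta$gauge_length_l0)
        stage_ix <- c(stage_ix, rep(s, length(lam)))
      }
    }
    raw_test(force, displacement, stage_ix, meta)
  }
  with_seed(config$seed, build())
}

#' Generate a synthetic ruptured/unruptured cohort
#'
#' Emulates the cohort-level structure the analysis assumes: per-specimen
#' ultimate stresses are drawn from log-normal distributions whose medians
#' differ by `stress_ratio` between the groups (unruptured stronger),
#' ultimate strains from a common log-normal (no group difference), and
#' each specimen's record is built with a Neo-Hookean response scaled to
#' rupture -- terminate -- at its drawn ultimate point.
#'
#' @param n_ruptured,n_unruptured group sizes (>= 1).
#' @param stress_ratio ratio of unruptured to ruptured median ultimate
#'   stress (> 0; 1 means the groups are identical in law).
#' @param seed integer seed.
#' @param median_stress ruptured-group median ultimate stress, MPa.
#' @param sdlog_stress log-scale spread of ultimate stress (see the methods
#'   vignette for the choice of default).
#' @param median_strain,sdlog_strain log-normal parameters of the common
#'   ultimate-strain distribution.
#' @param n_points points per specimen record.
#' @param noise_sd additive stress noise, MPa.
#' @return a list of `n_ruptured + n_unruptured` elements, each a list with
#'   `meta` (a [specimen_meta()], ultimate values filled in) and `raw`
#'   (a [raw_test()]).
#' @export
generate_cohort <- function(n_ruptured, n_unruptured, stress_ratio = 1,
                            seed = NULL,
                            median_stress = 1.0, sdlog_stress = 0.35,
                            median_strain = 1.3, sdlog_strain = 0.35,
                            n_points = 60L, noise_sd = 0) {
  if (!is.numeric(n_ruptured) || n_ruptured < 1 ||
      !is.numeric(n_unruptured) || n_unruptured < 1) {
    abort_validation("group sizes must be >= 1")
  }
  check_number(stress_ratio, "stress_ratio", lower = 0, strict = TRUE)
  status <- c(rep("ruptured", n_ruptured), rep("unruptured", n_unruptured))
  build <- function() {
    lapply(seq_along(status), function(i) {
      st <- status[i]
      med <- if (st == "unruptured") median_stress * stress_ratio else median_stress
      sig_r <- stats::rlnorm(1, meanlog = log(med), sdlog = sdlog_stress)
      eps_r <- stats::rlnorm(1, meanlog = log(median_strain), sdlog = sdlog_strain)
      lam_r <- 1 + eps_r
      # Neo-Hookean response scaled to reach sig_r exactly at lam_r
      c1 <- sig_r / (2 * (lam_r - lam_r^-2))
      meta <- specimen_meta(id = sprintf("S%02d_%s", i, substr(st, 1, 3)),
                            status = st, thickness = 0.2, width = 3,
                            gauge_length_l0 = 10,
                            ultimate_strain = eps_r, ultimate_stress = sig_r)
      cfg <- generator_config(coefficient_set("NEO_HOOKEAN", c1),
                              lambda_max = lam_r, n_points = n_points,
                              noise_sd = noise_sd, seed = NULL)
      raw <- generate_specimen_series(cfg, meta = meta)
      list(meta = meta, raw = raw)
    })
  }
  with_seed(seed, build())
}
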