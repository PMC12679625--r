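#' Pipeline configuration
#'
#' Central list of every tunable parameter of the per-participant pipeline,
#' with the package defaults. A YAML file with (a subset of) the same nested
#' keys can be supplied instead; unknown keys are rejected.
#'
#' @param ... Named overrides of the nested defaults, e.g.
#'   `filter = list(cutoff_hz = 8)`.
#' @param file Optional path to a YAML file of overrides.
#' @return A `gait_config` nested list.
#' @export
gait_config <- function(..., file = NULL) {
  defaults <- list(
    axis_map = c(ml = "x", ap = "y", vert = "z"),
    trim_strides = 2,
    filter = list(cutoff_hz = 10, order = 4),
    events = list(min_stride_s = 1, prominence_m = 0.05),
    embed = list(tau = "auto", n = "auto", max_n = 8,
                 fnn_threshold = 0.05, ami_bins = NULL),
    lf = list(anchor_side = "left", embed_n = 0, n_phases = 24,
              energy = 0.99, min_stride_pairs = NULL, cond_max = 1e8),
    rosenstein = list(fit_fraction = 0.5, theiler_strides = 1,
                      max_refs = 1000)
  )
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- modifyList(yaml::read_yaml(file), overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, overrides), class = "gait_config")
}

#' Run the full stability pipeline for one participant
#'
#' Executes, per trial: complete-frame filtering, CoM/CoP surrogates, the
#' relative M/L signal y(t), gait-event detection, boundary-stride trimming
#' and per-trial mean normalization; then stitches the trials, low-pass
#' filters the stitched record, differentiates to the phase trajectory,
#' selects the embedding delay (first AMI minimum) and dimension (false
#' nearest neighbours), embeds, estimates the monodromy/Floquet spectrum
#' over the median stride period, computes the Rosenstein short-term
#' exponent, and assesses stability. The requested embedding dimension is
#' capped so that the monodromy fit keeps more anchor pairs than unknown
#' state dimensions (with a warning when the cap binds).
#'
#' @param trials List of [marker_set()] trials for one participant, or a
#'   single marker set.
#'
#' Two state representations serve the two estimators. The monodromy fit
#' uses the planar section state m(t) = \[Y, dY/dt\] (`lf$embed_n = 0`): on
#' a stride-anchored Poincare section the cycle phase is pinned by the
#' section itself, the planar state spans the transverse dynamics of the
#' medio-lateral sway model, and every added delay block multiplies the d^2
#' fit parameters resting on ~20 stride pairs while contributing
#' noise-dominated directions whose spurious multipliers distort the
#' spectrum. The neighbour-based Rosenstein estimator, by contrast, needs a
#' fully unfolded attractor, so it runs on the optimized delay embedding
#' (AMI first-minimum delay, false-nearest-neighbour dimension).
#'
#' @param participant_id Identifier copied into the output row.
#' @param config A [gait_config()].
#' @return One-row tibble of metrics (`mean_FM`, `max_LE_L`, `max_LE_S`,
#'   cadence, stride time, stride count, embedding parameters, diagnostics,
#'   stability flags) with the fitted `gait_monodromy` and
#'   `gait_rosenstein` objects attached as attribute `details`.
#' @export
run_participant <- function(trials, participant_id = NA_character_,
                            config = gait_config()) {
  if (inherits(trials, "marker_set")) {
    trials <- list(trials)
  }
  if (length(trials) == 0L) {
    stop_validation("no trials supplied.")
  }
  side <- match.arg(config$lf$anchor_side, c("left", "right"))
  prep <- lapply(seq_along(trials), function(i) {
    mts <- trials[[i]]
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort(sprintf("participant %s, trial %d, stage `%s`: %s",
                      participant_id, i, what, conditionMessage(e)),
              class = class(e)[1])
      })
    }
    mts <- step("drop_invalid_frames", drop_invalid_frames(mts))
    y <- step("relative_ml_signal",
              relative_ml_signal(com_surrogate(mts), cop_surrogate(mts)))
    ev <- step("detect_gait_events",
               detect_gait_events(mts,
                                  min_stride_s = config$events$min_stride_s,
                                  prominence_m = config$events$prominence_m))
    y <- step("trim_boundary_strides",
              trim_boundary_strides(y, ev, n_trim = config$trim_strides,
                                    side = side))
    list(y = mean_normalize(y), events = ev)
  })
  stitched <- stitch_trials(lapply(prep, `[[`, "y"))
  filtered <- lowpass_filter(stitched, cutoff = config$filter$cutoff_hz,
                             order = config$filter$order)
  stride_time <- median(unlist(lapply(prep, function(p) p$events$stride_times)))
  cadence <- mean(vapply(prep, function(p) p$events$cadence, numeric(1)))
  n_strides <- length(stride_anchors(filtered)) - length(prep)

  phase <- differentiate(filtered)
  tau <- config$embed$tau
  if (identical(tau, "auto")) {
    tau <- optimal_delay(filtered, bins = config$embed$ami_bins)
  }
  n_emb <- config$embed$n
  if (identical(n_emb, "auto")) {
    n_emb <- optimal_dimension(phase, tau = tau,
                               max_n = config$embed$max_n,
                               threshold = config$embed$fnn_threshold,
                               stride_time = stride_time)
  }
  emb_lf <- delay_embed(phase, tau = max(1L, tau), n = config$lf$embed_n,
                        stride_time = stride_time)
  mono <- estimate_monodromy(emb_lf,
                             min_pairs = config$lf$min_stride_pairs,
                             n_phases = config$lf$n_phases,
                             energy = config$lf$energy,
                             cond_max = config$lf$cond_max)
  emb <- delay_embed(phase, tau = tau, n = n_emb, stride_time = stride_time)
  rosen <- rosenstein_le(emb,
                         fit_fraction = config$rosenstein$fit_fraction,
                         theiler_strides = config$rosenstein$theiler_strides,
                         max_refs = config$rosenstein$max_refs)
  stab <- assess_stability(mono, rosen)
  row <- tibble(
    id = participant_id,
    cadence = cadence,
    stride_time_s = stride_time,
    n_strides = n_strides,
    embed_tau = emb$tau,
    embed_n = emb$n,
    mean_FM = mono$mean_abs_fm,
    max_LE_L = mono$max_le_l,
    max_LE_S = rosen$max_le_s,
    condition_number = mono$condition_number,
    rosenstein_r2 = rosen$fit_r2,
    stable_fm = stab$stable_fm,
    stable_le = stab$stable_le
  )
  attr(row, "details") <- list(monodromy = mono, rosenstein = rosen,
                               stability = stab)
  row
}

#' Run the cohort study end-to-end
#'
#' For a marker-level cohort ([simulate_cohort()] or an equivalent structure
#' read from disk), runs [run_participant()] for every participant and joins
#' the metrics to the participant table; a metrics-level table
#' ([simulate_metrics_cohort()] or [read_metrics_table()]) is used as-is.
#' Then reproduces the statistical battery: Welch tests on the
#' demographics, one ANCOVA per stability metric with sex, age and cadence
#' as covariates, post-hoc per-group regressions for every continuous
#' covariate whose ANCOVA effect is significant at p < 0.05 (the trigger is
#' a pure function of the ANCOVA table), and Spearman correlations of each
#' metric with the severity scores when present.
#'
#' @param cohort A `gait_cohort` or a metrics-level data frame.
#' @param config A [gait_config()] (marker-level input only).
#' @param dependents Metric columns to model.
#' @param covariates ANCOVA covariates (default sex, age, cadence).
#' @return A `gait_cohort_report`: `metrics` table, `demographics`,
#'   `ancova` (named list of `gait_ancova`), `ancova_terms` (stacked tidy
#'   table), `posthoc` (triggered regressions), `spearman`.
#' @export
run_cohort <- function(cohort, config = gait_config(),
                       dependents = c("mean_FM", "max_LE_L", "max_LE_S"),
                       covariates = c("sex", "age", "cadence")) {
  if (inherits(cohort, "gait_cohort")) {
    if (is.null(cohort$trials)) {
      stop_validation("cohort carries no marker trials; pass a metrics table instead.")
    }
    metrics <- purrr::map_dfr(seq_along(cohort$trials), function(i) {
      run_participant(cohort$trials[[i]],
                      participant_id = cohort$participants$id[i],
                      config = config)
    })
    table <- dplyr::left_join(
      dplyr::select(cohort$participants, -dplyr::any_of("cadence")),
      metrics, by = "id")
  } else {
    table <- as_tibble(cohort)
  }
  if (min(table(table$group)) < 2L) {
    stop_validation("each group needs at least 2 participants.")
  }
  demo <- demographics_tests(table)
  ancovas <- lapply(dependents,
                    function(dep) ancova(table, dep, covariates = covariates))
  names(ancovas) <- dependents
  terms_tbl <- purrr::map_dfr(dependents, function(dep) {
    dplyr::mutate(tidy(ancovas[[dep]]), dependent = dep, .before = 1L)
  })
  cont_covariates <- intersect(c("age", "cadence"), unique(terms_tbl$term))
  triggered <- terms_tbl[terms_tbl$term %in% cont_covariates &
                           terms_tbl$p.value < 0.05, ]
  posthoc <- if (nrow(triggered) > 0L) {
    purrr::map_dfr(seq_len(nrow(triggered)), function(i) {
      posthoc_regression(table, dependent = triggered$dependent[i],
                         predictor = triggered$term[i])
    })
  } else {
    tibble()
  }
  spearman <- tibble()
  if ("psprs" %in% names(table) &&
      sum(table$group == "PSP" & !is.na(table$psprs)) >= 5L) {
    spearman <- purrr::map_dfr(dependents, function(dep) {
      dplyr::bind_rows(spearman_corr(table, dep, "psprs"),
                       spearman_corr(table, dep, "psprs_gm"))
    })
  }
  structure(list(metrics = table, demographics = demo, ancova = ancovas,
                 ancova_terms = terms_tbl, posthoc = posthoc,
                 spearman = spearman),
            class = "gait_cohort_report")
}

#' @export
print.gait_cohort_report <- function(x, ...) {
  cat("<gait_cohort_report>\n\n== Demographics (Welch) ==\n")
  print(x$demographics)
  cat("\n== ANCOVA terms ==\n")
  print(x$ancova_terms)
  if (nrow(x$posthoc) > 0L) {
    cat("\n== Post-hoc regressions (triggered covariates) ==\n")
    print(x$posthoc)
  }
  if (nrow(x$spearman) > 0L) {
    cat("\n== Spearman vs severity (PSP) ==\n")
    print(x$spearman)
  }
  invisible(x)
}
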