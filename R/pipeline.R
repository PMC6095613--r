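#' Time-shifted surrogate stimuli
#'
#' Circularly shifts each stimulus trace by its stated amount (auditory 60 s,
#' visual 30 s by default), destroying the stimulus-brain alignment while
#' preserving length and spectral content; neural data are untouched.
#' Decomposition maps computed against shifted stimuli estimate the analysis
#' bias expected by chance.
#'
#' @param audio_env,lip_area Stimulus traces ([avp_ts]).
#' @param shift_a_s,shift_v_s Shifts in seconds (defaults 60 and 30); must be
#'   positive multiples of nothing in particular but strictly less than the
#'   trace duration.
#' @return List with shifted `audio_env` and `lip_area`.
#' @export
time_shift_surrogate <- function(audio_env, lip_area, shift_a_s = 60, shift_v_s = 30) {
  stopifnot(inherits(audio_env, "avp_ts"), inherits(lip_area, "avp_ts"))
  dur_a <- length(audio_env) / audio_env$fs
  dur_v <- length(lip_area) / lip_area$fs
  if (shift_a_s >= dur_a || shift_v_s >= dur_v) {
    stop("surrogate shift must be smaller than the trace duration", call. = FALSE)
  }
  if (shift_a_s < 0 || shift_v_s < 0) stop("shifts must be >= 0", call. = FALSE)
  list(
    audio_env = avp_ts(
      shift_circular(audio_env$values, round(shift_a_s * audio_env$fs)),
      audio_env$fs, audio_env$label
    ),
    lip_area = avp_ts(
      shift_circular(lip_area$values, round(shift_v_s * lip_area$fs)),
      lip_area$fs, lip_area$label
    )
  )
}

pid_terms <- c("red", "uni_a", "uni_v", "syn")

# one subject x one node -> avp_pid, through the full phase pipeline
pid_for_node <- function(audio_env, lip_area, node, band_center, band_halfwidth,
                         lag_ms, n_mc, rng_seed, bias_correct = TRUE) {
  fs <- node$fs
  sa <- bandpass_analytic(audio_env, band_center, band_halfwidth)
  sv <- bandpass_analytic(lip_area, band_center, band_halfwidth)
  sm <- bandpass_analytic(node, band_center, band_halfwidth)
  ta <- trim_edges(sa$values, fs)
  tv <- trim_edges(sv$values, fs)
  tm <- trim_edges(sm$values, fs)
  aa <- lag_align(ta, tm, lag_ms = lag_ms, fs = fs)
  av <- lag_align(tv, tm, lag_ms = lag_ms, fs = fs)
  pa <- phase_2d(aa$stimulus)
  pv <- phase_2d(av$stimulus)
  pm <- phase_2d(aa$neural)
  ok <- pa$defined & pv$defined & pm$defined
  pid_decompose(
    cbind(pm$x[ok], pm$y[ok]),
    cbind(pa$x[ok], pa$y[ok]),
    cbind(pv$x[ok], pv$y[ok]),
    n_mc = n_mc, rng_seed = rng_seed, bias_correct = bias_correct
  )
}

#' Run the PID pipeline over a cohort
#'
#' For every subject and neural node: band-pass filter stimuli and node at
#' the analysis band (default 3-7 Hz), Hilbert transform, trim filter edges,
#' compensate the stimulus-to-brain delay (default 100 ms), form unit-circle
#' phase representations, copula-normalise, fit the 6-dimensional joint
#' Gaussian model and decompose with [pid_decompose()]. A surrogate twin of
#' every map is computed against [time_shift_surrogate()] stimuli. Seeds for
#' the Monte-Carlo integrals are derived deterministically from `rng_seed`.
#'
#' @param cohort An `avp_cohort` (or any list of subject records with
#'   `audio_env`, `lip_area`, `nodes`, `kinds`, `comprehension`, `id`).
#' @param band_center,band_halfwidth Analysis band in Hz (defaults 5 and 2).
#' @param lag_ms Stimulus-to-brain delay compensation (default 100 ms).
#' @param n_mc Monte-Carlo samples per redundancy integral (default 1e5).
#' @param shift_a_s,shift_v_s Surrogate shifts in seconds (defaults 60, 30).
#' @param rng_seed Master seed for the Monte-Carlo integrals (default the
#'   cohort config's seed plus 1).
#' @param condition Condition label attached to the result.
#' @return A tibble of class `avp_info_maps`: columns `subject`, `node`,
#'   `kind`, `comprehension`, `term`, `main`, `surrogate` (bits); attributes
#'   `condition` and `provenance` (band, lag, seeds, `n_mc`).
#' @export
run_pid_pipeline <- function(cohort,
                             band_center = 5, band_halfwidth = 2,
                             lag_ms = 100, n_mc = 1e5,
                             shift_a_s = 60, shift_v_s = 30,
                             rng_seed = NULL, condition = "synthetic") {
  cfg <- attr(cohort, "config")
  if (is.null(rng_seed)) {
    rng_seed <- if (!is.null(cfg)) cfg$rng_seed + 1L else 1L
  }
  n_nodes <- length(cohort[[1]]$nodes)
  seeds <- matrix(
    derive_seeds(rng_seed, 2L * length(cohort) * n_nodes),
    nrow = length(cohort)
  )
  rows <- purrr::imap(cohort, function(subj, i) {
    surro <- time_shift_surrogate(subj$audio_env, subj$lip_area, shift_a_s, shift_v_s)
    purrr::imap(subj$nodes, function(node, nm) {
      j <- match(nm, names(subj$nodes))
      main <- pid_for_node(subj$audio_env, subj$lip_area, node,
        band_center, band_halfwidth, lag_ms, n_mc,
        rng_seed = seeds[i, 2 * j - 1]
      )
      surr <- pid_for_node(surro$audio_env, surro$lip_area, node,
        band_center, band_halfwidth, lag_ms, n_mc,
        rng_seed = seeds[i, 2 * j]
      )
      tibble(
        subject = subj$id,
        node = nm,
        kind = if (!is.null(subj$kinds)) unname(subj$kinds[nm]) else NA_character_,
        comprehension = subj$comprehension %||% NA_real_,
        term = pid_terms,
        main = unlist(main[pid_terms], use.names = FALSE),
        surrogate = unlist(surr[pid_terms], use.names = FALSE)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows,
    class = c("avp_info_maps", class(rows)),
    condition = condition,
    provenance = list(
      band_center = band_center, band_halfwidth = band_halfwidth,
      lag_ms = lag_ms, n_mc = n_mc, rng_seed = rng_seed,
      shift_a_s = shift_a_s, shift_v_s = shift_v_s
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surrogate normalisation of information maps
#'
#' Subtracts each subject's time-shift surrogate map from the main map,
#' removing the per-subject analysis bias, and returns the maps with a
#' `value` column (`main - surrogate`).
#'
#' @param maps An `avp_info_maps` tibble from [run_pid_pipeline()].
#' @return The same tibble with a `value` column added.
#' @export
surrogate_normalise <- function(maps) {
  stopifnot(all(c("main", "surrogate") %in% names(maps)))
  out <- dplyr::mutate(maps, value = .data$main - .data$surrogate)
  structure(out,
    class = unique(c("avp_info_maps", class(out))),
    condition = attr(maps, "condition"),
    provenance = attr(maps, "provenance")
  )
}

#' Classify planted node kinds from normalised maps
#'
#' Labels each subject x node with the PID term of largest
#' surrogate-normalised value, mapped back to its planted kind (`red ->
#' redundant`, `uni_a -> unique_a`, `uni_v -> unique_v`, `syn ->
#' synergistic`). `null` nodes have no dominant term by construction and are
#' excluded from the accuracy summary.
#'
#' @param maps Normalised maps (see [surrogate_normalise()]).
#' @return Tibble with `subject`, `node`, `kind`, `predicted`, `correct`.
#' @export
classify_nodes <- function(maps) {
  if (!"value" %in% names(maps)) maps <- surrogate_normalise(maps)
  term_to_kind <- c(
    red = "redundant", uni_a = "unique_a",
    uni_v = "unique_v", syn = "synergistic"
  )
  maps |>
    dplyr::group_by(.data$subject, .data$node, .data$kind) |>
    dplyr::summarise(
      predicted = term_to_kind[[.data$term[which.max(.data$value)]]],
      .groups = "drop"
    ) |>
    dplyr::mutate(correct = .data$predicted == .data$kind)
}

#' @rdname classify_nodes
#' @return `node_recovery_accuracy()`: the fraction of non-null nodes whose
#'   planted kind is recovered.
#' @export
node_recovery_accuracy <- function(maps) {
  cls <- classify_nodes(maps)
  cls <- dplyr::filter(cls, .data$kind != "null")
  mean(cls$correct)
}
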