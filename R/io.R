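#' Write / read a subject dataset directory
#'
#' One directory per subject: `signals.tsv` holds all series (one column per
#' signal, header row naming them, `# fs=<Hz>` comment line) and `meta.json`
#' carries the node kind tags, gains, behavioral score, congruence flag and
#' seed.
#'
#' @param subject An `avp_subject` record.
#' @param dir Directory to create/use.
#' @return The directory path, invisibly.
#' @export
write_subject_dir <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  signals <- c(
    list(audio_env = subject$audio_env, lip_area = subject$lip_area),
    stats::setNames(subject$nodes, paste0("node_", names(subject$nodes)))
  )
  write_signal_tsv(signals, file.path(dir, "signals.tsv"))
  meta <- list(
    id = subject$id,
    kinds = as.list(subject$kinds),
    gains = as.list(subject$gains),
    comprehension = subject$comprehension,
    congruent = subject$congruent,
    seed = subject$seed
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_subject_dir
#' @export
read_subject_dir <- function(dir) {
  signals <- read_signal_tsv(file.path(dir, "signals.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  node_cols <- grep("^node_", names(signals), value = TRUE)
  nodes <- stats::setNames(
    signals[node_cols],
    sub("^node_", "", node_cols)
  )
  structure(
    list(
      id = meta$id,
      audio_env = signals$audio_env,
      lip_area = signals$lip_area,
      nodes = nodes,
      kinds = unlist(meta$kinds),
      gains = unlist(meta$gains),
      comprehension = meta$comprehension,
      congruent = meta$congruent,
      seed = meta$seed
    ),
    class = "avp_subject"
  )
}

#' Write / read a cohort as a directory of subject directories
#'
#' @param cohort An `avp_cohort`.
#' @param dir Root directory; subjects go to `subject_01/`, `subject_02/`, ...
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort)) {
    write_subject_dir(cohort[[i]], file.path(dir, sprintf("subject_%02d", i)))
  }
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- purrr::map(dirs, read_subject_dir)
  structure(subjects, class = "avp_cohort")
}

#' Write analysis outputs as delimited text with a provenance sidecar
#'
#' @param x A tibble (info maps or contrast result).
#' @param path Output `.tsv` path; a `.json` sidecar with the object's
#'   provenance attributes is written alongside.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  side <- list(
    condition = attr(x, "condition"),
    provenance = attr(x, "provenance"),
    alpha = attr(x, "alpha"),
    n_perm = attr(x, "n_perm"),
    written = format(Sys.time(), tz = "UTC")
  )
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
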