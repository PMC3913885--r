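#' Run configuration
#'
#' Collects every tunable of the extraction pipeline with its default:
#' `k = 30` clusters, supra-threshold mask fractions 10% / 5% with a
#' 6-voxel minimum component at 6-connectivity, 0.005-0.1 Hz band-pass,
#' 4 mm smoothing, global signal regression on, 50,000 permutations.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see [default_run_config()]).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
default_run_config <- function() {
  list(k = 30L,
       mask.enabled = TRUE,
       mask.p_high = 0.10,
       mask.p_low = 0.05,
       mask.min_component = 6L,
       mask.connectivity = 6L,
       bandpass.low = 0.005,
       bandpass.high = 0.1,
       smoothing.fwhm_mm = 4,
       gsr.enabled = TRUE,
       n_perm = 50000L,
       n_restarts = 5L,
       max_iter = 300L,
       seed = 1L)
}

#' Load a run configuration from a YAML or JSON file
#'
#' Flat key-value files using the keys of [default_run_config()];
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, vals)
}

#' Extract CAPs end to end
#'
#' Runs supra-threshold masking, frame-wise k-means clustering, and CAP
#' map construction on a conditioned frame matrix, optionally writing
#' results (label TSV, clustering JSON, CAP NIfTI maps and metrics TSV,
#' plus the effective configuration) to an output directory.
#' Deterministic given the config seed.
#'
#' @param frames a `frame_matrix` of preprocessed frames (use
#'   [preprocess_session()] upstream for raw data).
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `assignment` (`cap_clustering`), `caps`
#'   (`cap_set`), `masked` (the masked `frame_matrix`) and `config`.
#' @export
run_extract <- function(frames, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(frames, "frame_matrix"))
  masked <- if (isTRUE(config$mask.enabled))
    mask_frames(frames, config$mask.p_high, config$mask.p_low,
                config$mask.min_component, config$mask.connectivity)
  else frames
  assignment <- kmeans_frames(masked, k = config$k, seed = config$seed,
                              max_iter = config$max_iter,
                              n_restarts = config$n_restarts)
  caps <- compute_caps(frames, assignment)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_clustering(assignment, masked, out_dir)
    write_caps(caps, frames$mask, out_dir)
    prov <- list(config = unclass(config),
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("capkit")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(assignment = assignment, caps = caps, masked = masked,
       config = config)
}

#' Compare group occurrence rates end to end
#'
#' Convenience wrapper: per-subject occurrence matrix from a clustering
#' and session table, then the permutation test between the two group
#' labels in the table.
#'
#' @param assignment a `cap_clustering`.
#' @param sessions a [session_table()] with exactly two group labels.
#' @param n_perm,seed forwarded to [permutation_test()].
#' @return The [permutation_test()] result.
#' @export
run_group_test <- function(assignment, sessions, n_perm = 50000L,
                           seed = 1L) {
  occ <- session_occurrence_matrix(assignment, sessions)
  subj_group <- sessions$group_label[!duplicated(sessions$subject_id)]
  permutation_test(occ, subj_group, n_perm = n_perm, seed = seed)
}
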