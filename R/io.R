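## Run-directory persistence. Layout:
##   config.json, space.json, targets.json, ledger.csv, reference_set.csv,
##   wave<k>_bank.json + wave<k>_bank_train.csv, report.json
## CSV for tabular artifacts, JSON for structured metadata; everything
## plain-text and diffable. Reports carry no timestamps so a rerun with the
## same config and seed is byte-identical.

#' Write calibration targets to / from JSON
#'
#' @param targets A [target_spec()].
#' @param path File path.
#' @return `read_targets()` returns a [target_spec()].
#' @export
write_targets <- function(targets, path) {
  df <- data.frame(biomarker = targets$biomarker_names, mu = targets$mu,
                   sigma = targets$sigma)
  jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  target_spec(df$biomarker, df$mu, df$sigma)
}

#' Summary report of a history-matching run
#'
#' Per wave: threshold, simulations added, cumulative NROY size over the
#' reference set, per-biomarker emulator scores, and the maximum/median
#' variance quotient over the wave's NROY reference points. Optionally the
#' implausibility of a known ground-truth point at every wave.
#'
#' @param run An `hm_run`.
#' @param truth Optional unit-frame ground-truth vector.
#' @return A list (JSON-ready).
#' @export
run_report <- function(run, truth = NULL) {
  waves <- lapply(seq_along(run$waves), function(j) {
    w <- run$waves[[j]]
    m <- ref_mask(run, j)
    vq <- vq_stats(w$bank, run$targets, run$reference_set, m)
    list(
      wave = j, threshold = w$threshold, n_new_sims = w$n_new_sims,
      nroy_size_pct = nroy_size(run, j),
      vq_max = vq$max, vq_median = vq$median,
      truth_implausibility = if (is.null(truth)) NULL else
        implausibility(w$bank, run$targets, matrix(truth, nrow = 1)),
      emulator_scores = if (is.null(w$scores)) NULL else w$scores)
  })
  list(
    n_waves = length(run$waves),
    thresholds = run$config$thresholds,
    n_simulations = nrow(run$ledger),
    n_reference = nrow(run$reference_set),
    final_nroy_size_pct = nroy_size(run),
    waves = waves)
}

#' Persist a history-matching run to a directory
#'
#' Writes the run-directory layout described above. Banks are written per
#' wave and can be reloaded with [read_bank()] for emulator reuse.
#'
#' @param run An `hm_run`.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth vector forwarded to [run_report()].
#' @param config_json Optional original run-configuration list to store.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, truth = NULL, config_json = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_space(run$space, file.path(dir, "space.json"))
  write_targets(run$targets, file.path(dir, "targets.json"))
  cfg <- unclass(run$config)
  if (!is.null(config_json)) cfg <- utils::modifyList(config_json, cfg)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(format(run$ledger, digits = 17, trim = TRUE),
                   file.path(dir, "ledger.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(format(as.data.frame(run$reference_set), digits = 17,
                          trim = TRUE),
                   file.path(dir, "reference_set.csv"), row.names = FALSE,
                   quote = FALSE)
  for (j in seq_along(run$waves))
    write_bank(run$waves[[j]]$bank, dir, name = sprintf("wave%d_bank", j))
  jsonlite::write_json(run_report(run, truth = truth),
                       file.path(dir, "report.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read artifacts back from a run directory
#'
#' `read_run_bank()` reloads the emulator bank of one wave (default: the
#' last available); `read_reference_set()` reloads the fixed reference set.
#'
#' @param dir Run directory written by [write_run()].
#' @param wave Wave index; `NULL` picks the highest on disk.
#' @return A `gpe_bank` / unit-frame matrix respectively.
#' @export
read_run_bank <- function(dir, wave = NULL) {
  banks <- list.files(dir, pattern = "^wave[0-9]+_bank\\.json$")
  if (!length(banks))
    stop("no emulator bank found in run directory: ", dir, call. = FALSE)
  if (is.null(wave))
    wave <- max(as.integer(sub("^wave([0-9]+)_bank\\.json$", "\\1", banks)))
  read_bank(dir, name = sprintf("wave%d_bank", wave))
}

#' @rdname read_run_bank
#' @export
read_reference_set <- function(dir) {
  path <- file.path(dir, "reference_set.csv")
  if (!file.exists(path))
    stop("reference set not found in run directory: ", dir, call. = FALSE)
  U <- as.matrix(utils::read.csv(path, check.names = FALSE))
  attr(U, "frame") <- "unit"
  U
}

#' Simulator backed by a precomputed design/response table
#'
#' Builds a simulator callback from a CSV holding one row per already-run
#' simulation: the parameter columns (natural units, named as in the
#' space) followed by biomarker columns. Requested design rows are matched
#' against the table within a tolerance; unmatched rows are an error — the
#' lookup never invents values.
#'
#' @param path CSV file path.
#' @param space A [parameter_space()].
#' @param tol Relative matching tolerance on each parameter.
#' @return A simulator function for [run_history_matching()].
#' @export
csv_simulator <- function(path, space, tol = 1e-8) {
  tab <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(space$names, names(tab))
  if (length(missing))
    stop("simulation table lacks parameter column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  P <- as.matrix(tab[, space$names, drop = FALSE])
  B <- tab[, setdiff(names(tab), space$names), drop = FALSE]
  scale <- pmax(abs(space$upper - space$lower), 1e-12)
  function(X_nat) {
    X_nat <- as.matrix(X_nat)[, space$names, drop = FALSE]
    idx <- vapply(seq_len(nrow(X_nat)), function(i) {
      d <- sweep(abs(sweep(P, 2, X_nat[i, ], "-")), 2, scale, "/")
      hit <- which(apply(d, 1, max) <= tol)
      if (!length(hit)) NA_integer_ else hit[1]
    }, integer(1))
    if (anyNA(idx))
      stop(sprintf("no stored simulation matches %d requested design row(s)",
                   sum(is.na(idx))), call. = FALSE)
    B[idx, , drop = FALSE]
  }
}
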