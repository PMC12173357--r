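#' Process a directory of records
#'
#' Every subdirectory of `input_dir` is treated as one CSV-format record
#' (see [load_record()]); each is processed independently with
#' [run_pipeline()] and its per-window estimates written to
#' `<subject>_rr.csv` under `out_dir`. Failures are isolated per record
#' and recorded in the run manifest, which is written as
#' `manifest.json` alongside the outputs.
#'
#' @param input_dir Directory containing record subdirectories.
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param format Record format passed to [load_record()].
#' @return The manifest (list with `config`, `package_version`,
#'   `timestamp`, `records`: per-record path + status), invisibly.
#' @export
run_batch <- function(input_dir, cfg = pipeline_config(),
                      out_dir = file.path(input_dir, "out"),
                      format = "csv") {
  entries <- if (format == "csv")
    list.dirs(input_dir, recursive = FALSE) else
    unique(sub("\\.hea$", "", list.files(input_dir, "\\.hea$", full.names = TRUE)))
  entries <- entries[normalizePath(entries, mustWork = FALSE) !=
                       normalizePath(out_dir, mustWork = FALSE)]
  if (length(entries) == 0)
    rf_config_error("no records found in %s", input_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  statuses <- lapply(entries, function(p) {
    res <- tryCatch({
      rec <- load_record(p, format = format)
      est <- run_pipeline(rec, cfg)
      out <- file.path(out_dir, paste0(rec$subject_id, "_rr.csv"))
      utils::write.csv(est, out, row.names = FALSE)
      list(path = p, status = "ok", output = out, n_windows = nrow(est))
    }, error = function(e) {
      warning("record failed: ", p, " (", conditionMessage(e), ")")
      list(path = p, status = "failed", error = conditionMessage(e))
    })
    res
  })
  manifest <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("respifuse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    records = statuses
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
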