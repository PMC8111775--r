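#' Write a simulated experiment to a fixture bundle on disk
#'
#' Serialises every table of a [simulate_experiment()] result as a TSV
#' (tab-delimited, header row, UTF-8, "." decimal, full float precision, so
#' a fixed seed yields a byte-identical bundle), the ground truth as JSON,
#' and a manifest recording the seed, a hash of the configuration, and the
#' file list.
#'
#' @param sim A `ptj_sim` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_bundle <- function(sim, dir) {
  if (!inherits(sim, "ptj_sim")) {
    ptj_abort("`sim` must be a `ptj_sim` from simulate_experiment().",
              "ptj_error_argument")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    ptj_abort(sprintf("cannot write to directory '%s'.", dir),
              class = "ptj_error_io")
  }
  tables <- c("sample_frame", "cells", "cell_cycle", "qpcr", "rrna",
              "expression", "annotation")
  files <- character()
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".tsv"))
    readr::write_tsv(sim[[tb]], path, progress = FALSE)
    files <- c(files, basename(path))
  }
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sim$ground_truth, gt_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  files <- c(files, basename(gt_path))
  manifest <- list(
    package = "plastidtraj",
    seed = sim$config$seed,
    config_hash = rlang::hash(sim$config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle back into memory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return A list with the seven tables (tibbles), `ground_truth` and
#'   `manifest` (lists).
#' @export
read_fixture_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    ptj_abort(sprintf("no manifest.json in '%s'.", dir),
              class = "ptj_error_io")
  }
  tables <- c("sample_frame", "cells", "cell_cycle", "qpcr", "rrna",
              "expression", "annotation")
  out <- lapply(setNames(tables, tables), function(tb) {
    readr::read_tsv(file.path(dir, paste0(tb, ".tsv")),
                    show_col_types = FALSE, progress = FALSE)
  })
  out$ground_truth <- jsonlite::read_json(
    file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  out$manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  out
}
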