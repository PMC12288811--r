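#' Write an imputation stack to disk
#'
#' Serializes the completed datasets as numbered CSV files plus a JSON
#' manifest recording the number of datasets, seeds and any method settings
#' stored in the stack's metadata.
#'
#' @param stack An `fgmi_stack`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the numbered CSVs.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "imputation") {
  stopifnot(inherits(stack, "fgmi_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- length(stack$datasets)
  files <- sprintf("%s_%03d.csv", prefix, seq_len(m))
  for (j in seq_len(m)) {
    readr::write_csv(stack$datasets[[j]], file.path(dir, files[j]))
  }
  manifest <- c(stack$meta[setdiff(names(stack$meta), "diagnostics")],
                list(files = files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an imputation stack written by [write_stack()]
#'
#' @param dir Directory containing the numbered CSVs and `manifest.json`.
#' @return An `fgmi_stack`.
#' @export
read_stack <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  datasets <- lapply(manifest$files, function(f) {
    readr::read_csv(file.path(dir, f), show_col_types = FALSE)
  })
  new_fgmi_stack(datasets, meta = manifest[setdiff(names(manifest), "files")])
}
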