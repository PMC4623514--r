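#' Write a table as CSV with a metadata header
#'
#' Writes `#`-prefixed `key=value` provenance lines (package version plus
#' any supplied metadata) followed by a standard CSV body with a header
#' row. `read_table_csv()` reads it back, returning the metadata in
#' attribute `meta`.
#'
#' @param df A data frame.
#' @param path File path.
#' @param meta Named list of scalar metadata.
#' @return The path, invisibly; `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("spinquench ",
                                  as.character(utils::packageVersion("spinquench")))),
            meta)
  hdr <- sprintf("# %s=%s", names(meta), vapply(meta, format, ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      v <- suppressWarnings(as.numeric(kv[2]))
      meta[[kv[1]]] <- if (is.na(v)) kv[2] else v
    }
  }
  df <- utils::read.csv(text = paste(lines[!is_hdr], collapse = "\n"))
  structure(as_tibble(df), meta = meta)
}

config_meta <- function(config) {
  list(
    L_s = config$L_s, n = config$n, J = config$J, temp = config$temp,
    n_mcs = config$n_mcs, n_runs = config$n_runs, seed = config$seed,
    snapshot_times = paste(config$snapshot_times, collapse = ";")
  )
}
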