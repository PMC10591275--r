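#' Export an electrode table in BIDS-iEEG format
#'
#' Writes `<tag>_electrodes.tsv` (columns `name`, `x`, `y`, `z`, `size`, then
#' any extra value columns) and `<tag>_coordsystem.json` declaring a
#' subject-native scanner-RAS coordinate system with units mm. Missing cells
#' are written as the literal `n/a`, tab-separated, UTF-8, unquoted. When
#' shifted coordinates are present they are exported as an additional sidecar
#' pair `<tag>_space-shifted_electrodes.tsv` / `_coordsystem.json` rather than
#' overwriting native coordinates.
#'
#' @param table An electrode table with at least one localized record.
#' @param out_dir Output directory (created if absent).
#' @param subject_tag Filename prefix, e.g. `"sub-01"`.
#' @return Character vector of the files written, invisibly.
#' @export
export_bids <- function(table, out_dir, subject_tag = "sub-01") {
  coords <- table[, c("x", "y", "z")]
  if (nrow(table) == 0L || !any(stats::complete.cases(coords))) {
    stop("cannot export: no electrode in the table has coordinates",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()

  core <- c("number", "channel", "group", "index", "x", "y", "z",
            "x_shifted", "y_shifted", "z_shifted",
            "vox_i", "vox_j", "vox_k", "provenance")
  extra <- setdiff(names(table), core)

  write_electrode_tsv <- function(xyz, path) {
    out <- tibble::tibble(name = table$channel,
                          x = fmt_bids(xyz[[1]]),
                          y = fmt_bids(xyz[[2]]),
                          z = fmt_bids(xyz[[3]]),
                          size = "n/a")
    for (col in extra) out[[col]] <- fmt_bids(table[[col]])
    readr::write_tsv(out, path, na = "n/a", progress = FALSE)
    path
  }

  tsv <- file.path(out_dir, paste0(subject_tag, "_electrodes.tsv"))
  written <- c(written, write_electrode_tsv(table[, c("x", "y", "z")], tsv))
  js <- file.path(out_dir, paste0(subject_tag, "_coordsystem.json"))
  jsonlite::write_json(
    list(iEEGCoordinateSystem = "Other",
         iEEGCoordinateSystemDescription = "subject-native scanner RAS",
         iEEGCoordinateUnits = "mm"),
    js, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, js)

  if ("x_shifted" %in% names(table) && any(!is.na(table$x_shifted))) {
    tsv2 <- file.path(out_dir,
                      paste0(subject_tag, "_space-shifted_electrodes.tsv"))
    written <- c(written, write_electrode_tsv(
      table[, c("x_shifted", "y_shifted", "z_shifted")], tsv2))
    js2 <- file.path(out_dir,
                     paste0(subject_tag, "_space-shifted_coordsystem.json"))
    jsonlite::write_json(
      list(iEEGCoordinateSystem = "Other",
           iEEGCoordinateSystemDescription =
             "subject-native scanner RAS, brain-shift corrected",
           iEEGCoordinateUnits = "mm"),
      js2, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, js2)
  }
  invisible(written)
}

fmt_bids <- function(v) {
  if (is.numeric(v)) {
    out <- vapply(v, function(x) {
      if (is.na(x)) NA_character_ else format(x, digits = 15, trim = TRUE,
                                              scientific = FALSE)
    }, character(1))
    out
  } else {
    as.character(v)
  }
}

#' Read a BIDS electrodes.tsv back into an electrode table
#'
#' @param path Path to an `*_electrodes.tsv` file.
#' @return An electrode table; `name` becomes the channel label and group /
#'   within-group index are recovered from the channel label where possible.
#' @export
read_bids_electrodes <- function(path) {
  tab <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(tab))) {
    stop("not a BIDS electrodes.tsv (need name, x, y, z): ", path,
         call. = FALSE)
  }
  grp <- sub("[0-9]+$", "", tab$name)
  idx <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", tab$name)))
  out <- tibble::tibble(
    number = seq_len(nrow(tab)),
    channel = tab$name,
    group = grp,
    index = idx,
    x = as.numeric(tab$x), y = as.numeric(tab$y), z = as.numeric(tab$z),
    provenance = NA_character_
  )
  extra <- setdiff(names(tab), c("name", "x", "y", "z", "size"))
  for (col in extra) out[[col]] <- tab[[col]]
  new_electrode_table(out)
}

#' Export the full electrode table as one plain-text TSV
#'
#' Every field of the table, one row per electrode, missing cells as `n/a`.
#'
#' @param table An electrode table with at least one localized record.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
export_plaintext <- function(table, path) {
  coords <- table[, c("x", "y", "z")]
  if (nrow(table) == 0L || !any(stats::complete.cases(coords))) {
    stop("cannot export: no electrode in the table has coordinates",
         call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(unclass_tbl(table)),
                       dplyr::across(dplyr::where(is.numeric), fmt_bids))
  readr::write_tsv(out, path, na = "n/a", progress = FALSE)
  invisible(path)
}

#' Read a plain-text electrode table written by [export_plaintext()]
#'
#' @param path Path to the TSV.
#' @return An electrode table.
#' @export
read_electrode_table <- function(path) {
  tab <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                         progress = FALSE)
  tab$number <- as.integer(tab$number)
  tab$index <- as.integer(tab$index)
  for (col in intersect(c("x", "y", "z", "x_shifted", "y_shifted", "z_shifted"),
                        names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  new_electrode_table(tab)
}
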