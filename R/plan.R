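#' Declare a contact group (sEEG shaft, ECoG grid or strip)
#'
#' @param label Short shaft/grid code, e.g. `"LA"`.
#' @param kind One of `"sEEG"`, `"ECoG-grid"`, `"ECoG-strip"`.
#' @param n_contacts Number of contacts in the group (>= 1).
#' @param grid_dims Integer `(rows, cols)`; required for `"ECoG-grid"` and
#'   must satisfy `rows * cols == n_contacts`. Contacts are numbered row-major.
#' @param spacing Nominal inter-contact pitch in mm (optional).
#' @return A one-row tibble describing the group.
#' @export
contact_group <- function(label, kind = c("sEEG", "ECoG-grid", "ECoG-strip"),
                          n_contacts, grid_dims = NULL, spacing = NA_real_) {
  kind <- match.arg(kind)
  n_contacts <- as.integer(n_contacts)
  if (is.na(n_contacts) || n_contacts < 1L) {
    stop("n_contacts must be a positive integer", call. = FALSE)
  }
  rows <- cols <- NA_integer_
  if (kind == "ECoG-grid") {
    if (is.null(grid_dims) || length(grid_dims) != 2L) {
      stop("grid_dims (rows, cols) required for an ECoG-grid group",
           call. = FALSE)
    }
    rows <- as.integer(grid_dims[1]); cols <- as.integer(grid_dims[2])
    if (rows * cols != n_contacts) {
      stop(sprintf("group '%s': grid_dims %dx%d inconsistent with n_contacts %d",
                   label, rows, cols, n_contacts), call. = FALSE)
    }
  } else if (!is.null(grid_dims)) {
    stop("grid_dims only applies to ECoG-grid groups", call. = FALSE)
  }
  tibble::tibble(label = as.character(label), kind = kind,
                 n_contacts = n_contacts, rows = rows, cols = cols,
                 spacing = as.numeric(spacing))
}

#' Assemble an electrode plan from contact groups
#'
#' @param ... One-row tibbles from [contact_group()], or a single data frame
#'   with the same columns.
#' @return A tibble of class `electrode_plan`, one row per group.
#' @export
electrode_plan <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1]]) &&
      !inherits(args[[1]], "rowwise_df")) {
    plan <- tibble::as_tibble(args[[1]])
  } else {
    plan <- dplyr::bind_rows(args)
  }
  required <- c("label", "kind", "n_contacts")
  missing_cols <- setdiff(required, names(plan))
  if (length(missing_cols)) {
    stop("plan is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"rows" %in% names(plan)) plan$rows <- NA_integer_
  if (!"cols" %in% names(plan)) plan$cols <- NA_integer_
  if (!"spacing" %in% names(plan)) plan$spacing <- NA_real_
  if (anyDuplicated(plan$label)) {
    dup <- unique(plan$label[duplicated(plan$label)])
    stop("duplicate group label(s) in plan: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- plan$kind == "ECoG-grid" &
    (is.na(plan$rows) | is.na(plan$cols) | plan$rows * plan$cols != plan$n_contacts)
  if (any(bad)) {
    stop("group '", plan$label[which(bad)[1]],
         "': grid_dims inconsistent with n_contacts", call. = FALSE)
  }
  class(plan) <- c("electrode_plan", class(tibble::tibble()))
  plan
}

#' Read an electrode plan from JSON or TSV
#'
#' JSON: an array of objects with fields `label`, `kind`, `n_contacts` and
#' optional `grid_dims` (two integers) and `spacing`. TSV: columns `label`,
#' `kind`, `n_contacts` and optional `rows`, `cols`, `spacing`.
#'
#' @param path Path to the plan file (`.json`, `.tsv` or `.txt`).
#' @return An [electrode_plan()].
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    rows <- purrr::map(raw, function(g) {
      contact_group(g$label, g$kind, g$n_contacts,
                    grid_dims = g$grid_dims,
                    spacing = g$spacing %||% NA_real_)
    })
    return(electrode_plan(dplyr::bind_rows(rows)))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  electrode_plan(tab)
}

#' @method tidy electrode_plan
#' @export
tidy.electrode_plan <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}

#' Create the template electrode table from a plan
#'
#' One row per planned contact, numbered consecutively in plan order, with
#' coordinates unset. Channel labels default to group label + within-group
#' index (e.g. `"LA3"`), matching clinical shaft-code convention.
#'
#' @param plan An [electrode_plan()].
#' @return A tibble of class `electrode_table` with columns `number`,
#'   `channel`, `group`, `index` (1-based within group), `x`, `y`, `z`
#'   (native world mm, `NA` when not yet localized) and `provenance`.
#' @export
table_from_plan <- function(plan) {
  plan <- electrode_plan(plan)  # revalidates
  if (nrow(plan) == 0L) return(new_electrode_table(empty_records()))
  recs <- purrr::pmap(plan, function(label, kind, n_contacts, ...) {
    tibble::tibble(
      channel = paste0(label, seq_len(n_contacts)),
      group = label,
      index = seq_len(n_contacts)
    )
  })
  recs <- dplyr::bind_rows(recs)
  recs <- dplyr::mutate(recs, number = dplyr::row_number(), .before = 1)
  recs$x <- NA_real_
  recs$y <- NA_real_
  recs$z <- NA_real_
  recs$provenance <- NA_character_
  new_electrode_table(recs)
}

empty_records <- function() {
  tibble::tibble(number = integer(), channel = character(),
                 group = character(), index = integer(),
                 x = double(), y = double(), z = double(),
                 provenance = character())
}

new_electrode_table <- function(tbl, frame = "native subject RAS (mm)") {
  stopifnot(all(c("number", "channel", "group", "index",
                  "x", "y", "z") %in% names(tbl)))
  if (nrow(tbl) && !identical(as.integer(tbl$number), seq_len(nrow(tbl)))) {
    stop("electrode numbers must be dense from 1 in table order",
         call. = FALSE)
  }
  attr(tbl, "coordinate_frame") <- frame
  class(tbl) <- unique(c("electrode_table", class(tibble::tibble())))
  tbl
}

#' @method glance electrode_table
#' @export
glance.electrode_table <- function(x, ...) {
  tibble::tibble(
    n_electrodes = nrow(x),
    n_localized = sum(stats::complete.cases(x[, c("x", "y", "z")])),
    n_groups = dplyr::n_distinct(x$group),
    n_shifted = if ("x_shifted" %in% names(x)) sum(!is.na(x$x_shifted)) else 0L,
    n_labeled = if ("anat_label_name" %in% names(x)) sum(!is.na(x$anat_label_name)) else 0L
  )
}

#' Merge per-electrode values into the table
#'
#' Imports a delimited value table (or data frame) keyed by electrode
#' `number` or `channel`/`name`. Matched cells become extra columns on the
#' electrode table; blank and `"n/a"` cells leave the value unset; keys that
#' match no electrode are reported with a warning but do not abort.
#'
#' @param table An [table_from_plan()] electrode table.
#' @param values A data frame, or a path to a `.tsv`/`.csv` file.
#' @param key Key column name; by default the first of `number`, `channel`,
#'   `name` present in `values`.
#' @return The electrode table with the value columns merged in; row order
#'   and count are unchanged.
#' @export
import_values <- function(table, values, key = NULL) {
  if (is.character(values) && length(values) == 1L) {
    values <- read_delimited_auto(values)
  }
  values <- tibble::as_tibble(values)
  if (is.null(key)) {
    key <- intersect(c("number", "channel", "name"), names(values))[1]
    if (is.na(key) || is.null(key)) {
      stop("value table has no key column (need `number`, `channel` or `name`)",
           call. = FALSE)
    }
  } else if (!key %in% names(values)) {
    stop("key column '", key, "' not present in the value table", call. = FALSE)
  }
  table_key <- if (key == "number") table$number else table$channel
  value_key <- values[[key]]
  if (key == "number") value_key <- as.integer(value_key)
  pos <- match(value_key, table_key)
  if (anyNA(pos)) {
    unmatched <- value_key[is.na(pos)]
    warning("value rows keyed to unknown electrode(s): ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  data_cols <- setdiff(names(values), key)
  for (col in data_cols) {
    v <- values[[col]]
    if (is.character(v)) {
      v[trimws(v) %in% c("", "n/a", "N/A", "NA")] <- NA
      num <- suppressWarnings(as.numeric(v))
      if (all(is.na(num) == is.na(v))) v <- num
    }
    if (!col %in% names(table)) {
      table[[col]] <- v[NA_integer_][rep(1L, nrow(table))]
    }
    keep <- !is.na(pos) & !is.na(v)
    table[[col]][pos[keep]] <- v[keep]
  }
  table
}

read_delimited_auto <- function(path) {
  if (!file.exists(path)) stop("value file not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "n/a", "NA"))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "n/a", "NA"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
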