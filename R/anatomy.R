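#' Parcellation label volume
#'
#' Integer label array plus voxel-to-world affine and an id-to-name lookup
#' table. Ids absent from the lookup are implicitly `"unknown"`; id 0 is
#' `"unknown"` unless the lookup says otherwise.
#'
#' @param labels 3-D integer array.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param lut Data frame with columns `id`, `name` (extra columns ignored),
#'   or a named list / named character vector keyed by id.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, affine = diag(4), lut = NULL) {
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3-D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  affine <- as_affine(affine)
  lut <- normalize_lut(lut)
  structure(list(labels = labels, affine = affine,
                 shape = as.integer(dim(labels)), lut = lut),
            class = "label_volume")
}

normalize_lut <- function(lut) {
  if (is.null(lut)) {
    return(tibble::tibble(id = 0L, name = "unknown"))
  }
  if (is.data.frame(lut)) {
    out <- tibble::tibble(id = as.integer(lut$id), name = as.character(lut$name))
  } else {
    out <- tibble::tibble(id = as.integer(names(lut)),
                          name = as.character(unlist(lut, use.names = FALSE)))
  }
  if (!any(out$id == 0L)) {
    out <- dplyr::bind_rows(tibble::tibble(id = 0L, name = "unknown"), out)
  }
  out
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(x$shape, collapse = " x "),
      " voxels, ", nrow(x$lut), " lookup entries\n", sep = "")
  invisible(x)
}

lut_name <- function(lv, id) {
  pos <- match(id, lv$lut$id)
  out <- lv$lut$name[pos]
  out[is.na(pos)] <- "unknown"
  out
}

#' Read a FreeSurfer-style color lookup table
#'
#' Whitespace-delimited text with columns id, name, R, G, B, A; `#` comments
#' and blank lines skipped; color columns ignored.
#'
#' @param path Path to the LUT text file.
#' @return Tibble with columns `id`, `name`.
#' @export
read_lut <- function(path) {
  if (!file.exists(path)) stop("LUT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(tibble::tibble(id = 0L, name = "unknown"))
  parts <- strsplit(lines, "[ \t]+")
  tibble::tibble(
    id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    name = vapply(parts, function(p) p[2], character(1))
  )
}

#' Read a parcellation volume (NIfTI) with its lookup table
#'
#' @param path NIfTI file of integer labels (e.g. FreeSurfer aparc+aseg
#'   exported to NIfTI).
#' @param lut_path Optional FreeSurfer-LUT-style text file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, lut_path = NULL) {
  vol <- read_volume(path)
  lut <- if (is.null(lut_path)) NULL else read_lut(lut_path)
  label_volume(round(vol$data), vol$affine, lut)
}

#' Majority-vote anatomic label at world coordinates
#'
#' For each point, the most frequent label over the 3x3x3 cube of voxels
#' centered on the point's voxel is returned (out-of-bounds neighbours are
#' skipped). On a tie for the maximal count the label of the cube's center
#' voxel is used. Voting makes the assignment robust to sub-voxel electrode
#' shifts.
#'
#' @param lv A [label_volume()].
#' @param p World point(s): length-3 vector or n x 3 matrix (mm).
#' @return Tibble with columns `id`, `name`, one row per point.
#' @export
majority_label <- function(lv, p) {
  pts <- as_points(p)
  v <- world_to_voxel(lv, pts)
  ok <- in_bounds_voxel(lv, v)
  if (!all(ok)) {
    bad <- pts[which(!ok)[1], ]
    stop(sprintf("point (%.2f, %.2f, %.2f) mm is outside the label volume",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  ctr <- round(v)  # 0-based center voxel
  ids <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ids[i] <- vote_cube(lv, ctr[i, ])
  }
  tibble::tibble(id = ids, name = lut_name(lv, ids))
}

vote_cube <- function(lv, ctr) {
  sh <- lv$shape
  ii <- (ctr[1] - 1):(ctr[1] + 1); ii <- ii[ii >= 0 & ii < sh[1]]
  jj <- (ctr[2] - 1):(ctr[2] + 1); jj <- jj[jj >= 0 & jj < sh[2]]
  kk <- (ctr[3] - 1):(ctr[3] + 1); kk <- kk[kk >= 0 & kk < sh[3]]
  cube <- lv$labels[ii + 1, jj + 1, kk + 1]
  counts <- table(cube)
  top <- counts[counts == max(counts)]
  if (length(top) > 1L) {
    # tie: the center voxel's label wins, applied literally
    return(lv$labels[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1])
  }
  as.integer(names(top))
}

#' Transfer anatomic labels onto an electrode table
#'
#' Fills `anat_label_id` / `anat_label_name` for every record with native
#' coordinates; records without coordinates are left untouched; electrodes
#' outside the label volume get `"unknown"` with a warning.
#'
#' @param table An electrode table.
#' @param lv A [label_volume()].
#' @return The electrode table with anatomy columns filled.
#' @export
label_table <- function(table, lv) {
  if (!"anat_label_id" %in% names(table)) table$anat_label_id <- NA_integer_
  if (!"anat_label_name" %in% names(table)) table$anat_label_name <- NA_character_
  loc <- which(stats::complete.cases(table[, c("x", "y", "z")]))
  if (length(loc) == 0L) return(table)
  pts <- as.matrix(table[loc, c("x", "y", "z")])
  v <- world_to_voxel(lv, pts)
  inside <- in_bounds_voxel(lv, v)
  if (any(!inside)) {
    warning(sum(!inside), " electrode(s) outside the label volume; labeled 'unknown'",
            call. = FALSE)
    table$anat_label_id[loc[!inside]] <- 0L
    table$anat_label_name[loc[!inside]] <- "unknown"
  }
  if (any(inside)) {
    res <- majority_label(lv, pts[inside, , drop = FALSE])
    table$anat_label_id[loc[inside]] <- res$id
    table$anat_label_name[loc[inside]] <- res$name
  }
  table
}
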