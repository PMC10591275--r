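#' Read a surface mesh (GIfTI or FreeSurfer binary)
#'
#' `.gii` files are parsed as GIfTI (ASCII, Base64Binary and
#' GZipBase64Binary encodings); anything else is read as a FreeSurfer
#' binary triangle surface (e.g. `lh.pial`).
#'
#' @param path Path to the surface file.
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("surface file not found: ", path, call. = FALSE)
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    read_gifti_surface(path)
  } else {
    read_fs_surface(path)
  }
}

#' Write a surface mesh
#'
#' Format chosen by extension: `.gii` writes GIfTI (GZipBase64Binary,
#' little-endian), anything else writes FreeSurfer binary triangle format.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    write_gifti_surface(mesh, path)
  } else {
    write_fs_surface(mesh, path)
  }
  invisible(path)
}

# ---- GIfTI ------------------------------------------------------------

gifti_decode <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- tolower(xml2::xml_attr(node, "Endian") %||% "LittleEndian")
  endian <- if (identical(endian, "bigendian")) "big" else "little"
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"),
                       xml2::xml_attr(node, "Dim1")))
  dims[is.na(dims)] <- 1L
  order <- xml2::xml_attr(node, "ArrayIndexingOrder") %||% "RowMajorOrder"
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//d1:Data",
                                             c(d1 = "http://www.nitrc.org/frs/?group_id=75")))
  if (is.na(txt)) {
    txt <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
  }
  rtype <- if (grepl("FLOAT", dtype)) "double" else "integer"
  size <- if (grepl("FLOAT64", dtype)) 8L else 4L
  n <- prod(dims)
  vals <- switch(enc,
    "ASCII" = {
      v <- scan(text = txt, quiet = TRUE)
      if (rtype == "integer") as.integer(v) else v
    },
    "Base64Binary" = {
      raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
      readBin(raw, rtype, n = n, size = size, endian = endian)
    },
    "GZipBase64Binary" = {
      raw <- memDecompress(jsonlite::base64_dec(gsub("\\s", "", txt)),
                           type = "gzip")
      readBin(raw, rtype, n = n, size = size, endian = endian)
    },
    stop("unsupported GIfTI encoding: ", enc, call. = FALSE)
  )
  if (length(dims) == 2L && dims[2] > 1L) {
    if (identical(order, "RowMajorOrder")) {
      matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    } else {
      matrix(vals, nrow = dims[1], ncol = dims[2])
    }
  } else {
    vals
  }
}

gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name() = 'DataArray']")
  stats::setNames(
    lapply(nodes, gifti_decode),
    vapply(nodes, function(n) xml2::xml_attr(n, "Intent"), character(1))
  )
}

read_gifti_surface <- function(path) {
  arrays <- gifti_arrays(path)
  v <- arrays[["NIFTI_INTENT_POINTSET"]]
  f <- arrays[["NIFTI_INTENT_TRIANGLE"]]
  if (is.null(v) || is.null(f)) {
    stop("GIfTI file lacks POINTSET/TRIANGLE arrays: ", path, call. = FALSE)
  }
  surface_mesh(v, f + 1L)  # GIfTI faces are 0-based
}

gifti_data_node <- function(values, dtype, intent, dims) {
  raw <- if (dtype == "NIFTI_TYPE_FLOAT32") {
    writeBin(as.numeric(values), raw(), size = 4L, endian = "little")
  } else {
    writeBin(as.integer(values), raw(), size = 4L, endian = "little")
  }
  b64 <- jsonlite::base64_enc(memCompress(raw, type = "gzip"))
  paste0(
    '  <DataArray Intent="', intent, '" DataType="', dtype,
    '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="', dims[1],
    '" Dim1="', dims[2],
    '" Encoding="GZipBase64Binary" Endian="LittleEndian"',
    ' ExternalFileName="" ExternalFileOffset="">\n',
    "    <Data>", gsub("\n", "", b64), "</Data>\n",
    "  </DataArray>\n"
  )
}

# row-major flattening of an n x 3 matrix
flatten_rowmajor <- function(m) as.vector(t(m))

write_gifti_surface <- function(mesh, path) {
  body <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI xmlns="http://www.nitrc.org/frs/?group_id=75" Version="1.0" NumberOfDataArrays="2">\n',
    gifti_data_node(flatten_rowmajor(mesh$vertices), "NIFTI_TYPE_FLOAT32",
                    "NIFTI_INTENT_POINTSET", dim(mesh$vertices)),
    gifti_data_node(flatten_rowmajor(mesh$faces - 1L), "NIFTI_TYPE_INT32",
                    "NIFTI_INTENT_TRIANGLE", dim(mesh$faces)),
    "</GIFTI>\n"
  )
  writeLines(body, path, useBytes = TRUE)
  invisible(path)
}

#' Write per-vertex values as a GIfTI functional file or CSV
#'
#' `.gii` writes a `.func.gii`-style file (one FLOAT32 data array, NaN for
#' unassigned vertices); any other extension writes CSV with columns
#' `vertex_index` (0-based) and `value`, unassigned vertices omitted.
#'
#' @param values Numeric vector, one element per mesh vertex (`NA` =
#'   unassigned).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vertex_values <- function(values, path) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    vals <- as.numeric(values)
    vals[is.na(vals)] <- NaN
    body <- paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<GIFTI xmlns="http://www.nitrc.org/frs/?group_id=75" Version="1.0" NumberOfDataArrays="1">\n',
      gifti_data_node(vals, "NIFTI_TYPE_FLOAT32", "NIFTI_INTENT_NONE",
                      c(length(vals), 1L)),
      "</GIFTI>\n"
    )
    writeLines(body, path, useBytes = TRUE)
  } else {
    keep <- !is.na(values)
    readr::write_csv(
      tibble::tibble(vertex_index = which(keep) - 1L, value = values[keep]),
      path, progress = FALSE)
  }
  invisible(path)
}

#' Read per-vertex values written by [write_vertex_values()]
#'
#' @param path `.gii` or `.csv` path.
#' @param n_vertices Required for CSV input: total vertex count.
#' @return Numeric vector with `NA` for unassigned vertices.
#' @export
read_vertex_values <- function(path, n_vertices = NULL) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) {
    arrays <- gifti_arrays(path)
    vals <- as.numeric(arrays[[1]])
    vals[is.nan(vals)] <- NA_real_
    return(vals)
  }
  if (is.null(n_vertices)) {
    stop("n_vertices is required to read CSV vertex values", call. = FALSE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- rep(NA_real_, n_vertices)
  out[tab$vertex_index + 1L] <- tab$value
  out
}

# ---- FreeSurfer binary triangle surface --------------------------------

TRIANGLE_FILE_MAGIC <- c(0xff, 0xff, 0xfe)

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3, size = 1, signed = FALSE)
  if (!identical(as.integer(magic), as.integer(TRIANGLE_FILE_MAGIC))) {
    stop("not a FreeSurfer binary triangle surface: ", path, call. = FALSE)
  }
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0) stop("truncated surface file: ", path, call. = FALSE)
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  v <- readBin(con, "double", n = 3 * nv, size = 4, endian = "big")
  f <- readBin(con, "integer", n = 3 * nf, size = 4, endian = "big")
  surface_mesh(matrix(v, ncol = 3, byrow = TRUE),
               matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(TRIANGLE_FILE_MAGIC), con)
  writeBin(charToRaw("created by ieegloc\n\n"), con)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(flatten_rowmajor(mesh$vertices)), con, size = 4,
           endian = "big")
  writeBin(as.integer(flatten_rowmajor(mesh$faces - 1L)), con, size = 4,
           endian = "big")
  invisible(path)
}
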