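#' Electrode-to-vertex mapping parameters
#'
#' @param decay_factor Dimensionless exponential decay rate (default 1.5).
#' @param max_radius Cutoff distance in mm (default 1.0); vertices farther
#'   than this from every electrode stay unassigned.
#' @param mode `"continuous"` (distance-weighted exponential average) or
#'   `"discrete"` (nearest-electrode value, for categorical data).
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(decay_factor = 1.5, max_radius = 1.0,
                           mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  if (max_radius <= 0) stop("max_radius must be positive", call. = FALSE)
  if (decay_factor < 0) stop("decay_factor must be >= 0", call. = FALSE)
  structure(list(decay_factor = decay_factor, max_radius = max_radius,
                 mode = mode), class = "mapping_params")
}

# electrodes: data frame with x, y, z and a value column, or an
# electrode_table (uses shifted coordinates when present).
electrode_points <- function(electrodes, value_col = "value") {
  stopifnot(is.data.frame(electrodes))
  if (!value_col %in% names(electrodes)) {
    stop("electrode table has no '", value_col, "' column", call. = FALSE)
  }
  xyz <- as.matrix(electrodes[, c("x", "y", "z")])
  if (all(c("x_shifted", "y_shifted", "z_shifted") %in% names(electrodes))) {
    sh <- as.matrix(electrodes[, c("x_shifted", "y_shifted", "z_shifted")])
    use <- stats::complete.cases(sh)
    xyz[use, ] <- sh[use, ]
  }
  vals <- electrodes[[value_col]]
  keep <- stats::complete.cases(xyz) & !is.na(vals)
  list(xyz = xyz[keep, , drop = FALSE], values = vals[keep])
}

#' Map per-electrode values onto surface vertices
#'
#' Continuous mode: each vertex within `max_radius` of at least one
#' valued electrode receives
#' `sum(w_i * v_i * exp(-d_i * decay_factor / max_radius)) / sum(w_i)` over
#' the in-radius electrodes, with inverse-distance weights
#' `w_i = 1 / max(d_i, 1e-6)`. Discrete mode: the raw value of the nearest
#' in-radius electrode. All other vertices are unassigned (`NA`). Electrodes
#' with unset values are skipped; shifted coordinates are used when present.
#'
#' @param mesh A [surface_mesh()].
#' @param electrodes Data frame with columns `x`, `y`, `z` and the value
#'   column (an electrode table works; shifted coordinates take precedence).
#' @param params A [mapping_params()].
#' @param value_col Name of the value column (default `"value"`).
#' @return Numeric vector of length `nrow(mesh$vertices)`; `NA` = unassigned.
#' @export
map_values <- function(mesh, electrodes, params = mapping_params(),
                       value_col = "value") {
  ep <- electrode_points(electrodes, value_col)
  if (nrow(ep$xyz) == 0L) {
    stop("no electrode has both coordinates and a value to map",
         call. = FALSE)
  }
  map_values_xyz(mesh$vertices, ep$xyz, ep$values, params)
}

map_values_xyz <- function(verts, exyz, evals, params) {
  nv <- nrow(verts)
  out <- rep(NA_real_, nv)
  # distance matrix vertex x electrode (nv * ne stays small for the meshes
  # and montages this package targets)
  d2 <- outer(rowSums(verts^2), rep(1, nrow(exyz))) +
    outer(rep(1, nv), rowSums(exyz^2)) - 2 * verts %*% t(exyz)
  d <- sqrt(pmax(d2, 0))
  within <- d <= params$max_radius
  hit <- which(rowSums(within) > 0)
  if (params$mode == "discrete") {
    for (i in hit) {
      j <- which(within[i, ])
      out[i] <- evals[j[which.min(d[i, j])]]
    }
  } else {
    for (i in hit) {
      j <- which(within[i, ])
      di <- d[i, j]
      w <- 1 / pmax(di, 1e-6)
      out[i] <- sum(w * evals[j] *
                      exp(-di * params$decay_factor / params$max_radius)) /
        sum(w)
    }
  }
  out
}

#' Map per-electrode time series onto surface vertices
#'
#' Applies [map_values()] independently at each timepoint.
#'
#' @param mesh A [surface_mesh()].
#' @param electrodes Data frame with `x`, `y`, `z` (shifted coordinates used
#'   when present).
#' @param value_matrix Numeric matrix, one row per electrode (aligned with
#'   `electrodes`) and one column per timepoint.
#' @param params A [mapping_params()].
#' @return Matrix of `nrow(mesh$vertices)` x `ncol(value_matrix)` vertex
#'   values (`NA` = unassigned).
#' @export
map_timeseries <- function(mesh, electrodes, value_matrix,
                           params = mapping_params()) {
  value_matrix <- as.matrix(value_matrix)
  if (nrow(value_matrix) != nrow(electrodes)) {
    stop("value_matrix must have one row per electrode (",
         nrow(electrodes), "), got ", nrow(value_matrix), call. = FALSE)
  }
  vapply(seq_len(ncol(value_matrix)), function(t) {
    e <- electrodes
    e$value <- value_matrix[, t]
    map_values(mesh, e, params)
  }, numeric(nrow(mesh$vertices)))
}

#' Mask electrode values below a display threshold
#'
#' Values below the threshold become `NA` and behave as unset in mapping,
#' mirroring the common display convention where only supra-threshold
#' activity is shown.
#'
#' @param values Numeric vector of per-electrode values.
#' @param threshold Scalar; values `< threshold` are masked.
#' @return The masked numeric vector.
#' @export
threshold_values <- function(values, threshold) {
  values[!is.na(values) & values < threshold] <- NA_real_
  values
}
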