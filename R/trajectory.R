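#' Snapping configuration for shaft automation
#'
#' @param search_radius mm; geometric predictions are snapped to the
#'   brightest CT density strictly closer than this (default 2.0 mm).
#' @param exclusion_radius mm; CT voxels closer than this to an already
#'   selected contact are excluded, preventing duplicate selection
#'   (default 1.5 mm, about half the common 3-3.5 mm contact pitch).
#' @param threshold,percentile Threshold spec shared with
#'   [resolve_threshold()].
#' @return A list of class `snap_config`.
#' @export
snap_config <- function(search_radius = 2.0, exclusion_radius = 1.5,
                        threshold = NULL, percentile = 99.5) {
  if (search_radius <= 0 || exclusion_radius <= 0) {
    stop("search_radius and exclusion_radius must be positive", call. = FALSE)
  }
  structure(list(search_radius = search_radius,
                 exclusion_radius = exclusion_radius,
                 threshold = threshold, percentile = percentile),
            class = "snap_config")
}

#' Snap a predicted contact position to the nearby CT density
#'
#' Among above-threshold voxels within `search_radius` of the prediction and
#' farther than `exclusion_radius` from every already-used contact, selects
#' the highest-intensity voxel (ties broken by distance to the prediction,
#' then by lowest flat voxel index), then refines from it with
#' [refine_contact()].
#'
#' @param vol A [ct_volume()].
#' @param predicted World point (mm), the geometric prediction.
#' @param cfg A [snap_config()].
#' @param used Matrix/list of world points already selected (or `NULL`).
#' @return Length-3 numeric world coordinate of the refined contact.
#' @export
snap_to_density <- function(vol, predicted, cfg = snap_config(), used = NULL) {
  thr <- resolve_threshold(vol, cfg$threshold, cfg$percentile)
  nb <- voxels_near(vol, predicted, cfg$search_radius, thr)
  if (!is.null(nb) && !is.null(used) && NROW(used) > 0) {
    used <- as_points(used)
    min_d2 <- rep(Inf, nrow(nb$world))
    for (u in seq_len(nrow(used))) {
      d2 <- rowSums(sweep(nb$world, 2, used[u, ])^2)
      min_d2 <- pmin(min_d2, d2)
    }
    keep <- min_d2 > cfg$exclusion_radius^2
    nb <- lapply(nb, function(f) {
      if (is.matrix(f)) f[keep, , drop = FALSE] else f[keep]
    })
    if (nrow(nb$world) == 0L) nb <- NULL
  }
  if (is.null(nb)) {
    stop(sprintf(
      "SnapFailure: no admissible CT density within %.2f mm of (%.2f, %.2f, %.2f)",
      cfg$search_radius, predicted[1], predicted[2], predicted[3]),
      call. = FALSE)
  }
  flat <- nb$vox[, 1] + vol$shape[1] * nb$vox[, 2] +
    vol$shape[1] * vol$shape[2] * nb$vox[, 3]
  ord <- order(-nb$intensity, nb$dist, flat)
  best <- nb$world[ord[1], ]
  refine_contact(vol, best, radius = cfg$search_radius,
                 threshold = cfg$threshold, percentile = cfg$percentile)
}

shaft_tibble <- function(pts, provenance) {
  tibble::tibble(index = seq_len(nrow(pts)),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 provenance = provenance)
}

#' Extrapolate a whole shaft from its first two contacts
#'
#' Refines the two seed contacts, then marches outward: the step between the
#' two most recently placed contacts predicts the next one, which is snapped
#' to the nearby CT density. When snapping fails (no admissible density), the
#' geometric prediction is kept with provenance `"geometric-fallback"` and a
#' warning, so one ambiguous CT region does not discard the shaft.
#'
#' @param vol A [ct_volume()].
#' @param c1,c2 World seeds for contacts 1 and 2 (mm).
#' @param n_total Total number of contacts in the shaft (>= 2).
#' @param cfg A [snap_config()].
#' @return Tibble with `index`, `x`, `y`, `z`, `provenance`
#'   (`"refined"` for the seeds, `"extrapolated"` or
#'   `"geometric-fallback"` for the rest), in shaft order.
#' @export
extrapolate_shaft <- function(vol, c1, c2, n_total, cfg = snap_config()) {
  stopifnot(n_total >= 2)
  if (sqrt(sum((as.numeric(c1) - as.numeric(c2))^2)) < 1e-9) {
    stop("the two seed contacts coincide", call. = FALSE)
  }
  pts <- matrix(NA_real_, n_total, 3)
  prov <- character(n_total)
  pts[1, ] <- refine_contact(vol, c1, radius = cfg$search_radius,
                             threshold = cfg$threshold,
                             percentile = cfg$percentile)
  pts[2, ] <- refine_contact(vol, c2, radius = cfg$search_radius,
                             threshold = cfg$threshold,
                             percentile = cfg$percentile)
  prov[1:2] <- "refined"
  for (k in seq_len(n_total)[-(1:2)]) {
    predicted <- pts[k - 1, ] + (pts[k - 1, ] - pts[k - 2, ])
    res <- tryCatch(
      snap_to_density(vol, predicted, cfg, used = pts[seq_len(k - 1), ,
                                                      drop = FALSE]),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("contact ", k, ": ", conditionMessage(res),
              "; keeping the geometric prediction", call. = FALSE)
      pts[k, ] <- predicted
      prov[k] <- "geometric-fallback"
    } else {
      pts[k, ] <- res
      prov[k] <- "extrapolated"
    }
  }
  shaft_tibble(pts, prov)
}

#' Interpolate a whole shaft between its two end contacts
#'
#' Refines both endpoints, then marches from the first end, re-aiming at
#' every step: the prediction for the next contact is the current contact
#' plus the remaining straight-line vector to the refined far endpoint
#' divided by the number of gaps left. Each prediction is snapped to the
#' nearby CT density, so bends accumulate no error; the final contact is the
#' refined far endpoint itself.
#'
#' @param vol A [ct_volume()].
#' @param c_first,c_last World seeds for the first and last contact (mm).
#' @param n_total Total contact count (>= 2).
#' @param cfg A [snap_config()].
#' @return Tibble as in [extrapolate_shaft()], provenance `"interpolated"`
#'   for interior contacts.
#' @export
interpolate_shaft <- function(vol, c_first, c_last, n_total,
                              cfg = snap_config()) {
  stopifnot(n_total >= 2)
  pts <- matrix(NA_real_, n_total, 3)
  prov <- character(n_total)
  pts[1, ] <- refine_contact(vol, c_first, radius = cfg$search_radius,
                             threshold = cfg$threshold,
                             percentile = cfg$percentile)
  pts[n_total, ] <- refine_contact(vol, c_last, radius = cfg$search_radius,
                                   threshold = cfg$threshold,
                                   percentile = cfg$percentile)
  prov[1] <- prov[n_total] <- "refined"
  if (n_total > 2) {
    for (k in 2:(n_total - 1)) {
      gaps_left <- n_total - k + 1
      predicted <- pts[k - 1, ] + (pts[n_total, ] - pts[k - 1, ]) / gaps_left
      used <- pts[c(seq_len(k - 1), n_total), , drop = FALSE]
      res <- tryCatch(snap_to_density(vol, predicted, cfg, used = used),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning("contact ", k, ": ", conditionMessage(res),
                "; keeping the geometric prediction", call. = FALSE)
        pts[k, ] <- predicted
        prov[k] <- "geometric-fallback"
      } else {
        pts[k, ] <- res
        prov[k] <- "interpolated"
      }
    }
  }
  shaft_tibble(pts, prov)
}

#' Evenly spaced collinear contacts (manual, no-CT fallback)
#'
#' @param c_first,c_last World endpoints (mm).
#' @param n_total Contact count (>= 2).
#' @return Tibble with `index`, `x`, `y`, `z`, `provenance = "manual"`;
#'   endpoints exact, spacing `|c_last - c_first| / (n_total - 1)`.
#' @export
geometric_interpolate <- function(c_first, c_last, n_total) {
  stopifnot(n_total >= 2)
  a <- as.numeric(c_first); b <- as.numeric(c_last)
  t <- seq(0, 1, length.out = n_total)
  pts <- cbind(a[1] + t * (b[1] - a[1]),
               a[2] + t * (b[2] - a[2]),
               a[3] + t * (b[3] - a[3]))
  shaft_tibble(pts, rep("manual", n_total))
}
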