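#' Localize every planned group from seed contacts
#'
#' Seeds give, per group, two clicked contacts: `first` + `second` selects
#' extrapolation (march outward from the entry pair), `first` + `last`
#' selects interpolation (re-aimed march between the ends). An explicit
#' `method` column in the seeds overrides this inference. Contact counts
#' come from the plan.
#'
#' @param vol A [ct_volume()] (post-implant CT).
#' @param plan An [electrode_plan()].
#' @param seeds Data frame with columns `group`, `which` (`"first"`,
#'   `"second"` or `"last"`), `x`, `y`, `z` (world mm), optional `method`;
#'   or a path to such a TSV.
#' @param cfg A [snap_config()].
#' @return An electrode table with native coordinates, voxel coordinates
#'   and per-contact provenance filled in for every seeded group.
#' @export
localize_plan <- function(vol, plan, seeds, cfg = snap_config()) {
  plan <- electrode_plan(plan)
  if (is.character(seeds)) {
    seeds <- readr::read_tsv(seeds, show_col_types = FALSE, progress = FALSE)
  }
  seeds <- tibble::as_tibble(seeds)
  need <- c("group", "which", "x", "y", "z")
  if (!all(need %in% names(seeds))) {
    stop("seeds need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(seeds$group), plan$label)
  if (length(unknown)) {
    stop("seed group(s) not in the plan: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table <- table_from_plan(plan)
  for (g in unique(seeds$group)) {
    sg <- seeds[seeds$group == g, ]
    n_total <- plan$n_contacts[plan$label == g]
    first <- sg[sg$which == "first", ]
    if (nrow(first) != 1L) {
      stop("group '", g, "': seeds must contain exactly one 'first' contact",
           call. = FALSE)
    }
    p1 <- c(first$x, first$y, first$z)
    method <- if ("method" %in% names(sg) && !all(is.na(sg$method))) {
      stats::na.omit(sg$method)[1]
    } else if (any(sg$which == "second")) "extrapolate" else "interpolate"
    if (method == "extrapolate") {
      second <- sg[sg$which == "second", ]
      if (nrow(second) != 1L) {
        stop("group '", g, "': extrapolation needs a 'second' seed contact",
             call. = FALSE)
      }
      res <- extrapolate_shaft(vol, p1, c(second$x, second$y, second$z),
                               n_total, cfg)
    } else {
      last <- sg[sg$which == "last", ]
      if (nrow(last) != 1L) {
        stop("group '", g, "': interpolation needs a 'last' seed contact",
             call. = FALSE)
      }
      res <- interpolate_shaft(vol, p1, c(last$x, last$y, last$z),
                               n_total, cfg)
    }
    rows <- which(table$group == g)
    table$x[rows] <- res$x
    table$y[rows] <- res$y
    table$z[rows] <- res$z
    table$provenance[rows] <- res$provenance
  }
  # voxel coordinates consistent with the CT affine
  loc <- which(!is.na(table$x))
  if (length(loc)) {
    v <- world_to_voxel(vol, as.matrix(table[loc, c("x", "y", "z")]))
    table$vox_i <- NA_real_
    table$vox_j <- NA_real_
    table$vox_k <- NA_real_
    table$vox_i[loc] <- v[, 1]
    table$vox_j[loc] <- v[, 2]
    table$vox_k[loc] <- v[, 3]
  }
  table
}
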