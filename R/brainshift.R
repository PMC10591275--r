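#' Correct ECoG brain shift by projection onto the pial envelope
#'
#' Subdural (ECoG) electrodes sit on the brain surface by construction, so a
#' post-implant CT position found *inside* the preoperative pial envelope
#' must reflect brain shift. Only contacts whose plan group is of an ECoG
#' kind are corrected; sEEG contacts are never touched. Interior ECoG
#' contacts are moved to the surface in two stages:
#'
#' 1. independent exact nearest-point projection of each interior contact;
#' 2. topology regularization — minimize
#'    `sum ||s_i - proj_i||^2 + lambda_topo * sum_(i,j adjacent)
#'    (||s_i - s_j|| - ||o_i - o_j||)^2`
#'    by coordinate-wise relaxation sweeps (at most 100, or relative change
#'    < 1e-6), re-projecting every `s_i` onto the surface after each sweep.
#'
#' Adjacency is the 4-neighbourhood within a grid (row-major contact
#' numbering) and chain neighbours within a strip. Original coordinates are
#' always retained; shifted ones are written to `x_shifted`/`y_shifted`/
#' `z_shifted`.
#'
#' @param table An electrode table with native coordinates.
#' @param plan The [electrode_plan()] declaring group kinds and grid
#'   dimensions.
#' @param mesh A closed [surface_mesh()] (pial envelope); a list of meshes
#'   (e.g. one per hemisphere) is accepted, each contact using the mesh with
#'   the nearer vertex centroid.
#' @param lambda_topo Weight (>= 0) of the adjacency-distance penalty;
#'   default 1.0. At 0 the correction is pure nearest-point projection.
#' @return The electrode table with shifted coordinates for corrected
#'   contacts and `provenance` annotated with `"+shifted"`.
#' @export
correct_brain_shift <- function(table, plan, mesh, lambda_topo = 1.0) {
  stopifnot(lambda_topo >= 0)
  meshes <- if (inherits(mesh, "surface_mesh")) list(mesh) else mesh
  for (m in meshes) {
    if (!is_closed(m)) {
      stop("brain-shift correction requires a closed pial envelope mesh",
           call. = FALSE)
    }
  }
  plan <- electrode_plan(plan)
  if (!"x_shifted" %in% names(table)) {
    table$x_shifted <- table$y_shifted <- table$z_shifted <- NA_real_
  }
  centroids <- t(vapply(meshes, function(m) colMeans(m$vertices), numeric(3)))

  for (g in seq_len(nrow(plan))) {
    kind <- plan$kind[g]
    if (kind == "sEEG") next
    rows <- which(table$group == plan$label[g] &
                    stats::complete.cases(table[, c("x", "y", "z")]))
    if (length(rows) == 0L) next
    o <- as.matrix(table[rows, c("x", "y", "z")])

    # assign the whole group to the mesh nearest its mean contact
    mi <- which.min(rowSums(sweep(centroids, 2, colMeans(o))^2))
    m <- meshes[[mi]]

    interior <- is_inside(m, o)
    if (!any(interior)) next

    adj <- group_adjacency(plan[g, ])
    if (!is.null(adj)) {
      # remap within-group contact indices to row positions among the
      # located contacts, dropping pairs with an unlocated member
      idx <- table$index[rows]
      a1 <- match(adj[, 1], idx); a2 <- match(adj[, 2], idx)
      keep <- !is.na(a1) & !is.na(a2)
      adj <- cbind(a1[keep], a2[keep])
    }
    if (is.null(adj)) {
      warning("group '", plan$label[g],
              "' lacks adjacency info; falling back to pure projection",
              call. = FALSE)
      s <- project_to_surface(m, o[interior, , drop = FALSE])
    } else {
      s <- shift_group(o, interior, m, adj, lambda_topo)
    }
    ri <- rows[interior]
    table$x_shifted[ri] <- s[, 1]
    table$y_shifted[ri] <- s[, 2]
    table$z_shifted[ri] <- s[, 3]
    table$provenance[ri] <- paste0(
      ifelse(is.na(table$provenance[ri]), "manual", table$provenance[ri]),
      "+shifted")
  }
  table
}

# Adjacency pairs (two-column matrix of within-group indices) for a plan row.
group_adjacency <- function(group) {
  if (group$kind == "ECoG-strip" || group$kind == "sEEG") {
    n <- group$n_contacts
    if (n < 2L) return(matrix(integer(), 0, 2))
    return(cbind(1:(n - 1), 2:n))
  }
  if (group$kind == "ECoG-grid") {
    if (is.na(group$rows) || is.na(group$cols)) return(NULL)
    r <- group$rows; cl <- group$cols
    at <- function(i, j) (i - 1L) * cl + j  # row-major numbering
    pairs <- list()
    for (i in seq_len(r)) for (j in seq_len(cl)) {
      if (j < cl) pairs[[length(pairs) + 1]] <- c(at(i, j), at(i, j + 1L))
      if (i < r) pairs[[length(pairs) + 1]] <- c(at(i, j), at(i + 1L, j))
    }
    return(do.call(rbind, pairs))
  }
  NULL
}

# Two-stage shift of one ECoG group. o: all located contacts (within-group
# order); interior: logical mask of contacts to move. Returns the shifted
# coordinates for the interior contacts only.
shift_group <- function(o, interior, mesh, adj, lambda_topo) {
  n <- nrow(o)
  proj <- o
  proj[interior, ] <- project_to_surface(mesh, o[interior, , drop = FALSE])
  s <- proj

  # original inter-contact distances over adjacent pairs
  d0 <- sqrt(rowSums((o[adj[, 1], , drop = FALSE] -
                        o[adj[, 2], , drop = FALSE])^2))

  neighbours <- lapply(seq_len(n), function(i) {
    k <- which(adj[, 1] == i | adj[, 2] == i)
    j <- ifelse(adj[k, 1] == i, adj[k, 2], adj[k, 1])
    list(j = j, d0 = d0[k])
  })

  obj <- function(s) {
    fit <- sum((s[interior, ] - proj[interior, , drop = FALSE])^2)
    d <- sqrt(rowSums((s[adj[, 1], , drop = FALSE] -
                         s[adj[, 2], , drop = FALSE])^2))
    fit + lambda_topo * sum((d - d0)^2)
  }

  prev <- obj(s)
  for (sweep_i in seq_len(100L)) {
    for (i in which(interior)) {
      nb <- neighbours[[i]]
      if (length(nb$j) == 0L || lambda_topo == 0) {
        s[i, ] <- proj[i, ]
        next
      }
      # spring relaxation: target at the original distance from each
      # neighbour, along the current direction
      targets <- matrix(NA_real_, length(nb$j), 3)
      for (q in seq_along(nb$j)) {
        dirv <- s[i, ] - s[nb$j[q], ]
        len <- sqrt(sum(dirv^2))
        dirv <- if (len < 1e-9) c(1, 0, 0) else dirv / len
        targets[q, ] <- s[nb$j[q], ] + nb$d0[q] * dirv
      }
      s[i, ] <- (proj[i, ] + lambda_topo * colSums(targets)) /
        (1 + lambda_topo * length(nb$j))
    }
    s[interior, ] <- project_to_surface(mesh, s[interior, , drop = FALSE])
    cur <- obj(s)
    if (abs(prev - cur) <= 1e-6 * max(prev, 1e-12)) break
    prev <- cur
  }
  s[interior, , drop = FALSE]
}
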