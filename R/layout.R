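# Sensor layouts and spatial adjacency.

#' Square-grid sensor layout
#'
#' Places `n` sensors on the smallest square grid that holds them, with unit
#' spacing. The default desk-scale simulations use an 8 x 8 grid (64 sensors).
#'
#' @param n number of sensors.
#' @return data frame with columns `sensor` (id string), `x`, `y`.
#' @export
grid_layout <- function(n = 64) {
  stopifnot(n >= 1)
  side <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  data.frame(
    sensor = sprintf("S%03d", seq_len(n)),
    x = as.numeric(idx %% side),
    y = as.numeric(idx %/% side),
    stringsAsFactors = FALSE
  )
}

#' Helmet-like concentric sensor layout
#'
#' Approximates a whole-head axial gradiometer array (275 sensors by default)
#' by concentric rings of increasing radius. Intended for scale testing, not
#' for anatomical realism.
#'
#' @param n number of sensors.
#' @return data frame with columns `sensor`, `x`, `y`.
#' @export
helmet_layout <- function(n = 275) {
  stopifnot(n >= 1)
  pts <- matrix(0, 0, 2)
  ring <- 0
  while (nrow(pts) < n) {
    k <- if (ring == 0) 1 else round(2 * pi * ring / 0.9)
    ang <- 2 * pi * seq_len(k) / k + ring * 0.35
    pts <- rbind(pts, cbind(ring * cos(ang), ring * sin(ang)))
    ring <- ring + 1
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  data.frame(sensor = sprintf("S%03d", seq_len(n)),
             x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
}

#' Sensor adjacency matrix
#'
#' Builds the symmetric neighbour structure used by the cluster-based
#' permutation test. For grid layouts the default radius captures the 8
#' surrounding sensors (rook + bishop moves); alternatively a k-nearest
#' neighbour rule (symmetrized) suits irregular helmet layouts.
#'
#' @param layout sensor layout data frame (`sensor`, `x`, `y`).
#' @param method `"radius"` or `"knn"`.
#' @param radius neighbourhood radius; default 1.5 times the smallest
#'   inter-sensor distance (captures diagonal grid neighbours).
#' @param k number of nearest neighbours when `method = "knn"`.
#' @return logical `n x n` matrix, symmetric, `FALSE` diagonal.
#' @export
sensor_adjacency <- function(layout, method = c("radius", "knn"),
                             radius = NULL, k = 6) {
  method <- match.arg(method)
  if (anyDuplicated(layout$sensor)) stop("duplicate sensor ids in layout")
  n <- nrow(layout)
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  if (method == "radius") {
    if (is.null(radius)) {
      dmin <- min(d[upper.tri(d)])
      radius <- 1.5 * dmin
    }
    adj <- d <= radius & d > 0
  } else {
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:min(k + 1, n)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(layout$sensor, layout$sensor)
  adj
}

# Connected components of a sensor subset under an adjacency matrix.
# Returns a list of integer index vectors (into the full sensor set).
connected_components <- function(members, adjacency) {
  members <- which(members)
  comps <- list()
  seen <- logical(length(members))
  names(seen) <- members
  pool <- members
  while (length(pool) > 0) {
    frontier <- pool[1]
    comp <- frontier
    pool <- pool[-1]
    while (length(frontier) > 0) {
      nb <- which(adjacency[frontier[1], ])
      nb <- intersect(nb, pool)
      frontier <- c(frontier[-1], nb)
      comp <- c(comp, nb)
      pool <- setdiff(pool, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}
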