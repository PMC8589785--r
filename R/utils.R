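#' @keywords internal
#' @importFrom stats rnorm pnorm qnorm qf sd var quantile plogis setNames
#' @importFrom utils read.csv write.csv
#' @importFrom MASS mvrnorm
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic entry points funnel through this so that a `seed` argument
# fully determines the output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Label connected components of a voxel set
#'
#' Labels the connected components of a sparse set of voxels on a regular
#' grid, using face connectivity (6-neighbour in 3D, 4-neighbour in 2D).
#' Operates on linear voxel indices so only the occupied voxels are touched.
#'
#' @param idx integer vector of linear indices into an array of dimension
#'   `dim` (1-based, as produced by `which()` on a logical array).
#' @param dim integer vector of array dimensions (length 2 or 3).
#' @return integer vector of component labels (1-based, arbitrary order),
#'   parallel to `idx`; `integer(0)` for empty input.
#' @export
label_components <- function(idx, dim) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  nd <- length(dim)
  stopifnot(nd %in% c(2L, 3L))
  coords <- arrayInd(idx, dim)
  ord <- order(idx)
  sidx <- idx[ord]
  # neighbour offsets in linear index space (valid only away from edges;
  # edge wrap is guarded by coordinate checks below)
  strides <- c(1L, dim[1L], if (nd == 3L) dim[1L] * dim[2L] else NULL)
  labels <- integer(n)
  cur <- 0L
  # BFS over occupied voxels
  lab_sorted <- integer(n)
  scoords <- coords[ord, , drop = FALSE]
  for (start in seq_len(n)) {
    if (lab_sorted[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab_sorted[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      for (d in seq_len(nd)) {
        for (s in c(-1L, 1L)) {
          cand_coord <- scoords[q, d] + s
          ok <- cand_coord >= 1L & cand_coord <= dim[d]
          if (!any(ok)) next
          cand <- sidx[q[ok]] + s * strides[d]
          p <- findInterval(cand, sidx)
          hit <- p >= 1L & sidx[pmax(p, 1L)] == cand
          p <- p[hit]
          p <- p[lab_sorted[p] == 0L]
          if (length(p)) {
            p <- unique(p)
            lab_sorted[p] <- cur
            queue <- c(queue, p)
          }
        }
      }
    }
  }
  labels[ord] <- lab_sorted
  labels
}

# world coordinates (mm) of voxel centres along each axis, centred grid
grid_axes <- function(dim, spacing) {
  lapply(seq_along(dim), function(d) {
    (seq_len(dim[d]) - (dim[d] + 1) / 2) * spacing[d]
  })
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a
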