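# Cell/nucleus segmentation for smFISH stacks: Otsu thresholding on
# maximum-intensity projections, connected-component labeling, and a
# seeded watershed-style growth that splits touching cells along the
# geodesic midline between their nuclei.

#' Wrap a 3D intensity array as an image stack
#'
#' Arrays are indexed `[z, y, x]`. Coordinates reported by the spot
#' detector are 1-based continuous voxel-center positions in this frame.
#'
#' @param arr Non-negative 3D numeric array `(z, y, x)`.
#' @param channel Label, e.g. `"nuclear"` or `"fish"`.
#' @return The array with class `ImageStack` and a `channel` attribute.
#' @export
image_stack <- function(arr, channel = "fish") {
  stopifnot(is.array(arr), length(dim(arr)) == 3L, all(arr >= 0))
  structure(arr, channel = channel, class = c("ImageStack", class(arr)))
}

#' Maximum-intensity projection along z
#' @param stack 3D array `(z, y, x)`.
#' @return 2D matrix `(y, x)`.
#' @export
max_project <- function(stack) {
  apply(stack, c(2, 3), max)
}

#' Otsu threshold of an image
#'
#' Maximizes between-class variance over a binned intensity histogram.
#' Constant images return `Inf` (nothing above threshold).
#'
#' @param x Numeric vector/matrix of intensities.
#' @param nbins Number of histogram bins (default 256).
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  r <- range(x)
  if (diff(r) == 0) return(Inf)
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  # on a plateau (clean bimodal gap) take the middle bin, not its edge
  top <- which(between >= max(between) - 1e-12 * max(between))
  mids[top[ceiling(length(top) / 2)]]
}

# 8-connected component labeling of a logical matrix via vectorized BFS
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  nextlab <- 0L
  offsets <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  row_of <- function(p) ((p - 1L) %% nr) + 1L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    lab[seed] <- nextlab
    frontier <- seed
    while (length(frontier)) {
      cand <- integer(0)
      fr <- row_of(frontier)
      for (k in seq_along(offsets)) {
        o <- offsets[k]
        # suppress wraps across matrix columns
        okrow <- if (o %in% c(-1L, -nr - 1L, nr - 1L)) fr > 1L
                 else if (o %in% c(1L, -nr + 1L, nr + 1L)) fr < nr
                 else rep(TRUE, length(frontier))
        nb <- frontier[okrow] + o
        nb <- nb[nb >= 1L & nb <= nr * nc]
        cand <- c(cand, nb[mask[nb] & lab[nb] == 0L])
      }
      cand <- unique(cand)
      lab[cand] <- nextlab
      frontier <- cand
    }
  }
  lab
}

# grow seed labels over mask by iterative 4-neighbor dilation (geodesic
# distance watershed); earlier directions win ties deterministically
.grow_labels <- function(seeds, mask) {
  nr <- nrow(seeds); nc <- ncol(seeds)
  lab <- seeds
  lab[!mask] <- 0L
  offsets <- c(-1L, 1L, -nr, nr)
  repeat {
    frontier <- which(lab != 0L)
    grew <- FALSE
    fr <- ((frontier - 1L) %% nr) + 1L
    for (k in seq_along(offsets)) {
      o <- offsets[k]
      okrow <- if (o == -1L) fr > 1L else if (o == 1L) fr < nr
               else rep(TRUE, length(frontier))
      src <- frontier[okrow]
      nb <- src + o
      keep <- nb >= 1L & nb <= nr * nc
      src <- src[keep]; nb <- nb[keep]
      sel <- mask[nb] & lab[nb] == 0L
      if (any(sel)) {
        lab[nb[sel]] <- lab[src[sel]]
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  lab
}

#' Segment cells and nuclei from a paired smFISH field
#'
#' Max-projects both channels, thresholds the nuclear channel (Otsu) to
#' find nuclei and the FISH channel to find cell bodies (diffuse
#' cytoplasmic signal), then grows cell labels outward from the nuclei over
#' the cell mask, splitting touching cells along the geodesic midline
#' (seeded watershed). Cell-mask area unreachable from any nucleus is
#' discarded. Each nucleus keeps the label of its cell.
#'
#' @param nuclear_stack,fish_stack 3D arrays `(z, y, x)` of equal `(y, x)`
#'   shape.
#' @param min_nucleus_px Minimum nucleus size in projected pixels
#'   (default 20).
#' @param fallback_dilate If the FISH channel yields no usable cell mask,
#'   cells are approximated by dilating nuclei this many pixels
#'   (default 8).
#' @return List of class `CellSegmentation` with integer label matrices
#'   `cells` and `nuclei` (`(y, x)`, 0 = background) and `n_cells`.
#' @export
segment_cells <- function(nuclear_stack, fish_stack, min_nucleus_px = 20L,
                          fallback_dilate = 8L) {
  stopifnot(all(dim(nuclear_stack)[2:3] == dim(fish_stack)[2:3]))
  nuc_proj <- max_project(nuclear_stack)
  fish_proj <- max_project(fish_stack)

  nuc_mask <- nuc_proj > otsu_threshold(nuc_proj)
  nuclei <- .label_components(nuc_mask)
  sizes <- tabulate(nuclei)
  drop <- which(sizes < min_nucleus_px)
  if (length(drop)) nuclei[nuclei %in% drop] <- 0L
  labs <- sort(unique(nuclei[nuclei > 0L]))
  nuclei <- matrix(match(nuclei, labs, nomatch = 0L),
                   nrow(nuclei), ncol(nuclei))
  if (length(labs) == 0L) {
    out <- list(cells = matrix(0L, nrow(nuc_proj), ncol(nuc_proj)),
                nuclei = nuclei, n_cells = 0L)
    class(out) <- "CellSegmentation"
    return(out)
  }

  cell_mask <- fish_proj > otsu_threshold(fish_proj)
  cell_mask <- cell_mask | nuclei > 0L
  if (sum(cell_mask) <= sum(nuclei > 0L)) {
    # flat FISH channel: dilate nuclei instead
    cell_mask <- .dilate(nuclei > 0L, fallback_dilate)
  }
  cells <- .grow_labels(nuclei, cell_mask)
  # nuclei must sit inside their cells; orphaned nuclei removed
  nuclei[cells == 0L] <- 0L
  out <- list(cells = cells, nuclei = nuclei,
              n_cells = length(unique(cells[cells > 0L])))
  class(out) <- "CellSegmentation"
  out
}

.dilate <- function(mask, r) {
  out <- mask
  nr <- nrow(mask)
  for (i in seq_len(r)) {
    idx <- which(out)
    rows <- ((idx - 1L) %% nr) + 1L
    nb <- c(idx[rows > 1L] - 1L, idx[rows < nr] + 1L,
            idx[idx > nr] - nr, idx[idx <= nr * (ncol(mask) - 1L)] + nr)
    out[nb] <- TRUE
  }
  out
}

#' @export
print.CellSegmentation <- function(x, ...) {
  cat(sprintf("CellSegmentation: %d cell(s) on a %d x %d field\n",
              x$n_cells, nrow(x$cells), ncol(x$cells)))
  invisible(x)
}
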