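# Synthetic smFISH fields: disk cells with interior nuclei on a nuclear
# channel, planted 3D Gaussian spots on the FISH channel, Gaussian read
# noise, and a full planted-truth record (masks, centers, intensities).

#' Simulate a paired smFISH image field with planted ground truth
#'
#' Cells are rendered as disks on a jittered grid with concentric nuclei.
#' Cytoplasmic spots (single RNAs, intensity lognormal around 1 RNA) and
#' nuclear candidate transcription sites are planted as 3D Gaussians whose
#' amplitude is `rna * unit_amplitude`; each allele is active with
#' probability `active_fraction` (bright site) and otherwise either silent
#' or a dim sub-threshold focus. Planted spots keep a minimum mutual
#' distance so detection truth-matching is unambiguous. All intensities are
#' clamped at zero after adding Gaussian read noise.
#'
#' @param n_cells Number of cells (default 9); error if they do not fit.
#' @param dim Stack dimensions `c(z, y, x)` (default `c(27, 192, 192)`, 27
#'   z-planes as in a typical acquisition).
#' @param cell_radius,nucleus_radius Disk radii in pixels (defaults 20
#'   and 10).
#' @param n_cyto Cytoplasmic spots per cell (default 25).
#' @param n_sites Nuclear candidate sites (alleles) per cell (default 2).
#' @param active_fraction Probability an allele carries an active site
#'   (default 0.3).
#' @param active_rna,inactive_rna Ranges (length 2) of RNA equivalents for
#'   active and dim inactive sites (defaults `c(4, 8)` and `c(0.2, 1.2)`).
#' @param p_dim_site Probability an inactive allele shows a dim focus
#'   rather than nothing (default 0.5).
#' @param sigma_xy,sigma_z PSF sigmas in pixels/planes (defaults 1.5, 1.0).
#' @param unit_amplitude Peak amplitude of a 1-RNA spot (default 60).
#' @param noise_sd Gaussian read-noise sd (default 6, i.e. SNR 10 for a
#'   single RNA).
#' @param cell_level,nuc_level Diffuse levels: FISH-channel cytoplasmic
#'   background inside cells (25) and nuclear-channel level inside nuclei
#'   (120).
#' @param camera_offset Constant detector baseline added to both channels
#'   (default 100, a typical sCMOS offset), so read noise is Gaussian
#'   everywhere rather than clipped at zero.
#' @param min_separation Minimum distance between planted spots in pixels
#'   (default 5).
#' @param seed Integer seed.
#' @return List of class `SmfishField`: `nuclear` and `fish`
#'   ([image_stack()]s) and `truth` (list: `cells`, `nuclei` label
#'   matrices, `spots` data.frame with planted centers/intensities,
#'   `sites` data.frame with per-allele activity).
#' @export
simulate_smfish_stack <- function(n_cells = 9L, dim = c(27L, 192L, 192L),
                                  cell_radius = 20, nucleus_radius = 10,
                                  n_cyto = 25L, n_sites = 2L,
                                  active_fraction = 0.3,
                                  active_rna = c(4, 8),
                                  inactive_rna = c(0.2, 1.2),
                                  p_dim_site = 0.5,
                                  sigma_xy = 1.5, sigma_z = 1.0,
                                  unit_amplitude = 60, noise_sd = 6,
                                  cell_level = 25, nuc_level = 120,
                                  camera_offset = 100,
                                  min_separation = 5, seed = 1L) {
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  pitch <- ceiling(2 * cell_radius + 6)
  per_row <- max(1L, (nx - 8L) %/% pitch)
  n_rows <- max(1L, (ny - 8L) %/% pitch)
  if (n_cells > per_row * n_rows)
    stop("cells do not fit in the requested field", call. = FALSE)
  with_seed(seed, {
    cells <- matrix(0L, ny, nx)
    nuclei <- matrix(0L, ny, nx)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    centers <- matrix(0, n_cells, 2)
    for (i in seq_len(n_cells)) {
      gy <- (i - 1L) %/% per_row
      gx <- (i - 1L) %% per_row
      cy <- 4 + gy * pitch + cell_radius + 1 + runif(1, -2, 2)
      cx <- 4 + gx * pitch + cell_radius + 1 + runif(1, -2, 2)
      centers[i, ] <- c(cy, cx)
      d2 <- (yy - cy)^2 + (xx - cx)^2
      cells[d2 <= cell_radius^2] <- i
      nuclei[d2 <= nucleus_radius^2] <- i
    }

    if (n_cells == 0L) {
      spot_df <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                            rna = numeric(0), amplitude = numeric(0),
                            cell = integer(0), compartment = character(0))
      sites <- data.frame(cell = integer(0), allele = integer(0),
                          rna = numeric(0), active = logical(0))
    } else {
      placed <- matrix(numeric(0), 0, 3)  # z, y, x
      zmargin <- max(1, min(4, floor((nz - 1) / 3)))
      place_spot <- function(cy, cx, rmin, rmax) {
        for (try in 1:2000) {
          r <- sqrt(runif(1, rmin^2, rmax^2))
          th <- runif(1, 0, 2 * pi)
          y <- cy + r * sin(th); x <- cx + r * cos(th)
          z <- runif(1, 1 + zmargin, nz - zmargin)
          if (nrow(placed) == 0L ||
              min((placed[, 1] - z)^2 + (placed[, 2] - y)^2 +
                    (placed[, 3] - x)^2) >= min_separation^2) {
            placed <<- rbind(placed, c(z, y, x))
            return(c(z, y, x))
          }
        }
        stop("could not place spots at the requested separation",
             call. = FALSE)
      }
      rows <- list()
      sites <- list()
      for (i in seq_len(n_cells)) {
        cy <- centers[i, 1]; cx <- centers[i, 2]
        for (s in seq_len(n_cyto)) {
          p <- place_spot(cy, cx, nucleus_radius + 2, cell_radius - 2)
          rna <- exp(rnorm(1, 0, 0.15))
          rows[[length(rows) + 1L]] <- data.frame(
            z = p[1], y = p[2], x = p[3], rna = rna,
            amplitude = rna * unit_amplitude, cell = i,
            compartment = "cytoplasmic")
        }
        for (a in seq_len(n_sites)) {
          active <- runif(1) < active_fraction
          rna <- if (active) runif(1, active_rna[1], active_rna[2])
                 else if (runif(1) < p_dim_site)
                   runif(1, inactive_rna[1], inactive_rna[2])
                 else 0
          sites[[length(sites) + 1L]] <- data.frame(
            cell = i, allele = a, rna = rna, active = active)
          if (rna > 0) {
            p <- place_spot(cy, cx, 0, nucleus_radius - 2)
            rows[[length(rows) + 1L]] <- data.frame(
              z = p[1], y = p[2], x = p[3], rna = rna,
              amplitude = rna * unit_amplitude, cell = i,
              compartment = "nuclear")
          }
        }
      }
      spot_df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                   rna = numeric(0), amplitude = numeric(0),
                   cell = integer(0), compartment = character(0))
      sites <- do.call(rbind, sites)
    }

    fish <- array(camera_offset, c(nz, ny, nx))
    in_cell <- cells > 0L
    for (z in seq_len(nz)) fish[z, , ][in_cell] <- camera_offset + cell_level
    # render 3D Gaussian spots over a +/- 4 sigma window
    wz <- ceiling(4 * sigma_z); wxy <- ceiling(4 * sigma_xy)
    for (s in seq_len(nrow(spot_df))) {
      z0 <- spot_df$z[s]; y0 <- spot_df$y[s]; x0 <- spot_df$x[s]
      zi <- max(1, floor(z0 - wz)):min(nz, ceiling(z0 + wz))
      yi <- max(1, floor(y0 - wxy)):min(ny, ceiling(y0 + wxy))
      xi <- max(1, floor(x0 - wxy)):min(nx, ceiling(x0 + wxy))
      gz <- exp(-(zi - z0)^2 / (2 * sigma_z^2))
      gy <- exp(-(yi - y0)^2 / (2 * sigma_xy^2))
      gx <- exp(-(xi - x0)^2 / (2 * sigma_xy^2))
      fish[zi, yi, xi] <- fish[zi, yi, xi] +
        spot_df$amplitude[s] * outer(outer(gz, gy), gx)
    }
    nuc <- array(camera_offset, c(nz, ny, nx))
    in_nuc <- nuclei > 0L
    for (z in seq_len(nz)) nuc[z, , ][in_nuc] <- camera_offset + nuc_level
    if (noise_sd > 0) {
      fish <- fish + rnorm(length(fish), 0, noise_sd)
      nuc <- nuc + rnorm(length(nuc), 0, noise_sd)
    }
    fish <- pmax(fish, 0); dim(fish) <- c(nz, ny, nx)
    nuc <- pmax(nuc, 0); dim(nuc) <- c(nz, ny, nx)
    structure(list(
      nuclear = image_stack(nuc, "nuclear"),
      fish = image_stack(fish, "fish"),
      truth = list(cells = cells, nuclei = nuclei, spots = spot_df,
                   sites = sites)),
      class = "SmfishField")
  })
}
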