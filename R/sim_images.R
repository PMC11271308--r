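#' Parameters for the synthetic fat-body image generator
#'
#' @param shape image shape in pixels, `c(rows, cols)`
#' @param n_cells number of cells to place
#' @param membrane_enrichment ratio of membrane to cytoplasm mean
#'   reporter intensity (>= 1)
#' @param droplet_area_fraction target fraction of each cell's area
#'   covered by lipid droplets, in `[0, 1)`
#' @param noise_sd additive Gaussian noise SD (intensity units)
#' @param seed integer seed
#' @return object of class `image_sim_params`
#' @export
image_sim_params <- function(shape = c(128, 128), n_cells = 4,
                             membrane_enrichment = 1,
                             droplet_area_fraction = 0,
                             noise_sd = 0, seed = 1) {
  if (length(shape) != 2L) stop_param("shape must be c(rows, cols)")
  p <- list(
    shape = c(check_count(shape[1], "rows"), check_count(shape[2], "cols")),
    n_cells = check_count(n_cells, "n_cells"),
    membrane_enrichment = check_number(membrane_enrichment,
                                       "membrane_enrichment", min = 1),
    droplet_area_fraction = check_number(droplet_area_fraction,
                                         "droplet_area_fraction", min = 0,
                                         max = 1 - 1e-9),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(p, class = "image_sim_params")
}

disk_mask <- function(shape, center, radius) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Simulate a fat-body tissue image with planted ground truth
#'
#' Cells are laid out on a rectangular grid of equal square tiles so
#' that nuclei sit at tile centers and the shared tile boundaries act as
#' plasma membranes: the midpoint of any line between two adjacent
#' nuclei falls exactly on the membrane, as required by the
#' nucleus-to-nucleus line-profile score. The membrane band half-width
#' is 5% of the tile side, so the band covers exactly the central 10%
#' of an adjacent-nucleus line and the surround windows sample pure
#' cytoplasm. Before noise, membrane pixels of the reporter channel have
#' mean intensity `membrane_enrichment` times the cytoplasm mean.
#' Lipid droplets are non-overlapping disks placed on an interior grid
#' of each cell until the planted area fraction is matched to within
#' one droplet's area.
#'
#' @param params an [image_sim_params()] object
#' @return list with `stack` (an [image_stack()] with channels
#'   `reporter`, `membrane`, `nuclei`, `droplet`), `truth` (masks
#'   `cell_labels`, `membrane_mask`, `droplet_mask`; `nuclei` centers as
#'   0-based `(row, col)`; `pairs` of adjacent-nucleus index pairs;
#'   planted `cytoplasm_mean` and `membrane_mean`), and `params`
#' @export
sim_fatbody_image <- function(params = image_sim_params()) {
  if (!inherits(params, "image_sim_params"))
    stop_param("params must be an image_sim_params object")
  shape <- params$shape
  n <- params$n_cells
  # grid with tiles as close to square as the shape allows
  k_r <- max(1L, round(sqrt(n * shape[1] / shape[2])))
  k_c <- ceiling(n / k_r)
  while (k_r * k_c < n) k_c <- k_c + 1L
  side <- min(floor(shape[1] / k_r), floor(shape[2] / k_c))
  # odd tile side puts nucleus centers on integer pixels, so a
  # nucleus-to-nucleus line samples the lattice exactly (no bilinear
  # blur of the membrane edge into the surround window)
  if (side %% 2L == 0L) side <- side - 1L
  if (side < 24L)
    stop_param("shape too small to place ", n, " cells (tile side ", side,
               " px < 24 px)")
  hw <- 0.05 * side # membrane band half-width: 5% of nucleus spacing

  r_idx <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c_idx <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  tile_r <- pmin(r_idx %/% side, k_r - 1)
  tile_c <- pmin(c_idx %/% side, k_c - 1)
  in_tissue <- r_idx < k_r * side & c_idx < k_c * side
  cell_id <- ifelse(in_tissue, tile_r * k_c + tile_c + 1, 0)
  cell_id[cell_id > n] <- 0
  # distance to the nearest tile boundary (interior grid lines and the
  # tissue outline)
  dr <- pmin(r_idx %% side, side - 1 - r_idx %% side) + 0.5
  dc <- pmin(c_idx %% side, side - 1 - c_idx %% side) + 0.5
  membrane_mask <- cell_id > 0 & (dr <= hw | dc <= hw)

  centers <- t(vapply(seq_len(n), function(i) {
    tr <- (i - 1) %/% k_c
    tc <- (i - 1) %% k_c
    c(tr * side + (side - 1) / 2, tc * side + (side - 1) / 2)
  }, numeric(2)))
  pairs <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    tri <- (i - 1) %/% k_c; tci <- (i - 1) %% k_c
    trj <- (j - 1) %/% k_c; tcj <- (j - 1) %% k_c
    if (abs(tri - trj) + abs(tci - tcj) == 1L) pairs <- rbind(pairs, c(i, j))
  }

  nuc_r <- max(2, round(side / 10))
  nuclei_mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(n))
    nuclei_mask <- nuclei_mask | disk_mask(shape, centers[i, ], nuc_r)

  cyt <- 100
  mem <- params$membrane_enrichment * cyt
  reporter <- matrix(0, shape[1], shape[2])
  reporter[cell_id > 0] <- cyt
  reporter[membrane_mask] <- mem
  membrane_ch <- matrix(2, shape[1], shape[2])
  membrane_ch[membrane_mask] <- 200
  nuclei_ch <- matrix(2, shape[1], shape[2])
  nuclei_ch[nuclei_mask] <- 200

  # droplets: interior grid per cell, kept clear of membrane and nucleus
  droplet_mask <- matrix(FALSE, shape[1], shape[2])
  if (params$droplet_area_fraction > 0) {
    drop_r <- max(2, round(side / 12))
    drop_area <- sum(disk_mask(c(2 * drop_r + 3, 2 * drop_r + 3),
                               c(drop_r + 1, drop_r + 1), drop_r))
    cell_area <- side^2
    n_drops <- round(params$droplet_area_fraction * cell_area / drop_area)
    margin <- ceiling(hw) + drop_r + 2
    avail <- side - 2 * margin
    k <- floor(avail / (2 * drop_r + 2)) + 1
    if (n_drops > 0) {
      if (k < 1 || k * k < n_drops)
        stop_param("droplet_area_fraction too high to place ",
                   n_drops, " non-overlapping droplets per cell")
      pos1 <- if (k == 1) (side - 1) / 2 else
        seq(margin, side - 1 - margin, length.out = k)
      grid_pos <- expand.grid(r = pos1, c = pos1)
      # drop grid points nearest the nucleus first so droplets avoid it
      d_nuc <- sqrt((grid_pos$r - (side - 1) / 2)^2 +
                    (grid_pos$c - (side - 1) / 2)^2)
      keep <- order(-d_nuc)[seq_len(n_drops)]
      for (i in seq_len(n)) {
        tr <- (i - 1) %/% k_c; tc <- (i - 1) %% k_c
        for (g in keep) {
          ctr <- c(tr * side + grid_pos$r[g], tc * side + grid_pos$c[g])
          droplet_mask <- droplet_mask | disk_mask(shape, ctr, drop_r)
        }
      }
    }
  }
  droplet_ch <- matrix(5, shape[1], shape[2])
  droplet_ch[droplet_mask] <- 200

  stack <- local_seed(params$seed, {
    add_noise <- function(img) {
      if (params$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, params$noise_sd),
                            nrow(img), ncol(img))
      pmax(img, 0)
    }
    image_stack(reporter = add_noise(reporter),
                membrane = add_noise(membrane_ch),
                nuclei = add_noise(nuclei_ch),
                droplet = add_noise(droplet_ch))
  })
  list(stack = stack,
       truth = list(cell_labels = cell_id, membrane_mask = membrane_mask,
                    nuclei_mask = nuclei_mask, droplet_mask = droplet_mask,
                    nuclei = centers, pairs = pairs,
                    cytoplasm_mean = cyt, membrane_mean = mem,
                    tile_side = side),
       params = params)
}

#' Simulate a GCaMP/tdTomato neuron time series with planted ratios
#'
#' Neurons are disks in a single field. The tdTomato channel is constant
#' per neuron (up to noise); the GCaMP channel is the planted ratio
#' times the tdTomato intensity. The soma ratio equals `baseline_ratio`
#' everywhere except at `transient_times` (ratio `transient_amp`) and
#' from `kcl_frame` onward (ratio `kcl_amp`), emulating a KCl viability
#' challenge at the end of a recording.
#'
#' @param n_neurons,n_frames counts; frame indices are 1-based
#' @param baseline_ratio planted GCaMP/tdTomato soma ratio
#' @param transient_times frame indices of calcium transients
#' @param transient_amp planted ratio during a transient
#' @param kcl_frame first frame of the KCl response, or `NULL` for none;
#'   must be < `n_frames`
#' @param kcl_amp planted ratio from `kcl_frame` onward
#' @param noise_sd additive Gaussian noise SD on both channels
#' @param seed integer seed
#' @return list with `frames` (list of [image_stack()]s with channels
#'   `gcamp`, `tdtomato`), `soma_rois` (logical masks), and
#'   `truth` (`ratio_series`, the planted per-frame soma ratio)
#' @export
sim_neuron_frames <- function(n_neurons = 4, n_frames = 20,
                              baseline_ratio = 1,
                              transient_times = integer(0),
                              transient_amp = 2 * baseline_ratio,
                              kcl_frame = NULL,
                              kcl_amp = transient_amp,
                              noise_sd = 0, seed = 1) {
  n_neurons <- check_count(n_neurons, "n_neurons")
  n_frames <- check_count(n_frames, "n_frames")
  baseline_ratio <- check_number(baseline_ratio, "baseline_ratio",
                                 min = 0, strict_min = TRUE)
  if (length(transient_times) &&
      (any(transient_times < 1) || any(transient_times > n_frames)))
    stop_param("transient index out of range 1..", n_frames)
  if (!is.null(kcl_frame)) {
    kcl_frame <- check_count(kcl_frame, "kcl_frame")
    if (kcl_frame >= n_frames)
      stop_param("kcl_frame must be < n_frames")
  }
  side <- 24L
  shape <- c(side, side * n_neurons)
  soma_rois <- lapply(seq_len(n_neurons), function(i)
    disk_mask(shape, c((side - 1) / 2, (i - 1) * side + (side - 1) / 2),
              side / 4))
  ratio <- rep(baseline_ratio, n_frames)
  ratio[transient_times] <- transient_amp
  if (!is.null(kcl_frame)) ratio[kcl_frame:n_frames] <- kcl_amp
  td_level <- 100
  local_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      td <- matrix(5, shape[1], shape[2])
      gc <- matrix(5, shape[1], shape[2])
      for (i in seq_len(n_neurons)) {
        td[soma_rois[[i]]] <- td_level
        gc[soma_rois[[i]]] <- ratio[f] * td_level
      }
      if (noise_sd > 0) {
        td <- td + matrix(rnorm(length(td), 0, noise_sd), shape[1], shape[2])
        gc <- gc + matrix(rnorm(length(gc), 0, noise_sd), shape[1], shape[2])
      }
      image_stack(gcamp = pmax(gc, 0), tdtomato = pmax(td, 0))
    })
    list(frames = frames, soma_rois = soma_rois,
         truth = list(ratio_series = ratio, tdtomato_level = td_level))
  })
}
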