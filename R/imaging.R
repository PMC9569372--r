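## 3D confocal nucleus quantification: per-plane dual-Otsu segmentation,
## watershed splitting of touching nuclei, centroid linking across z,
## volume filtering, per-nucleus intensities, colocalization, and
## spheroid projected area.
##
## Conventions: a plane is a numeric matrix [row = y, col = x]; a stack
## channel is a 3D array [y, x, z].  All distances and volumes are
## computed in physical micrometres, never voxel units, so anisotropic
## voxels are handled transparently.

#' Construct a multi-channel z-stack
#'
#' @param channels named list of 3D arrays [y, x, z], all the same shape,
#'   non-negative intensities.
#' @param pixel_size_xy lateral pixel size, um/pixel.
#' @param z_step axial step, um.
#' @return object of class \code{zstack}.
#' @export
zstack <- function(channels, pixel_size_xy, z_step) {
  stopifnot(length(channels) >= 1L, !is.null(names(channels)),
            pixel_size_xy > 0, z_step > 0)
  d <- dim(channels[[1L]])
  if (length(d) != 3L) stop_malformed("channels must be 3D [y, x, z] arrays")
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop_malformed("channel shapes differ")
    if (any(ch < 0)) stop_malformed("negative intensities")
  }
  structure(list(channels = channels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, dim = d), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  cat(sprintf("z-stack: %d x %d x %d voxels, %.3g um/px, %.3g um z-step, channels: %s\n",
              x$dim[1L], x$dim[2L], x$dim[3L], x$pixel_size_xy, x$z_step,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

new_labeled_volume <- function(labels, pixel_size_xy, z_step) {
  structure(list(labels = labels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("labeled volume: %s voxels, %d labels\n",
              paste(dim(x$labels), collapse = " x "), max(x$labels)))
  invisible(x)
}

## Otsu threshold of a numeric vector/matrix; shift- and scale-invariant
## (values are normalized to [0, 1] before EBImage::otsu and the threshold
## mapped back).
.otsu_val <- function(v, levels = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  x <- (v - lo) / (hi - lo)
  t01 <- EBImage::otsu(EBImage::Image(matrix(x, ncol = 1L)),
                       range = c(0, 1), levels = levels)
  lo + t01 * (hi - lo)
}

#' Segment one z-plane by combined global and local Otsu thresholding
#'
#' The global threshold rejects dim background; the local threshold,
#' computed per block and bilinearly interpolated between block centres,
#' handles uneven illumination.  The two are combined by logical AND
#' (default) or OR.  Near-constant planes return an empty mask instead of
#' a degenerate threshold.
#'
#' @param plane numeric matrix [y, x].
#' @param block_size_px local-Otsu block edge, pixels (>= 8).
#' @param combine \code{"and"} (default) or \code{"or"}.
#' @param dynamic_floor relative dynamic-range floor: a plane (or block)
#'   with (max - min) < dynamic_floor * max is treated as constant.
#' @return logical matrix mask.
#' @export
segment_plane <- function(plane, block_size_px = 64L,
                          combine = c("and", "or"), dynamic_floor = 0.02) {
  combine <- match.arg(combine)
  if (block_size_px < 8L) stop_malformed("block_size_px must be >= 8")
  plane <- as.matrix(plane)
  if (length(plane) == 0L) stop_malformed("empty plane")
  lo <- min(plane); hi <- max(plane)
  if (hi - lo < dynamic_floor * max(hi, .Machine$double.eps))
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  gthr <- .otsu_val(plane)

  nby <- max(1L, ceiling(nrow(plane) / block_size_px))
  nbx <- max(1L, ceiling(ncol(plane) / block_size_px))
  bt <- matrix(NA_real_, nby, nbx)
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    rows <- (((by - 1L) * block_size_px + 1L):min(by * block_size_px,
                                                  nrow(plane)))
    cols <- (((bx - 1L) * block_size_px + 1L):min(bx * block_size_px,
                                                  ncol(plane)))
    blk <- plane[rows, cols]
    if (max(blk) - min(blk) >= dynamic_floor * max(max(blk),
                                                   .Machine$double.eps))
      bt[by, bx] <- .otsu_val(blk)
  }
  bt[is.na(bt)] <- gthr
  lthr <- if (nby == 1L && nbx == 1L)
    matrix(bt[1L, 1L], nrow(plane), ncol(plane))
  else as.matrix(EBImage::resize(EBImage::Image(bt), w = nrow(plane),
                                 h = ncol(plane)))
  if (combine == "and") plane > gthr & plane > lthr
  else plane > gthr | plane > lthr
}

#' Split touching nuclei in a 2D mask by seeded watershed
#'
#' Euclidean distance transform of the mask; seed peaks are its regional
#' maxima separated by at least half the nominal nuclear diameter; the
#' mask is then divided between seeds along the ridge of the (negated)
#' distance map (EBImage::propagate with a distance-dominated metric).
#' Connected components without a seed of their own keep a single label.
#'
#' @param mask logical matrix from [segment_plane()].
#' @param pixel_size_xy um/pixel.
#' @param nominal_diameter rough nuclear diameter, um.
#' @return integer label matrix (0 = background).
#' @export
split_touching <- function(mask, pixel_size_xy, nominal_diameter = 10) {
  mask <- as.matrix(mask) > 0
  lab0 <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(lab0)
  min_sep_px <- max(2, (nominal_diameter / 2) / pixel_size_xy)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dms <- EBImage::gblur(dm, sigma = max(1, min_sep_px / 6))
  dil <- EBImage::dilate(dms, EBImage::makeBrush(
    2L * as.integer(ceiling(min_sep_px / 2)) + 1L, shape = "box"))
  seeds <- (as.matrix(dms) >= as.matrix(dil) - 1e-9) & mask &
    as.matrix(dm) > 0.5
  seed_lab <- EBImage::bwlabel(EBImage::Image(seeds * 1))
  comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
  comp_m <- as.matrix(comp); seed_m <- as.matrix(seed_lab)
  ## components with no seed keep one label: plant a seed at their
  ## distance-map maximum
  ncomp <- max(comp_m)
  has_seed <- tabulate(comp_m[seed_m > 0], nbins = ncomp) > 0L
  if (any(!has_seed)) {
    dm_m <- as.matrix(dm)
    fg <- which(comp_m > 0)
    fg <- fg[!has_seed[comp_m[fg]]]
    ord <- fg[order(comp_m[fg], -dm_m[fg])]
    top <- ord[!duplicated(comp_m[ord])]       # best pixel per component
    seed_m[top] <- max(seed_m) + seq_along(top)
  }
  ws <- EBImage::propagate(x = dms, seeds = EBImage::Image(seed_m),
                           mask = EBImage::Image(mask * 1), lambda = 1e4)
  out <- as.matrix(ws)
  ## relabel contiguously, stable in seed order
  ids <- sort(unique(out[out > 0]))
  lab0[] <- match(out, ids, nomatch = 0L) * (out > 0)
  storage.mode(lab0) <- "integer"
  lab0
}

## centroids (um) of the segments of one 2D label plane
.plane_centroids <- function(lab, pixel_size_xy) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(data.frame(id = integer(), x = numeric(),
                                      y = numeric(), n = integer()))
  idx <- which(lab > 0)
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  f <- factor(lab[idx], levels = ids)
  data.frame(id = ids,
             x = as.numeric(tapply(cc, f, mean)) * pixel_size_xy,
             y = as.numeric(tapply(rr, f, mean)) * pixel_size_xy,
             n = as.integer(table(f)))
}

#' Link 2D nucleus segments across z-planes into 3D nuclei
#'
#' Between consecutive planes, segment pairs are linked greedily by
#' ascending centroid distance (each segment used at most once -- the
#' mutual-nearest rule) when their xy centroid distance is at most
#' \code{max_link_dist}.  Unlinked segments start or terminate nuclei.
#'
#' @param label_planes list of integer label matrices (one per z-plane) or
#'   a 3D array [y, x, z].
#' @param pixel_size_xy um/pixel.
#' @param z_step um between planes (stored on the result).
#' @param max_link_dist maximum centroid distance in um (default 1).
#' @return labeled_volume with contiguous positive 3D labels.
#' @export
link_z <- function(label_planes, pixel_size_xy, z_step = 1,
                   max_link_dist = 1) {
  if (is.array(label_planes) && length(dim(label_planes)) == 3L)
    label_planes <- lapply(seq_len(dim(label_planes)[3L]),
                           function(k) label_planes[, , k])
  nz <- length(label_planes)
  d <- dim(label_planes[[1L]])
  out <- array(0L, c(d, nz))
  cents <- lapply(label_planes, .plane_centroids, pixel_size_xy)
  next_label <- 0L
  ## map for plane k: integer vector over plane-label ids (contiguous)
  prev_map <- integer(0)
  for (k in seq_len(nz)) {
    ck <- cents[[k]]
    nk <- if (nrow(ck)) max(ck$id) else 0L
    map <- rep(NA_integer_, nk)
    if (k > 1L && nrow(ck) && length(prev_map)) {
      cp <- cents[[k - 1L]]
      pairs <- expand.grid(a = seq_len(nrow(cp)), b = seq_len(nrow(ck)))
      pairs$d <- sqrt((cp$x[pairs$a] - ck$x[pairs$b])^2 +
                        (cp$y[pairs$a] - ck$y[pairs$b])^2)
      pairs <- pairs[pairs$d <= max_link_dist, , drop = FALSE]
      pairs <- pairs[order(pairs$d, pairs$a, pairs$b), , drop = FALSE]
      used_a <- logical(nrow(cp)); used_b <- logical(nrow(ck))
      for (r in seq_len(nrow(pairs))) {
        a <- pairs$a[r]; b <- pairs$b[r]
        if (!used_a[a] && !used_b[b]) {
          used_a[a] <- TRUE; used_b[b] <- TRUE
          map[ck$id[b]] <- prev_map[cp$id[a]]
        }
      }
    }
    fresh <- which(is.na(map[ck$id]))
    if (length(fresh)) {
      map[ck$id[fresh]] <- next_label + seq_along(fresh)
      next_label <- next_label + length(fresh)
    }
    if (nrow(ck)) {
      lp <- label_planes[[k]]
      m3 <- array(0L, dim(lp))
      pos <- lp > 0
      m3[pos] <- map[lp[pos]]
      out[, , k] <- m3
    }
    prev_map <- map
  }
  ids <- sort(unique(out[out > 0]))
  out[] <- match(out, ids, nomatch = 0L) * (out > 0)
  storage.mode(out) <- "integer"
  new_labeled_volume(out, pixel_size_xy, z_step)
}

#' Remove small 3D segments
#'
#' Labels whose physical volume is strictly below \code{min_volume} are
#' removed; remaining labels are renumbered contiguously preserving
#' order.  Idempotent.
#'
#' @param volume labeled_volume.
#' @param min_volume um^3 threshold (default 100; an exactly-threshold
#'   object is kept).
#' @return labeled_volume.
#' @export
filter_small <- function(volume, min_volume = 100) {
  lab <- volume$labels
  vox <- volume$pixel_size_xy^2 * volume$z_step
  nmax <- max(lab)
  if (nmax == 0L) return(volume)
  counts <- tabulate(lab[lab > 0], nbins = nmax)
  keep <- which(counts * vox >= min_volume)
  newid <- integer(nmax)
  newid[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0] <- newid[lab[lab > 0]]
  storage.mode(out) <- "integer"
  new_labeled_volume(out, volume$pixel_size_xy, volume$z_step)
}

#' Full nucleus segmentation chain for a stack
#'
#' segment_plane + split_touching per plane on the nuclear channel,
#' link_z across planes, filter_small.
#'
#' @param stack zstack.
#' @param nuclear_channel channel name holding the DNA stain.
#' @param block_size_px,combine passed to [segment_plane()].
#' @param nominal_diameter passed to [split_touching()].
#' @param max_link_dist passed to [link_z()].
#' @param min_volume passed to [filter_small()].
#' @return labeled_volume.
#' @export
segment_stack <- function(stack, nuclear_channel = "dapi",
                          block_size_px = 64L, combine = "and",
                          nominal_diameter = 10, max_link_dist = 1,
                          min_volume = 100) {
  ch <- stack$channels[[nuclear_channel]]
  if (is.null(ch)) stop_malformed("no channel '%s' in stack", nuclear_channel)
  planes <- lapply(seq_len(dim(ch)[3L]), function(k) {
    m <- segment_plane(ch[, , k], block_size_px = block_size_px,
                       combine = combine)
    split_touching(m, stack$pixel_size_xy, nominal_diameter)
  })
  vol <- link_z(planes, stack$pixel_size_xy, stack$z_step, max_link_dist)
  filter_small(vol, min_volume)
}

#' Per-nucleus volume, centroid and mean channel intensities
#'
#' Mean intensity is total intensity divided by voxel count (per-voxel
#' mean); volume is voxel count times physical voxel volume.
#'
#' @param volume labeled_volume.
#' @param stack zstack sharing the volume's geometry.
#' @return data.frame: label, n_voxels, volume_um3, centroid_x/y/z_um and
#'   one \code{mean_<channel>} column per channel.
#' @export
measure_nuclei <- function(volume, stack) {
  lab <- volume$labels
  if (!identical(dim(lab), stack$dim))
    stop_malformed("label volume and stack geometries differ")
  if (abs(volume$pixel_size_xy - stack$pixel_size_xy) > 1e-9 ||
      abs(volume$z_step - stack$z_step) > 1e-9)
    stop_malformed("label volume and stack voxel sizes differ")
  nmax <- max(lab)
  vox <- volume$pixel_size_xy^2 * volume$z_step
  if (nmax == 0L)
    return(data.frame(label = integer(), n_voxels = integer(),
                      volume_um3 = numeric()))
  idx <- which(lab > 0)
  li <- lab[idx]
  d <- dim(lab)
  rr <- (idx - 1L) %% d[1L] + 1L
  cc <- ((idx - 1L) %/% d[1L]) %% d[2L] + 1L
  zz <- (idx - 1L) %/% (d[1L] * d[2L]) + 1L
  f <- factor(li, levels = seq_len(nmax))
  n <- as.integer(table(f))
  out <- data.frame(
    label = seq_len(nmax), n_voxels = n, volume_um3 = n * vox,
    centroid_x_um = as.numeric(tapply(cc, f, mean)) * volume$pixel_size_xy,
    centroid_y_um = as.numeric(tapply(rr, f, mean)) * volume$pixel_size_xy,
    centroid_z_um = as.numeric(tapply(zz, f, mean)) * volume$z_step)
  for (chn in names(stack$channels)) {
    v <- stack$channels[[chn]][idx]
    out[[paste0("mean_", chn)]] <- as.numeric(tapply(v, f, sum)) / n
  }
  out
}

#' Fraction of nuclei with high marker intensity
#'
#' Strictly greater than \code{threshold} counts as high.
#'
#' @param measurements output of [measure_nuclei()].
#' @param channel channel name.
#' @param threshold per-voxel mean intensity cutoff (default 300).
#' @return fraction in [0, 1].
#' @export
fraction_high <- function(measurements, channel, threshold = 300) {
  col <- paste0("mean_", channel)
  if (!col %in% names(measurements)) stop_malformed("no channel '%s'", channel)
  if (nrow(measurements) == 0L)
    stop_malformed("empty measurement list")
  mean(measurements[[col]] > threshold)
}

#' Pearson correlation of per-nucleus mean intensities of two channels
#'
#' @param measurements output of [measure_nuclei()].
#' @param channel_a,channel_b channel names.
#' @return Pearson r.
#' @export
nuclear_correlation <- function(measurements, channel_a, channel_b) {
  a <- measurements[[paste0("mean_", channel_a)]]
  b <- measurements[[paste0("mean_", channel_b)]]
  if (is.null(a) || is.null(b)) stop_malformed("unknown channel")
  if (length(a) < 3L) stop_malformed("need at least 3 nuclei")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_malformed("zero variance: correlation undefined")
  stats::cor(a, b)
}

#' Per-nucleus colocalization volume ratio
#'
#' Within each nucleus, every queried channel is binarized by an Otsu
#' threshold over that nucleus's own voxels; a voxel is colocalized when
#' it is foreground in all queried channels; the ratio is colocalized
#' voxels over nucleus voxels.  A channel that is constant within a
#' nucleus (e.g. saturating it entirely) falls back to the whole-channel
#' Otsu threshold; if it is constant over the whole stack the ratio is
#' reported as 0 with a warning.
#'
#' @param volume labeled_volume.
#' @param stack zstack.
#' @param channels 2 or 3 channel names.
#' @return data.frame (label, coloc_ratio).
#' @export
coloc_ratio <- function(volume, stack, channels) {
  if (!length(channels) %in% c(2L, 3L))
    stop_malformed("supply 2 or 3 channels")
  if (!all(channels %in% names(stack$channels)))
    stop_malformed("unknown channel among: %s", paste(channels, collapse = ", "))
  lab <- volume$labels
  nmax <- max(lab)
  global_thr <- vapply(channels, function(chn)
    .otsu_val(stack$channels[[chn]]), 0)
  res <- data.frame(label = seq_len(nmax), coloc_ratio = NA_real_)
  for (l in seq_len(nmax)) {
    idx <- which(lab == l)
    fg <- rep(TRUE, length(idx))
    degenerate <- FALSE
    for (chn in channels) {
      v <- stack$channels[[chn]][idx]
      thr <- .otsu_val(v)
      if (is.na(thr)) thr <- global_thr[[chn]]
      if (is.na(thr)) { degenerate <- TRUE; break }
      fg <- fg & (v > thr)
    }
    if (degenerate) {
      warning(sprintf("nucleus %d: constant channel, colocalization set to 0", l))
      res$coloc_ratio[l] <- 0
    } else res$coloc_ratio[l] <- sum(fg) / length(idx)
  }
  res
}

#' Projected area of a spheroid from a 2D autofluorescence image
#'
#' Global Otsu, largest connected foreground component, hole filling,
#' pixel count times pixel area.
#'
#' @param image 2D numeric matrix.
#' @param pixel_size_xy um/pixel.
#' @return area in um^2 (0 with a warning for an empty foreground).
#' @export
spheroid_projected_area <- function(image, pixel_size_xy) {
  image <- as.matrix(image)
  if (length(image) == 0L) stop_malformed("empty image")
  thr <- .otsu_val(image)
  if (is.na(thr) || !any(image > thr)) {
    warning("empty foreground: projected area 0")
    return(0)
  }
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image((image > thr) * 1)))
  counts <- tabulate(lab[lab > 0])
  big <- which.max(counts)
  filled <- EBImage::fillHull(EBImage::Image((lab == big) * 1))
  sum(as.matrix(filled) > 0) * pixel_size_xy^2
}

#' Write per-nucleus measurements as CSV
#' @param measurements data.frame from [measure_nuclei()].
#' @param path output file.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-channel TIFF z-stack with a YAML geometry sidecar
#'
#' The sidecar carries \code{pixel_size_xy}, \code{z_step},
#' \code{channels} (names, in slice order: all z of channel 1, then
#' channel 2, ...) and optionally \code{intensity_scale}, the physical
#' intensity corresponding to the TIFF's full range.
#'
#' @param tiff_path multi-slice TIFF.
#' @param yaml_path sidecar; defaults to \code{<tiff_path>.yaml}.
#' @return zstack.
#' @export
read_zstack <- function(tiff_path, yaml_path = paste0(tiff_path, ".yaml")) {
  meta <- yaml::read_yaml(yaml_path)
  slices <- tiff::readTIFF(tiff_path, all = TRUE)   # values in [0, 1]
  nch <- length(meta$channels)
  nz <- length(slices) / nch
  if (nz != round(nz)) stop_malformed("slice count not divisible by channels")
  scale <- meta$intensity_scale %||% 1
  chans <- lapply(seq_len(nch), function(c0) {
    arr <- array(0, c(dim(slices[[1L]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- slices[[(c0 - 1L) * nz + k]] * scale
    arr
  })
  names(chans) <- meta$channels
  zstack(chans, meta$pixel_size_xy, meta$z_step)
}

#' Write a labeled volume as a 16-bit multi-slice TIFF
#' @param volume labeled_volume.
#' @param path output TIFF.
#' @export
write_labeled_volume <- function(volume, path) {
  lab <- volume$labels
  if (max(lab) > 65535L) stop_malformed("more than 65535 labels")
  slices <- lapply(seq_len(dim(lab)[3L]),
                   function(k) lab[, , k] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}
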