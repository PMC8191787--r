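## Volumes are arrays with dim (nz, ny, nx) and stacks are lists with a
## $volume of dim (nz, ny, nx, 4); voxel indices are (z, y, x), 1-based
## in R arrays, and voxel_size is (z, y, x) in nm.

#' Construct a sequencing round stack
#'
#' @param volume numeric array, dim (nz, ny, nx, n_channels).
#' @param round_index 1-based round number.
#' @param channels channel names (default the four sequencing dyes).
#' @param voxel_size numeric (z, y, x) voxel size in nm.
#' @return object of class \code{round_stack}.
#' @export
round_stack <- function(volume, round_index,
                        channels = c("FAM", "Cy3", "TexasRed", "Cy5"),
                        voxel_size = c(500, 250, 250)) {
  stopifnot(length(dim(volume)) == 4L, dim(volume)[4] == length(channels))
  structure(list(volume = volume, round_index = round_index,
                 channels = channels, voxel_size = voxel_size),
            class = "round_stack")
}

#' @export
print.round_stack <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("round %d: %d x %d x %d volume, channels %s\n",
              x$round_index, d[1], d[2], d[3],
              paste(x$channels, collapse = "/")))
  invisible(x)
}

#' @keywords internal
.channel_sum <- function(stack) {
  v <- stack$volume
  d <- dim(v)
  array(rowSums(matrix(v, ncol = d[4])), d[1:3])
}

## integer translation with zero fill; shift = (dz, dy, dx) moves content
## towards higher indices
#' @keywords internal
.translate3 <- function(vol, shift) {
  d <- dim(vol)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { src[[a]] <- 1:(d[a] - s); dst[[a]] <- (1 + s):d[a] }
    else       { src[[a]] <- (1 - s):d[a]; dst[[a]] <- 1:(d[a] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Register sequencing rounds by translational cross-correlation
#'
#' Each non-reference round's channel-summed volume is aligned to the
#' reference round by the integer 3D shift maximising their circular
#' cross-correlation (computed by FFT), restricted to \code{max_shift}
#' voxels per axis, and the whole 4-channel stack is translated back by
#' that shift. A normalised peak correlation below
#' \code{confidence_threshold} flags the round as low confidence.
#'
#' @param stacks list of \code{round_stack}s of equal shape.
#' @param reference_round index of the reference round (default 1).
#' @param max_shift maximum absolute shift per axis in voxels.
#' @param confidence_threshold normalised-correlation floor for a
#'   confident shift (default 0.2).
#' @return list with \code{stacks} (registered), \code{shifts} (rounds x
#'   3 matrix of recovered (dz, dy, dx)) and \code{low_confidence}
#'   logical vector.
#' @export
register_rounds <- function(stacks, reference_round = 1, max_shift = 10,
                            confidence_threshold = 0.2) {
  if (length(stacks) < 2L) stop("need at least 2 rounds")
  d <- dim(stacks[[1]]$volume)[1:3]
  ref <- .channel_sum(stacks[[reference_round]])
  if (all(ref == 0)) warning("reference round is all-zero")
  refc <- ref - mean(ref)          # centred, so flat offsets do not
  fref <- stats::fft(refc)         # masquerade as correlation
  n <- length(stacks)
  shifts <- matrix(0L, n, 3, dimnames = list(NULL, c("dz", "dy", "dx")))
  lowconf <- logical(n)
  out <- stacks
  for (r in seq_len(n)) {
    if (r == reference_round) next
    mov <- .channel_sum(stacks[[r]])
    if (all(mov == 0)) {
      warning("round ", r, " is all-zero; zero shift assumed")
      lowconf[r] <- TRUE
      next
    }
    movc <- mov - mean(mov)
    cc <- Re(stats::fft(fref * Conj(stats::fft(movc)), inverse = TRUE)) /
      length(ref)
    ## admissible circular lags: |lag| <= max_shift per axis
    lag_ok <- lapply(d, function(nd) {
      lag <- c(0:(nd - 1))
      lag[lag > nd / 2] <- lag[lag > nd / 2] - nd
      abs(lag) <= max_shift
    })
    mask <- array(FALSE, d)
    mask[lag_ok[[1]], lag_ok[[2]], lag_ok[[3]]] <- TRUE
    cc[!mask] <- -Inf
    peak <- which.max(cc)
    idx <- arrayInd(peak, d) - 1L
    lag <- ifelse(idx > d / 2, idx - d, idx)
    ncc <- max(cc[mask]) / sqrt(sum(refc^2) * sum(movc^2))
    lowconf[r] <- ncc < confidence_threshold
    shifts[r, ] <- as.integer(-lag)   # planted shift is the negative lag
    v <- stacks[[r]]$volume
    for (ch in seq_len(dim(v)[4]))
      v[, , , ch] <- .translate3(v[, , , ch], as.integer(lag))
    out[[r]]$volume <- v
  }
  list(stacks = out, shifts = shifts, low_confidence = lowconf)
}

#' Morphological background subtraction
#'
#' Subtracts a grey morphological opening (box structuring element of
#' the given size, applied per z-plane) from the image and clamps
#' negatives to zero. Flat backgrounds are removed entirely while
#' punctate peaks narrower than the element are preserved.
#'
#' @param volume numeric array: 2D image, 3D volume (z, y, x) or 4D
#'   stack volume (z, y, x, channel).
#' @param opening_size structuring-element size in pixels (default 5).
#' @return array of the same shape, non-negative.
#' @export
subtract_background <- function(volume, opening_size = 5) {
  kern <- EBImage::makeBrush(opening_size, shape = "box")
  open2d <- function(m) .grey_open2d(m, kern)
  d <- dim(volume)
  if (is.null(d) || length(d) == 2L) {
    res <- volume - open2d(volume)
  } else if (length(d) == 3L) {
    res <- volume
    for (z in seq_len(d[1])) res[z, , ] <- volume[z, , ] - open2d(volume[z, , ])
  } else if (length(d) == 4L) {
    res <- volume
    for (ch in seq_len(d[4]))
      for (z in seq_len(d[1]))
        res[z, , , ch] <- volume[z, , , ch] - open2d(volume[z, , , ch])
  } else stop("unsupported array rank")
  res[res < 0] <- 0
  res
}

## grey opening on an arbitrary-scale matrix (EBImage grayscale
## morphology clips to [0, 1], so rescale around it; positive scaling
## commutes with morphology)
#' @keywords internal
.grey_open2d <- function(m, kern) {
  mx <- max(m)
  if (mx <= 0) return(m * 0)
  EBImage::opening(m / mx, kern) * mx
}

#' Background-subtract every channel of every round
#'
#' @param stacks list of \code{round_stack}s.
#' @param opening_size passed to [subtract_background()].
#' @return the stacks with subtracted volumes.
#' @export
subtract_background_rounds <- function(stacks, opening_size = 5) {
  lapply(stacks, function(s) {
    s$volume <- subtract_background(s$volume, opening_size)
    s
  })
}

#' Composite volume over rounds and channels
#'
#' Voxelwise sum of all channels of all (registered,
#' background-subtracted) rounds; the input to amplicon segmentation.
#'
#' @param stacks list of \code{round_stack}s of equal shape.
#' @return 3D numeric array (z, y, x).
#' @export
make_composite <- function(stacks) {
  d <- dim(stacks[[1]]$volume)
  for (s in stacks)
    if (!identical(dim(s$volume), d)) stop("round shapes differ")
  Reduce(`+`, lapply(stacks, .channel_sum))
}

## Vectorised shape-preserving (Fritsch-Carlson monotone) piecewise cubic
## interpolation of every column of a matrix from grid 1..n to `xi`.
#' @keywords internal
.pchip_columns <- function(y, xi) {
  n <- nrow(y)
  if (n < 2L) stop("need >= 2 z planes")
  h <- 1
  del <- diff(y)                           # (n-1) x m secant slopes
  m <- ncol(y)
  slopes <- matrix(0, n, m)
  if (n == 2L) {
    slopes[1, ] <- del[1, ]; slopes[2, ] <- del[1, ]
  } else {
    ## interior: weighted harmonic mean where secants share sign
    d1 <- del[-(n - 1L), , drop = FALSE]
    d2 <- del[-1L, , drop = FALSE]
    same <- d1 * d2 > 0
    hm <- matrix(0, n - 2L, m)
    hm[same] <- 2 * d1[same] * d2[same] / (d1[same] + d2[same])
    slopes[2:(n - 1L), ] <- hm
    ## one-sided ends (shape-preserving three-point formula)
    e1 <- (3 * del[1, ] - del[2, ]) / 2
    bad <- e1 * del[1, ] <= 0
    e1[bad] <- 0
    big <- !bad & abs(e1) > 3 * abs(del[1, ])
    e1[big] <- 3 * del[1, big]
    slopes[1, ] <- e1
    en <- (3 * del[n - 1L, ] - del[n - 2L, ]) / 2
    bad <- en * del[n - 1L, ] <= 0
    en[bad] <- 0
    big <- !bad & abs(en) > 3 * abs(del[n - 1L, ])
    en[big] <- 3 * del[n - 1L, big]
    slopes[n, ] <- en
  }
  k <- pmin(pmax(floor(xi), 1L), n - 1L)   # left knot per xi
  t <- xi - k
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  y[k, , drop = FALSE] * h00 + slopes[k, , drop = FALSE] * h10 +
    y[k + 1L, , drop = FALSE] * h01 + slopes[k + 1L, , drop = FALSE] * h11
}

#' @keywords internal
.interp_z <- function(vol, factor) {
  d <- dim(vol)
  nz2 <- (d[1] - 1L) * factor + 1L
  xi <- seq(1, d[1], length.out = nz2)
  m <- matrix(vol, nrow = d[1])
  array(.pchip_columns(m, xi), c(nz2, d[2], d[3]))
}

#' @keywords internal
.gauss_smooth3 <- function(vol, sigma) {
  d <- dim(vol)
  kern1 <- function(n, s) {
    x <- c(0:(n - 1))
    x[x > n / 2] <- x[x > n / 2] - n
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  }
  kz <- kern1(d[1], sigma[1]); ky <- kern1(d[2], sigma[2])
  kx <- kern1(d[3], sigma[3])
  K <- outer(outer(kz, ky), kx)
  Re(stats::fft(stats::fft(vol) * stats::fft(K), inverse = TRUE)) /
    length(vol)
}

#' Global Otsu threshold of a numeric array
#'
#' @param x numeric array or vector (non-negative).
#' @param levels histogram levels (default 256).
#' @return threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- as.numeric(x)
  mx <- max(v)
  if (mx <= 0) return(0)
  img <- EBImage::Image(v / mx, dim = c(length(v), 1))
  EBImage::otsu(img, range = c(0, 1), levels = levels) * mx
}

#' Segment amplicons in a composite volume
#'
#' The composite is upsampled in Z by shape-preserving piecewise cubic
#' interpolation (factor defaulting to the voxel anisotropy), punctate
#' signal amplified with a difference of Gaussians, binarised by the
#' Otsu method, and split by a seeded watershed: local maxima of the
#' filtered volume (minimum separation \code{sigma_small}) seed the
#' labels and every foreground voxel joins its nearest seed. Labels are
#' then downsampled back to the original Z grid and relabelled 1..N.
#'
#' @param composite 3D array (z, y, x) from [make_composite()].
#' @param z_interp_factor integer upsampling factor in Z; NULL derives
#'   it from \code{voxel_size} (z spacing / xy spacing, rounded).
#' @param dog_sigmas (small, large) Gaussian sigmas in interpolated
#'   voxels (default c(1, 3)).
#' @param voxel_size (z, y, x) nm, used only for the default factor.
#' @param min_voxels drop amplicons smaller than this (default 3).
#' @return list with \code{labels} (integer array, original shape) and
#'   \code{amplicons} (data.frame label, z, y, x centroid, n_voxels).
#' @export
segment_amplicons <- function(composite, z_interp_factor = NULL,
                              dog_sigmas = c(1, 3),
                              voxel_size = c(500, 250, 250),
                              min_voxels = 3) {
  d <- dim(composite)
  if (is.null(z_interp_factor))
    z_interp_factor <- max(1L, as.integer(round(voxel_size[1] /
                                                  voxel_size[2])))
  vol <- if (z_interp_factor > 1L) .interp_z(composite, z_interp_factor)
         else composite
  di <- dim(vol)
  s1 <- rep(dog_sigmas[1], 3); s2 <- rep(dog_sigmas[2], 3)
  dog <- .gauss_smooth3(vol, s1) - .gauss_smooth3(vol, s2)
  dog[dog < 0] <- 0
  thr <- otsu_threshold(dog)
  fg <- dog > thr
  if (!any(fg)) {
    warning("empty foreground; no amplicons")
    return(list(labels = array(0L, d),
                amplicons = data.frame(label = integer(0), z = numeric(0),
                                       y = numeric(0), x = numeric(0),
                                       n_voxels = integer(0))))
  }
  seeds <- .local_maxima3(dog, fg, min_sep = max(1, dog_sigmas[1]))
  labels_i <- array(0L, di)
  fg_idx <- which(fg)
  fg_pos <- arrayInd(fg_idx, di)
  ## nearest-seed assignment (seeded watershed on the DoG peaks)
  nseed <- nrow(seeds)
  assign <- integer(length(fg_idx))
  chunk <- 20000L
  for (start in seq(1L, length(fg_idx), by = chunk)) {
    rows <- start:min(start + chunk - 1L, length(fg_idx))
    dz <- outer(fg_pos[rows, 1], seeds[, 1], `-`)
    dy <- outer(fg_pos[rows, 2], seeds[, 2], `-`)
    dx <- outer(fg_pos[rows, 3], seeds[, 3], `-`)
    assign[rows] <- max.col(-(dz^2 + dy^2 + dx^2), ties.method = "first")
  }
  labels_i[fg_idx] <- assign
  ## uninterpolate: sample original z planes
  zsel <- if (z_interp_factor > 1L)
    seq(1L, di[1], by = z_interp_factor) else seq_len(di[1])
  labels <- labels_i[zsel, , , drop = FALSE]
  ## contiguous relabel, dropping tiny fragments
  tab <- tabulate(labels, nbins = nseed)
  keep <- which(tab >= min_voxels)
  remap <- integer(nseed)
  remap[keep] <- seq_along(keep)
  nz <- labels > 0L
  labels[nz] <- remap[labels[nz]]
  amp <- .amplicon_table(labels)
  list(labels = labels, amplicons = amp)
}

#' @keywords internal
.local_maxima3 <- function(vol, mask, min_sep = 1) {
  d <- dim(vol)
  ge_shift <- function(ax, s) {
    shifted <- array(-Inf, d)
    idx_src <- idx_dst <- lapply(d, seq_len)
    if (s > 0) { idx_src[[ax]] <- 1:(d[ax] - s); idx_dst[[ax]] <- (1 + s):d[ax] }
    else       { idx_src[[ax]] <- (1 - s):d[ax]; idx_dst[[ax]] <- 1:(d[ax] + s) }
    shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    shifted
  }
  is_max <- mask
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    if (d[ax] == 1L) next
    is_max <- is_max & (vol >= ge_shift(ax, s))
  }
  cand <- which(is_max)
  if (length(cand) == 0L) cand <- which.max(vol)
  ord <- cand[order(vol[cand], decreasing = TRUE)]
  pos <- arrayInd(ord, d)
  sep2 <- max(1, min_sep)^2
  acc <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    if (nrow(acc) == 0L ||
        min(rowSums((acc - matrix(p, nrow(acc), 3, byrow = TRUE))^2)) > sep2)
      acc <- rbind(acc, p)
  }
  acc
}

#' @keywords internal
.amplicon_table <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), n_voxels = integer(0)))
  pos <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  data.frame(label = sort(unique(lab)),
             z = tapply(pos[, 1], lab, mean),
             y = tapply(pos[, 2], lab, mean),
             x = tapply(pos[, 3], lab, mean),
             n_voxels = as.integer(table(lab)),
             row.names = NULL)
}

#' Quantile-normalise the four channels of a round
#'
#' Maps every channel's voxel intensity distribution onto the mean of
#' the four channels' order statistics, so that an argmax comparison
#' across channels is insensitive to per-fluorophore brightness. The
#' normalisation pools all voxels of the volume.
#'
#' @param stack \code{round_stack}.
#' @return the stack with normalised volume.
#' @export
quantile_normalize_round <- function(stack) {
  d <- dim(stack$volume)
  m <- matrix(stack$volume, ncol = d[4])
  mn <- limma::normalizeQuantiles(m, ties = TRUE)
  stack$volume <- array(mn, d)
  stack
}

#' Basecall one amplicon in one round
#'
#' Within the amplicon's voxels, each channel's normalised intensities
#' are sorted and the mean of the top \code{min(top_k, n_voxels)} values
#' computed; the called base is the channel map of the winning channel.
#' Ties keep the first channel in configured order and are flagged.
#'
#' @param voxel_idx integer linear indices of the amplicon's voxels in
#'   a (z, y, x) volume.
#' @param stack quantile-normalised \code{round_stack}.
#' @param channel_map bases in channel order (default c("A","C","G","T")).
#' @param top_k voxels averaged per channel (default 30).
#' @return list with \code{base}, \code{intensities} (per channel),
#'   \code{tie}.
#' @export
basecall_round <- function(voxel_idx, stack, channel_map = c("A", "C", "G", "T"),
                           top_k = 30) {
  if (length(voxel_idx) == 0L) stop("amplicon with 0 voxels")
  d <- dim(stack$volume)
  nvox <- prod(d[1:3])
  k <- min(top_k, length(voxel_idx))
  means <- vapply(seq_len(d[4]), function(ch) {
    v <- stack$volume[voxel_idx + (ch - 1L) * nvox]
    mean(sort(v, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
  best <- which.max(means)
  tie <- sum(means == means[best]) > 1L
  list(base = channel_map[best], intensities = means, tie = tie)
}

#' Basecall and decode all amplicons across rounds
#'
#' Quantile-normalises each round, basecalls every amplicon in every
#' round, concatenates the calls in round order into a barcode and
#' decodes it against the reference code.
#'
#' @param labels integer label array from [segment_amplicons()].
#' @param stacks list of registered, background-subtracted
#'   \code{round_stack}s; their number must equal the barcode length.
#' @param code \code{barcode_code} with gene assignment.
#' @param channel_map bases in channel order.
#' @param top_k voxels averaged per channel.
#' @return data.frame: label, centroid z/y/x, n_voxels, barcode,
#'   status, gene, distance, n_tied_rounds.
#' @export
basecall_all <- function(labels, stacks, code,
                         channel_map = c("A", "C", "G", "T"), top_k = 30) {
  if (length(stacks) != code$length)
    stop("round count (", length(stacks), ") != barcode length (",
         code$length, ")")
  amp <- .amplicon_table(labels)
  if (nrow(amp) == 0L)
    return(cbind(amp, barcode = character(0), status = character(0),
                 gene = character(0), distance = integer(0),
                 n_tied_rounds = integer(0)))
  vox <- split(which(labels > 0L), labels[labels > 0L])
  calls <- matrix("", nrow(amp), length(stacks))
  ties <- matrix(FALSE, nrow(amp), length(stacks))
  for (r in seq_along(stacks)) {
    ns <- quantile_normalize_round(stacks[[r]])
    for (i in seq_len(nrow(amp))) {
      bc <- basecall_round(vox[[as.character(amp$label[i])]], ns,
                           channel_map, top_k)
      calls[i, r] <- bc$base
      ties[i, r] <- bc$tie
    }
  }
  barcode <- apply(calls, 1, paste, collapse = "")
  dec <- decode_barcodes(barcode, code)
  data.frame(amp, barcode = barcode, status = dec$status,
             gene = dec$assigned_gene, distance = dec$distance,
             n_tied_rounds = rowSums(ties), stringsAsFactors = FALSE)
}

#' Full image-decoding pipeline
#'
#' Registration, background subtraction, composite segmentation and
#' per-round basecalling in one call.
#'
#' @param stacks list of raw \code{round_stack}s.
#' @param code \code{barcode_code} with gene assignment.
#' @param reference_round registration reference (default 1).
#' @param opening_size background opening size (default 5).
#' @param z_interp_factor,dog_sigmas passed to [segment_amplicons()].
#' @param channel_map,top_k passed to [basecall_all()].
#' @return list with \code{amplicons} (decoded table), \code{labels},
#'   \code{shifts}.
#' @export
decode_stacks <- function(stacks, code, reference_round = 1,
                          opening_size = 5, z_interp_factor = NULL,
                          dog_sigmas = c(1, 3),
                          channel_map = c("A", "C", "G", "T"), top_k = 30) {
  reg <- register_rounds(stacks, reference_round)
  st <- subtract_background_rounds(reg$stacks, opening_size)
  comp <- make_composite(st)
  seg <- segment_amplicons(comp, z_interp_factor = z_interp_factor,
                           dog_sigmas = dog_sigmas,
                           voxel_size = st[[1]]$voxel_size)
  amp <- basecall_all(seg$labels, st, code, channel_map, top_k)
  list(amplicons = amp, labels = seg$labels, shifts = reg$shifts)
}
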