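## Seeded synthetic data: transcriptomes with planted near-homologs,
## ground-truth amplicon fields, rendered multi-round 4-channel stacks
## and nucleus images. Everything the pipeline consumes can be produced
## here, so tests run end to end without external data.

#' Simulate a transcriptome with planted near-homologs
#'
#' Random ACGT transcripts; for each homolog pair a 25-nt window of the
#' source transcript is copied into the partner with exactly
#' \code{homolog_mismatches} substitutions, which exercises the
#' off-target screen at a known Hamming distance.
#'
#' @param n_genes number of genes (one transcript each).
#' @param length_range integer range of transcript lengths.
#' @param n_homolog_pairs planted homolog pairs (default 0).
#' @param homolog_mismatches substitutions in each planted copy.
#' @param seed RNG seed.
#' @return list with \code{transcripts} (data.frame transcript_id,
#'   gene_id, sequence) and \code{truth} (planted-window table:
#'   source/dest gene, 0-based starts, mismatches).
#' @export
make_transcriptome <- function(n_genes = 60, length_range = c(500, 2000),
                               n_homolog_pairs = 0, homolog_mismatches = 6,
                               seed = 1) {
  if (homolog_mismatches < 0 || homolog_mismatches > 25)
    stop("homolog_mismatches must be in 0..25")
  if (2 * n_homolog_pairs > n_genes)
    stop("not enough genes for ", n_homolog_pairs, " homolog pairs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  lens <- sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  gene_id <- sprintf("G%03d", seq_len(n_genes))
  truth <- NULL
  if (n_homolog_pairs > 0) {
    rows <- vector("list", n_homolog_pairs)
    for (p in seq_len(n_homolog_pairs)) {
      src <- 2L * p - 1L; dst <- 2L * p
      s_start <- sample(nchar(seqs[src]) - 24L, 1L)
      win <- substr(seqs[src], s_start, s_start + 24L)
      wv <- strsplit(win, "")[[1]]
      if (homolog_mismatches > 0) {
        posns <- sample(25L, homolog_mismatches)
        for (q in posns) wv[q] <- sample(setdiff(bases, wv[q]), 1L)
      }
      d_start <- sample(nchar(seqs[dst]) - 24L, 1L)
      substr(seqs[dst], d_start, d_start + 24L) <- paste(wv, collapse = "")
      rows[[p]] <- data.frame(source_gene = gene_id[src],
                              source_start = s_start - 1L,
                              dest_gene = gene_id[dst],
                              dest_start = d_start - 1L,
                              mismatches = homolog_mismatches)
    }
    truth <- do.call(rbind, rows)
  }
  list(transcripts = data.frame(transcript_id = paste0(gene_id, ".1"),
                                gene_id = gene_id, sequence = seqs,
                                stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate a ground-truth amplicon field
#'
#' Places nuclei with minimum separation in the XY plane, draws
#' amplicon positions around them (Gaussian scatter, minimum mutual
#' separation so rolling-circle amplicons stay resolvable), samples
#' each amplicon's gene from planted abundances, and plants per-round
#' base errors either at a per-base rate or as an exact number per
#' amplicon.
#'
#' @param n_cells number of cells (default 4).
#' @param amplicons_per_cell mean amplicons per cell (default 60).
#' @param field_shape volume shape (nz, ny, nx), default c(32, 256, 256).
#' @param code \code{barcode_code} with a gene assignment covering all
#'   simulated genes.
#' @param error_rate per-round, per-amplicon probability of a wrong
#'   base (default 0).
#' @param errors_per_amplicon exact planted errors per amplicon
#'   (overrides \code{error_rate} when not NULL).
#' @param nucleus_radius nucleus radius in pixels (default 18).
#' @param scatter_sd amplicon scatter around the nucleus centre
#'   (default 28 px).
#' @param min_amp_sep minimum XY separation between amplicons
#'   (default 6 px).
#' @param seed RNG seed.
#' @return object of class \code{ground_truth}: list with
#'   \code{amplicons} (id, gene, barcode, obs_barcode, z, y, x,
#'   intensity, cell), \code{nuclei} (cell, x, y, radius),
#'   \code{abundances}, \code{field_shape}, \code{code}.
#' @export
make_field <- function(n_cells = 4, amplicons_per_cell = 60,
                       field_shape = c(32, 256, 256), code,
                       error_rate = 0, errors_per_amplicon = NULL,
                       nucleus_radius = 18, scatter_sd = 28,
                       min_amp_sep = 6, seed = 1) {
  if (is.null(code$assignment)) stop("code needs a gene assignment")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nz <- field_shape[1]; ny <- field_shape[2]; nx <- field_shape[3]
  margin <- nucleus_radius + 3 * 4
  if (2 * margin >= min(ny, nx)) stop("field too small for the nuclei")
  ## nucleus centres: rejection sampling with minimum separation
  min_nuc_sep <- 2 * nucleus_radius + 2 * scatter_sd * 0.8
  cx <- cy <- numeric(0)
  tries <- 0L
  while (length(cx) < n_cells) {
    xx <- stats::runif(1, margin, nx - margin)
    yy <- stats::runif(1, margin, ny - margin)
    if (length(cx) == 0L ||
        min((cx - xx)^2 + (cy - yy)^2) > min_nuc_sep^2) {
      cx <- c(cx, xx); cy <- c(cy, yy)
    }
    tries <- tries + 1L
    if (tries > 5000L) stop("field too small for ", n_cells, " cells")
  }
  nuclei <- data.frame(cell = seq_len(n_cells), x = cx, y = cy,
                       radius = nucleus_radius)
  genes <- names(code$assignment)
  ab <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
  ab <- ab / sum(ab)
  names(ab) <- genes
  n_amp <- n_cells * amplicons_per_cell
  ax <- ay <- az <- numeric(0); acell <- integer(0)
  tries <- 0L
  while (length(ax) < n_amp) {
    cell <- sample.int(n_cells, 1L)
    xx <- stats::rnorm(1, cx[cell], scatter_sd)
    yy <- stats::rnorm(1, cy[cell], scatter_sd)
    if (xx < 6 || xx > nx - 5 || yy < 6 || yy > ny - 5) next
    if (length(ax) > 0L && min((ax - xx)^2 + (ay - yy)^2) < min_amp_sep^2) {
      tries <- tries + 1L
      if (tries > 50000L) stop("cannot place amplicons at this density")
      next
    }
    ax <- c(ax, xx); ay <- c(ay, yy)
    zlo <- min(6, max(1, floor(nz / 2)))
    zhi <- max(zlo, nz - 5)
    az <- c(az, stats::runif(1, zlo, zhi))
    acell <- c(acell, cell)
  }
  gene_of <- sample(genes, n_amp, replace = TRUE, prob = ab)
  barcode <- unname(code$assignment[gene_of])
  obs <- barcode
  n_rounds <- code$length
  bases <- c("A", "C", "G", "T")
  n_err <- if (!is.null(errors_per_amplicon))
    rep(as.integer(errors_per_amplicon), n_amp)
  else stats::rbinom(n_amp, n_rounds, error_rate)
  for (i in which(n_err > 0L)) {
    posns <- sample.int(n_rounds, min(n_err[i], n_rounds))
    v <- strsplit(obs[i], "")[[1]]
    for (q in posns) v[q] <- sample(setdiff(bases, v[q]), 1L)
    obs[i] <- paste(v, collapse = "")
  }
  amp <- data.frame(id = seq_len(n_amp), gene = gene_of,
                    barcode = barcode, obs_barcode = obs,
                    z = az, y = ay, x = ax,
                    intensity = stats::runif(n_amp, 150, 250),
                    cell = acell, stringsAsFactors = FALSE)
  structure(list(amplicons = amp, nuclei = nuclei, abundances = ab,
                 field_shape = field_shape, code = code),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d amplicons, %d cells, %d genes, field %s\n",
              nrow(x$amplicons), nrow(x$nuclei),
              length(unique(x$amplicons$gene)),
              paste(x$field_shape, collapse = "x")))
  invisible(x)
}

#' Render sequencing rounds and a nucleus image from ground truth
#'
#' Every amplicon contributes a 3D Gaussian of its intensity to the
#' channel encoding its (possibly error-planted) base in each round;
#' per-round global integer translations are applied, Gaussian noise
#' added and negatives clamped. Nuclei are rendered as smooth-edged
#' disks in a 2D DAPI image.
#'
#' @param truth \code{ground_truth} from [make_field()].
#' @param psf_sigma Gaussian point-spread sigma (z, y, x) in voxels
#'   (default c(1.2, 1.5, 1.5)).
#' @param noise_sd additive Gaussian noise sd (default 0).
#' @param shifts integer rounds x 3 matrix of per-round (dz, dy, dx)
#'   translations; NULL for none.
#' @param channel_map bases in channel order (default c("A","C","G","T")).
#' @param voxel_size voxel size (z, y, x) in nm.
#' @param seed RNG seed for the noise.
#' @return list with \code{stacks} (list of \code{round_stack}),
#'   \code{dapi} (2D matrix) and \code{shifts}.
#' @export
render_rounds <- function(truth, psf_sigma = c(1.2, 1.5, 1.5),
                          noise_sd = 0, shifts = NULL,
                          channel_map = c("A", "C", "G", "T"),
                          voxel_size = c(500, 250, 250), seed = 1) {
  if (any(psf_sigma <= 0)) stop("psf_sigma must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- truth$field_shape
  n_rounds <- truth$code$length
  if (is.null(shifts)) shifts <- matrix(0L, n_rounds, 3)
  amp <- truth$amplicons
  base_mat <- do.call(rbind, strsplit(amp$obs_barcode, ""))
  ext <- ceiling(3 * psf_sigma)
  stacks <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    vol <- array(0, c(d, 4))
    ch_of <- match(base_mat[, r], channel_map)
    for (i in seq_len(nrow(amp))) {
      z0 <- amp$z[i] + shifts[r, 1]
      y0 <- amp$y[i] + shifts[r, 2]
      x0 <- amp$x[i] + shifts[r, 3]
      zz <- max(1, floor(z0 - ext[1])):min(d[1], ceiling(z0 + ext[1]))
      yy <- max(1, floor(y0 - ext[2])):min(d[2], ceiling(y0 + ext[2]))
      xx <- max(1, floor(x0 - ext[3])):min(d[3], ceiling(x0 + ext[3]))
      if (length(zz) == 0L || length(yy) == 0L || length(xx) == 0L) next
      gz <- exp(-(zz - z0)^2 / (2 * psf_sigma[1]^2))
      gy <- exp(-(yy - y0)^2 / (2 * psf_sigma[2]^2))
      gx <- exp(-(xx - x0)^2 / (2 * psf_sigma[3]^2))
      spot <- amp$intensity[i] * outer(outer(gz, gy), gx)
      vol[zz, yy, xx, ch_of[i]] <- vol[zz, yy, xx, ch_of[i]] + spot
    }
    if (noise_sd > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, noise_sd)
      vol[vol < 0] <- 0
    }
    stacks[[r]] <- round_stack(vol, r, voxel_size = voxel_size)
  }
  dapi <- matrix(0, d[2], d[3])
  yg <- seq_len(d[2]); xg <- seq_len(d[3])
  for (k in seq_len(nrow(truth$nuclei))) {
    nc <- truth$nuclei[k, ]
    rr <- outer((yg - nc$y)^2, rep(1, d[3])) +
      outer(rep(1, d[2]), (xg - nc$x)^2)
    dapi <- dapi + 200 / (1 + exp((sqrt(rr) - nc$radius) / 1.5))
  }
  if (noise_sd > 0) {
    dapi <- dapi + stats::rnorm(length(dapi), 0, noise_sd)
    dapi[dapi < 0] <- 0
  }
  list(stacks = stacks, dapi = dapi, shifts = shifts)
}

#' Ready-made simulation presets
#'
#' \code{"96plex-mini"} is a desk-scale version of a 96-gene multiplexed
#' experiment: an 8-base distance-3 barcode code with 173 gene
#' assignments (96 mRNA + 77 miRNA names), of which the 96 mRNA genes
#' populate a 4-cell field of about 60 amplicons per cell in a
#' 32 x 256 x 256 volume, read out over 8 rounds.
#'
#' @param preset preset name (currently \code{"96plex-mini"}).
#' @param seed RNG seed propagated to all stages.
#' @param error_rate,errors_per_amplicon,noise_sd,shifts overrides
#'   passed to [make_field()] / [render_rounds()].
#' @return list with \code{truth}, \code{stacks}, \code{dapi},
#'   \code{code}, \code{shifts}.
#' @export
sim_preset <- function(preset = "96plex-mini", seed = 1, error_rate = 0,
                       errors_per_amplicon = NULL, noise_sd = 0,
                       shifts = NULL) {
  if (preset != "96plex-mini") stop("unknown preset: ", preset)
  code <- generate_code(8, 3, n_needed = 173)
  gene_ids <- c(sprintf("MR%02d", 1:96), sprintf("MIR%02d", 1:77))
  code <- assign_barcodes(code, gene_ids, seed = seed)
  mcode <- code
  mcode$assignment <- code$assignment[1:96]   # field uses the mRNA panel
  truth <- make_field(n_cells = 4, amplicons_per_cell = 60,
                      field_shape = c(32, 256, 256), code = mcode,
                      error_rate = error_rate,
                      errors_per_amplicon = errors_per_amplicon,
                      seed = seed)
  rend <- render_rounds(truth, noise_sd = noise_sd, shifts = shifts,
                        seed = seed)
  list(truth = truth, stacks = rend$stacks, dapi = rend$dapi,
       code = code, shifts = rend$shifts)
}
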