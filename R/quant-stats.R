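#' Count fluorescent spots in an image or stack
#'
#' A 3D stack is first combined by maximum intensity projection in Z.
#' Background is removed by rolling-ball subtraction (grey morphological
#' opening with a disc of the given radius), optionally followed by a
#' 3x3 box smooth. Spots are local maxima above an adaptive threshold
#' (image mean + \code{k_sd} standard deviations after background
#' subtraction) with a minimum mutual separation.
#'
#' @param image 2D matrix (y, x) or 3D array (z, y, x).
#' @param rolling_ball_radius background radius in pixels (10 is
#'   typical for rolling-circle amplicons, 2 for single-molecule FISH
#'   puncta).
#' @param smooth apply the 3x3 box smooth (default TRUE).
#' @param k_sd threshold stringency (default 3).
#' @param min_sep minimum spot separation in pixels (default 3).
#' @return integer spot count.
#' @export
count_spots <- function(image, rolling_ball_radius = 10, smooth = TRUE,
                        k_sd = 3, min_sep = 3) {
  d <- dim(image)
  img <- if (length(d) == 3L) apply(image, c(2, 3), max) else image
  if (max(img) == 0) return(0L)
  kern <- EBImage::makeBrush(.odd(2 * rolling_ball_radius + 1), "disc")
  bg <- .grey_open2d(img, kern)
  sub <- img - bg
  sub[sub < 0] <- 0
  if (smooth) {
    box <- matrix(1 / 9, 3, 3)
    sub <- t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(sub)),
                                                 box)))
  }
  thr <- mean(sub) + k_sd * stats::sd(sub)
  if (!any(sub > thr)) return(0L)
  m3 <- array(sub, c(1, dim(sub)))       # reuse the 3D maxima finder
  seeds <- .local_maxima3(m3, m3 > thr, min_sep = min_sep)
  nrow(seeds)
}

#' True discovery rate of a matched/mismatched probe pair
#'
#' TDR = M / (M + MM) x 100, where M and MM are the mean spot counts
#' per cell of the matched probe and of its single-mismatch
#' ligation-junction control.
#'
#' @param matched_mean mean matched-probe count per cell.
#' @param mismatched_mean mean mismatch-control count per cell.
#' @return percentage in \[0, 100\].
#' @examples
#' tdr(99, 1)  # 99
#' @export
tdr <- function(matched_mean, mismatched_mean) {
  if (matched_mean < 0 || mismatched_mean < 0)
    stop("counts must be non-negative")
  tot <- matched_mean + mismatched_mean
  if (tot == 0) stop("TDR undefined when both means are zero")
  matched_mean / tot * 100
}

#' Detection sensitivity relative to smFISH
#'
#' Mean spots per cell of the amplification-based assay divided by the
#' mean of single-molecule FISH for the same gene, as a percentage.
#'
#' @param assay_counts per-cell spot counts from the ligation assay.
#' @param smfish_counts per-cell smFISH spot counts.
#' @return percentage.
#' @export
sensitivity <- function(assay_counts, smfish_counts) {
  ms <- mean(smfish_counts)
  if (ms <= 0) stop("smFISH mean must be positive")
  mean(assay_counts) / ms * 100
}

#' Coefficient of variation between probes
#'
#' Sample (n-1) standard deviation over mean, in percent, across the
#' mean amplicon counts of probes targeting different regions of the
#' same transcript.
#'
#' @param per_probe_means numeric vector of per-probe mean counts.
#' @return percent COV.
#' @export
probe_cov <- function(per_probe_means) {
  if (length(per_probe_means) < 2L) stop("need at least 2 probes")
  m <- mean(per_probe_means)
  if (m == 0) stop("mean of zero; COV undefined")
  stats::sd(per_probe_means) / m * 100
}

#' Correlation of in situ counts with reference expression
#'
#' Pearson correlation between per-gene mean spot counts and reference
#' expression values (e.g. bulk RNA-seq), optionally on log1p scale.
#'
#' @param spot_means per-gene mean counts.
#' @param reference_values paired reference expression values.
#' @param log transform both vectors by log1p first (default FALSE).
#' @return Pearson r.
#' @export
expression_correlation <- function(spot_means, reference_values,
                                   log = FALSE) {
  if (length(spot_means) != length(reference_values) ||
      length(spot_means) < 3L)
    stop("need paired vectors of length >= 3")
  if (stats::sd(spot_means) == 0 || stats::sd(reference_values) == 0)
    stop("zero variance")
  if (log) {
    spot_means <- log1p(spot_means)
    reference_values <- log1p(reference_values)
  }
  stats::cor(spot_means, reference_values)
}
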