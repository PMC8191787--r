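## 2D images are matrices indexed (y, x); centroids are reported in
## (x, y) pixel coordinates.

#' Segment nuclei in a z-projected DAPI image
#'
#' Background is reduced with a grey top-hat filter (image minus its
#' opening), the result binarised with a global Otsu threshold, and
#' touching nuclei split by a watershed on the distance map. An optional
#' structure-tensor energy pre-filter (trace of the smoothed gradient
#' outer product) can be enabled for noisy images.
#'
#' @param dapi 2D numeric matrix (y, x).
#' @param tophat_size structuring-element size for the top-hat
#'   (default 31; should exceed the nucleus diameter).
#' @param min_area drop objects smaller than this many pixels.
#' @param structure_tensor apply the structure-tensor energy pre-filter.
#' @return list with \code{labels} (integer matrix) and \code{cells}
#'   (data.frame cell_id, x, y centroid, area).
#' @export
segment_nuclei <- function(dapi, tophat_size = 31, min_area = 20,
                           structure_tensor = FALSE) {
  img <- dapi
  if (structure_tensor) img <- .structure_tensor_energy(img)
  kern <- EBImage::makeBrush(.odd(tophat_size), shape = "disc")
  th <- img - .grey_open2d(img, kern)
  th[th < 0] <- 0
  if (max(th) == 0) {
    warning("no foreground in nucleus image")
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                cells = data.frame(cell_id = integer(0), x = numeric(0),
                                   y = numeric(0), area = integer(0))))
  }
  thr <- otsu_threshold(th)
  ## EBImage works in (x, y); transpose in and out
  bin <- EBImage::Image(t(th > thr) * 1)
  dm <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dm)
  labels <- t(EBImage::imageData(ws))
  tab <- tabulate(labels)
  small <- which(tab < min_area)
  labels[labels %in% small] <- 0L
  labels <- .relabel(labels)
  cells <- .label_centroids(labels)
  list(labels = labels, cells = cells)
}

#' @keywords internal
.odd <- function(n) { n <- as.integer(n); if (n %% 2L == 0L) n + 1L else n }

#' @keywords internal
.structure_tensor_energy <- function(img, sigma = 2) {
  gy <- img - rbind(img[1, , drop = FALSE], img[-nrow(img), , drop = FALSE])
  gx <- img - cbind(img[, 1, drop = FALSE], img[, -ncol(img), drop = FALSE])
  sm <- function(m) {
    k <- EBImage::makeBrush(.odd(ceiling(4 * sigma)), "gaussian",
                            sigma = sigma)
    t(EBImage::imageData(EBImage::filter2(EBImage::Image(t(m)), k)))
  }
  sm(gx^2) + sm(gy^2)
}

#' @keywords internal
.relabel <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  remap <- integer(max(c(0L, u)))
  remap[u] <- seq_along(u)
  nz <- labels > 0L
  labels[nz] <- remap[labels[nz]]
  labels
}

#' @keywords internal
.label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  pos <- arrayInd(idx, dim(labels))
  lab <- labels[idx]
  data.frame(cell_id = sort(unique(lab)),
             x = as.numeric(tapply(pos[, 2], lab, mean)),
             y = as.numeric(tapply(pos[, 1], lab, mean)),
             area = as.integer(table(lab)), row.names = NULL)
}

#' Perinuclear zones by sequential dilation
#'
#' Each nucleus is dilated \code{n_dilations} steps (3x3 neighbourhood);
#' pixels reached by several nuclei in the same step go to the nucleus
#' with the nearest centroid (ties to the lowest label), so zones are
#' disjoint and each zone contains its nucleus by construction.
#'
#' @param labels integer nucleus label matrix from [segment_nuclei()].
#' @param n_dilations dilation steps (default 8); 0 returns the nuclei.
#' @return integer matrix of zone labels.
#' @export
perinuclear_zones <- function(labels, n_dilations = 8) {
  zones <- labels
  if (n_dilations == 0L) return(zones)
  cents <- .label_centroids(labels)
  kern <- EBImage::makeBrush(3, "box")
  ids <- cents$cell_id
  for (step in seq_len(n_dilations)) {
    claims <- vector("list", length(ids))
    for (k in seq_along(ids)) {
      m <- t(EBImage::imageData(EBImage::dilate(
        EBImage::Image(t(zones == ids[k]) * 1), kern))) > 0
      claims[[k]] <- which(m & zones == 0L)
    }
    all_new <- unlist(claims)
    if (length(all_new) == 0L) break
    counts <- table(all_new)
    pos <- arrayInd(as.integer(names(counts)), dim(zones))
    owner <- integer(length(counts))
    contested <- as.integer(names(counts)[counts > 1L])
    single <- as.integer(names(counts)[counts == 1L])
    for (k in seq_along(ids))
      zones[intersect(claims[[k]], single)] <- ids[k]
    if (length(contested) > 0L) {
      cpos <- arrayInd(contested, dim(zones))
      d2 <- outer(cpos[, 2], cents$x, `-`)^2 + outer(cpos[, 1], cents$y, `-`)^2
      ## only claiming nuclei are eligible
      elig <- matrix(FALSE, length(contested), length(ids))
      for (k in seq_along(ids))
        elig[contested %in% claims[[k]], k] <- TRUE
      d2[!elig] <- Inf
      zones[contested] <- ids[max.col(-d2, ties.method = "first")]
    }
  }
  zones
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing on a similarity
#' matrix with damping, run to convergence or \code{maxit} iterations.
#'
#' @param S similarity matrix (larger = more similar); the diagonal is
#'   overwritten with \code{preference}.
#' @param preference shared preference (exemplar prior); the median
#'   off-diagonal similarity by default.
#' @param damping message damping in (0.5, 1) (default 0.9).
#' @param maxit maximum iterations (default 1000).
#' @param conv_its stop after this many iterations without exemplar
#'   changes (default 50).
#' @return list with \code{exemplars} (indices), \code{clusters}
#'   (assignment vector), \code{converged}.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 maxit = 1000, conv_its = 50) {
  n <- nrow(S)
  if (is.null(preference)) preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  ## tiny deterministic jitter to break symmetric ties
  set <- seq_len(n)
  S <- S + outer(set, set, function(i, j) (i * n + j) %% 7) * 1e-9
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; old_ex <- integer(0); converged <- FALSE
  for (it in seq_len(maxit)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(set, which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(set, which1)] <- S[cbind(set, which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, old_ex)) stable <- stable + 1L else stable <- 0L
    old_ex <- ex
    if (stable >= conv_its && length(ex) > 0L) { converged <- TRUE; break }
  }
  ex <- old_ex
  if (length(ex) == 0L) ex <- which.max(diag(A + R))
  clusters <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  clusters[ex] <- ex
  list(exemplars = ex, clusters = clusters, converged = converged)
}

#' Affinity propagation with a target cluster count
#'
#' Bisects the shared preference until message passing yields exactly
#' \code{k} clusters (the usual fixed-K usage of affinity propagation).
#'
#' @param S similarity matrix.
#' @param k desired number of clusters.
#' @param damping,maxit passed to [affinity_propagation()].
#' @param bisect_steps maximum bisection steps (default 25).
#' @return as [affinity_propagation()], plus \code{preference} and
#'   \code{k_achieved}.
#' @export
affinity_propagation_k <- function(S, k, damping = 0.9, maxit = 1000,
                                   bisect_steps = 25) {
  off <- S[row(S) != col(S)]
  lo <- min(off) * 3 - 1          # few clusters
  hi <- max(off) + 1              # many clusters
  best <- NULL
  for (step in seq_len(bisect_steps)) {
    mid <- (lo + hi) / 2
    fit <- affinity_propagation(S, preference = mid, damping = damping,
                                maxit = maxit)
    nk <- length(fit$exemplars)
    if (nk == k) {
      fit$preference <- mid; fit$k_achieved <- nk
      return(fit)
    }
    best <- fit; best$preference <- mid; best$k_achieved <- nk
    if (nk > k) hi <- mid else lo <- mid
  }
  best
}

#' Assign amplicons to cells
#'
#' Amplicons whose (x, y) position falls inside a perinuclear zone are
#' assigned to that zone's cell directly. The remaining amplicons are
#' clustered together with the nucleus centroids by affinity propagation
#' (similarity = negative squared Euclidean distance, preference bisected
#' to K = number of nuclei); each cluster inherits the cell of the
#' nucleus it contains (nearest nucleus to the exemplar when a cluster
#' holds no nucleus). If message passing does not converge the fallback
#' is nearest-zone assignment, with a warning.
#'
#' @param amplicons data.frame with columns \code{x}, \code{y} (pixels).
#' @param cells data.frame from [segment_nuclei()].
#' @param zones zone label matrix from [perinuclear_zones()].
#' @param damping,maxit affinity propagation controls.
#' @return integer vector of cell ids, one per amplicon row.
#' @export
assign_amplicons <- function(amplicons, cells, zones, damping = 0.9,
                             maxit = 1000) {
  if (nrow(cells) == 0L) stop("need at least one nucleus")
  n <- nrow(amplicons)
  cell_of <- rep(NA_integer_, n)
  xi <- pmin(pmax(round(amplicons$x), 1L), ncol(zones))
  yi <- pmin(pmax(round(amplicons$y), 1L), nrow(zones))
  zl <- zones[cbind(yi, xi)]
  inside <- zl > 0L
  cell_of[inside] <- zl[inside]
  rest <- which(!inside)
  if (length(rest) == 0L) return(cell_of)
  if (nrow(cells) == 1L) {
    cell_of[rest] <- cells$cell_id[1]
    return(cell_of)
  }
  pts <- rbind(cbind(amplicons$x[rest], amplicons$y[rest]),
               cbind(cells$x, cells$y))
  D2 <- as.matrix(stats::dist(pts))^2
  fit <- affinity_propagation_k(-D2, k = nrow(cells), damping = damping,
                                maxit = maxit)
  nearest_nucleus <- function(i) {
    cells$cell_id[which.min((cells$x - pts[i, 1])^2 +
                              (cells$y - pts[i, 2])^2)]
  }
  if (is.null(fit) || fit$k_achieved != nrow(cells) || !fit$converged) {
    warning("affinity propagation did not reach the nucleus count; ",
            "falling back to nearest-zone assignment")
    cell_of[rest] <- vapply(seq_along(rest), function(j)
      nearest_nucleus(j), integer(1))
    return(cell_of)
  }
  nuc_rows <- length(rest) + seq_len(nrow(cells))
  cl_to_cell <- integer(0)
  for (ex in fit$exemplars) {
    members <- which(fit$clusters == ex)
    nucs <- intersect(members, nuc_rows)
    cl_to_cell[as.character(ex)] <- if (length(nucs) >= 1L)
      cells$cell_id[nucs[1] - length(rest)]
    else nearest_nucleus(ex)
  }
  cell_of[rest] <- cl_to_cell[as.character(fit$clusters[seq_along(rest)])]
  cell_of
}

#' Build the cell-by-gene count matrix
#'
#' Counts assigned amplicons with a perfect or corrected decode per
#' (cell, gene); discarded decodes contribute nothing.
#'
#' @param cell_of integer cell id per amplicon (NA = unassigned).
#' @param decode data.frame with \code{status} and \code{gene} columns
#'   (for instance [basecall_all()] output).
#' @param cells optional cell data.frame; its centroids are attached as
#'   the \code{"centroids"} attribute.
#' @return integer matrix, rows = cells, columns = genes.
#' @export
build_count_matrix <- function(cell_of, decode, cells = NULL) {
  ok <- decode$status %in% c("perfect", "corrected") & !is.na(cell_of)
  tab <- table(cell = cell_of[ok], gene = decode$gene[ok])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  if (!is.null(cells)) {
    rows <- match(rownames(m), as.character(cells$cell_id))
    attr(m, "centroids") <- cells[rows, c("cell_id", "x", "y")]
  }
  m
}

#' Filter the count matrix by detection thresholds
#'
#' A gene is "detected" in a cell when its count is at least
#' \code{expression_threshold}. Genes detected in fewer than
#' \code{gene_det_in_min_cells} cells are dropped first; cells with
#' fewer than \code{min_det_genes_per_cell} detected genes (among the
#' surviving genes) are dropped second. The single genes-then-cells
#' pass makes the filter idempotent.
#'
#' @param m cell-by-gene count matrix.
#' @param expression_threshold detection count floor (default 1).
#' @param gene_det_in_min_cells minimum cells per kept gene (default 5).
#' @param min_det_genes_per_cell minimum detected genes per kept cell
#'   (default 15).
#' @return the filtered matrix.
#' @export
filter_matrix <- function(m, expression_threshold = 1,
                          gene_det_in_min_cells = 5,
                          min_det_genes_per_cell = 15) {
  det <- m >= expression_threshold
  keep_genes <- colSums(det) >= gene_det_in_min_cells
  m2 <- m[, keep_genes, drop = FALSE]
  det2 <- det[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(det2) >= min_det_genes_per_cell
  out <- m2[keep_cells, , drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    warning("filter removed all cells or all genes")
  cen <- attr(m, "centroids")
  if (!is.null(cen)) attr(out, "centroids") <- cen[keep_cells, , drop = FALSE]
  out
}
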