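## shared fixture builders; everything is generated in code at test time

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## small 3D volume with Gaussian spots at given (z, y, x) centres
render_spots <- function(dim3, centres, sigma = 1.5, amplitude = 100) {
  vol <- array(0, dim3)
  for (k in seq_len(nrow(centres))) {
    c0 <- centres[k, ]
    zz <- max(1, floor(c0[1] - 5)):min(dim3[1], ceiling(c0[1] + 5))
    yy <- max(1, floor(c0[2] - 5)):min(dim3[2], ceiling(c0[2] + 5))
    xx <- max(1, floor(c0[3] - 5)):min(dim3[3], ceiling(c0[3] + 5))
    g <- amplitude *
      outer(outer(exp(-(zz - c0[1])^2 / (2 * sigma^2)),
                  exp(-(yy - c0[2])^2 / (2 * sigma^2))),
            exp(-(xx - c0[3])^2 / (2 * sigma^2)))
    vol[zz, yy, xx] <- vol[zz, yy, xx] + g
  }
  vol
}

## 2D image of filled disks (nucleus-like), dim (ny, nx)
disk_image <- function(ny, nx, centres, radius, intensity = 200) {
  img <- matrix(0, ny, nx)
  for (k in seq_len(nrow(centres))) {
    rr <- outer((seq_len(ny) - centres[k, 2])^2, rep(1, nx)) +
      outer(rep(1, ny), (seq_len(nx) - centres[k, 1])^2)
    img <- img + intensity / (1 + exp((sqrt(rr) - radius) / 1.2))
  }
  img
}

## brute-force minimum Hamming distance over all windows, via Biostrings
oracle_min_mm <- function(target, gene, reference) {
  k <- nchar(target)
  pat <- Biostrings::DNAString(target)
  best <- Inf
  for (r in which(reference$gene_id != gene)) {
    subj <- Biostrings::DNAString(reference$sequence[r])
    nw <- nchar(reference$sequence[r]) - k + 1L
    if (nw < 1L) next
    d <- Biostrings::neditStartingAt(pat, subj, starting.at = seq_len(nw),
                                     with.indels = FALSE)
    best <- min(best, min(d))
  }
  best
}

## brute-force empty-circumcircle check: (i, j) is a Delaunay edge iff
## some circle through i and j contains no other point (checked over all
## third points)
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      ## circumcircle of (i, j, k)
      ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      if (abs(d) < 1e-12) next
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      r2 <- (ax - ux)^2 + (ay - uy)^2
      empty <- TRUE
      for (m in seq_len(n)) {
        if (m %in% c(i, j, k)) next
        if ((x[m] - ux)^2 + (y[m] - uy)^2 < r2 * (1 - 1e-9)) {
          empty <- FALSE; break
        }
      }
      if (empty) { found <- TRUE; break }
    }
    if (found) edges <- rbind(edges, c(i, j))
  }
  edges
}
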