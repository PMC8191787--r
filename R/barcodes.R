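#' Generate an error-robust DNA barcode set (greedy lexicode)
#'
#' Deterministic greedy lexicode: all \code{4^length} words are visited
#' in lexicographic order (A < C < G < T) and a word is kept iff its
#' Hamming distance to every previously kept word is at least
#' \code{min_dist}. The scan is implemented by blocking, for each kept
#' word, every word within distance \code{min_dist - 1}, which is
#' equivalent to the naive greedy rule. Optional composition filters
#' (homotetramer exclusion, GC bounds) are applied before the distance
#' test and are off by default.
#'
#' With \code{length = 8, min_dist = 3} the code corrects every
#' single-base error and flags double errors, and comfortably exceeds
#' the 173 barcodes needed for a 96 mRNA + 77 miRNA panel.
#'
#' @param length barcode length in bases (default 8).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param n_needed number of barcodes required; the scan stops once
#'   satisfied. NULL enumerates the full lexicode.
#' @param filter_homotetramer drop words containing any homotetramer.
#' @param gc_bounds optional numeric length-2 vector of GC-fraction
#'   bounds, e.g. \code{c(0.25, 0.75)}.
#' @return object of class \code{barcode_code}: list with
#'   \code{barcodes}, \code{length}, \code{min_dist}, \code{n_words}
#'   (the 4^length enumeration bound) and an empty \code{assignment}.
#' @examples
#' generate_code(length = 2, min_dist = 2, n_needed = 4)$barcodes
#' # "AA" "CC" "GG" "TT"
#' @export
generate_code <- function(length = 8, min_dist = 3, n_needed = NULL,
                          filter_homotetramer = FALSE, gc_bounds = NULL) {
  L <- as.integer(length)
  d <- as.integer(min_dist)
  if (L < 1L || d < 1L || d > L) stop("need 1 <= min_dist <= length")
  n_words <- 4L^L
  pow <- 4L^((L - 1L):0L)            # first base most significant
  blocked <- logical(n_words)
  kept <- integer(0)
  subs <- 1:3                         # digit offsets modulo 4
  radius <- d - 1L
  pos_sets <- if (radius >= 1L)
    unlist(lapply(seq_len(radius), function(m)
      utils::combn(L, m, simplify = FALSE)), recursive = FALSE)
  else list()
  for (w in 0:(n_words - 1L)) {
    if (blocked[w + 1L]) next
    digits <- (w %/% pow) %% 4L
    if (filter_homotetramer || !is.null(gc_bounds)) {
      word <- .int_to_dna(digits)
      if (filter_homotetramer &&
          grepl("AAAA|CCCC|GGGG|TTTT", word)) next
      if (!is.null(gc_bounds)) {
        gc <- mean(digits %in% c(1L, 2L))
        if (gc < gc_bounds[1] || gc > gc_bounds[2]) next
      }
    }
    kept <- c(kept, w)
    ## block all words within Hamming distance d-1 of w
    for (ps in pos_sets) {
      deltas <- lapply(ps, function(p)
        (((digits[p] + subs) %% 4L) - digits[p]) * pow[p])
      total <- Reduce(function(a, b) as.vector(outer(a, b, `+`)), deltas)
      blocked[w + total + 1L] <- TRUE
    }
    blocked[w + 1L] <- TRUE
    if (!is.null(n_needed) && length(kept) >= n_needed) break
  }
  if (!is.null(n_needed) && length(kept) < n_needed)
    stop("requested ", n_needed, " barcodes but only ", length(kept),
         " achievable at length ", L, ", min_dist ", d)
  words <- vapply(kept, function(w) .int_to_dna((w %/% pow) %% 4L),
                  character(1))
  if (!is.null(n_needed)) words <- words[seq_len(n_needed)]
  structure(list(barcodes = words, length = L, min_dist = d,
                 n_words = n_words, assignment = NULL),
            class = "barcode_code")
}

#' @export
print.barcode_code <- function(x, ...) {
  cat(sprintf("DNA barcode code: %d barcodes of length %d, design distance %d (word space %d)\n",
              length(x$barcodes), x$length, x$min_dist, x$n_words))
  if (!is.null(x$assignment))
    cat(sprintf("  %d gene assignments\n", length(x$assignment)))
  invisible(x)
}

#' Exact minimum pairwise Hamming distance of a code
#'
#' @param code a \code{barcode_code} or character vector of equal-length
#'   barcodes.
#' @return integer minimum over all pairs.
#' @export
verify_code <- function(code) {
  bcs <- if (inherits(code, "barcode_code")) code$barcodes else code
  if (length(bcs) < 2L) stop("need at least 2 barcodes")
  m <- .digit_matrix(bcs)
  n <- nrow(m)
  best <- ncol(m)
  for (i in seq_len(n - 1L)) {
    d <- rowSums(m[(i + 1L):n, , drop = FALSE] !=
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    best <- min(best, min(d))
    if (best == 0L) break
  }
  as.integer(best)
}

#' @keywords internal
.digit_matrix <- function(bcs) {
  t(vapply(bcs, .dna_to_int, integer(nchar(bcs[1]))))
}

#' Assign genes to barcodes
#'
#' Maps gene ids injectively onto the first (or seed-shuffled)
#' barcodes of a code. Generation itself is deterministic; the seed
#' only shuffles which gene gets which barcode.
#'
#' @param code \code{barcode_code}.
#' @param gene_ids character vector of gene identifiers.
#' @param seed optional integer; when given, the gene-to-barcode pairing
#'   is shuffled reproducibly.
#' @return the code with \code{assignment} set (named character vector
#'   gene_id -> barcode).
#' @export
assign_barcodes <- function(code, gene_ids, seed = NULL) {
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (length(gene_ids) > length(code$barcodes))
    stop("more genes than barcodes (", length(code$barcodes), " available)")
  bcs <- code$barcodes[seq_along(gene_ids)]
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    bcs <- sample(bcs)
  }
  names(bcs) <- gene_ids
  code$assignment <- bcs
  code
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Decode one observed barcode against a reference code
#'
#' Exact matches are \code{perfect}. Otherwise the Hamming distance to
#' every reference barcode is computed: a minimum distance above 2 gives
#' \code{discarded_distance}; a minimum achieved by two or more
#' references gives \code{discarded_ambiguous}; a unique minimum of 1
#' or 2 assigns the read to that reference (\code{corrected}).
#'
#' @param observed observed barcode (same length as the code).
#' @param code \code{barcode_code} with an \code{assignment}.
#' @return list with \code{observed}, \code{status}, \code{assigned_gene}
#'   (NA when discarded), \code{barcode} and \code{distance}.
#' @export
decode_barcode <- function(observed, code) {
  res <- decode_barcodes(observed, code)
  as.list(res[1L, ])
}

#' Decode a vector of observed barcodes
#'
#' Vectorised form of [decode_barcode()].
#'
#' @param observed character vector of observed barcodes.
#' @param code \code{barcode_code} with an \code{assignment}.
#' @return data.frame with columns \code{observed}, \code{status},
#'   \code{assigned_gene}, \code{barcode}, \code{distance}.
#' @export
decode_barcodes <- function(observed, code) {
  if (is.null(code$assignment)) stop("code has no gene assignment")
  refs <- unname(code$assignment)
  genes <- names(code$assignment)
  if (any(nchar(observed) != code$length) || any(grepl("[^ACGT]", observed)))
    stop("observed barcodes must be ", code$length, "-mers over ACGT")
  rm <- .digit_matrix(refs)
  om <- .digit_matrix(observed)
  n <- nrow(om); r <- nrow(rm)
  status <- character(n); gene <- rep(NA_character_, n)
  bc <- rep(NA_character_, n); dist <- rep(NA_integer_, n)
  exact <- match(observed, refs)
  for (i in seq_len(n)) {
    if (!is.na(exact[i])) {
      status[i] <- "perfect"; gene[i] <- genes[exact[i]]
      bc[i] <- refs[exact[i]]; dist[i] <- 0L
      next
    }
    d <- rowSums(rm != matrix(om[i, ], r, ncol(rm), byrow = TRUE))
    dmin <- min(d)
    if (dmin > 2L) {
      status[i] <- "discarded_distance"
    } else if (sum(d == dmin) > 1L) {
      status[i] <- "discarded_ambiguous"
    } else {
      k <- which.min(d)
      status[i] <- "corrected"; gene[i] <- genes[k]
      bc[i] <- refs[k]; dist[i] <- as.integer(dmin)
    }
  }
  data.frame(observed = observed, status = status, assigned_gene = gene,
             barcode = bc, distance = dist, stringsAsFactors = FALSE)
}

#' Summarise decode results
#'
#' Counts and fractions per decode status plus per-gene amplicon counts.
#'
#' @param observed character vector of observed barcodes, or a decode
#'   data.frame from [decode_barcodes()].
#' @param code \code{barcode_code}; required when `observed` is raw.
#' @return list with \code{summary} (status, count, fraction) and
#'   \code{per_gene} (gene, count) data.frames.
#' @export
decode_table <- function(observed, code = NULL) {
  res <- if (is.data.frame(observed)) observed
         else decode_barcodes(observed, code)
  lev <- c("perfect", "corrected", "discarded_distance",
           "discarded_ambiguous")
  counts <- table(factor(res$status, levels = lev))
  summary <- data.frame(status = lev, count = as.integer(counts),
                        fraction = as.numeric(counts) / max(1L, nrow(res)))
  gene_col <- if (!is.null(res$assigned_gene)) res$assigned_gene
              else res$gene                      # amplicon tables say "gene"
  assigned <- gene_col[!is.na(gene_col)]
  pg <- data.frame(gene = character(0), count = integer(0))
  if (length(assigned) > 0L) {
    tab <- table(assigned)
    pg <- data.frame(gene = names(tab), count = as.integer(tab))
  }
  list(summary = summary, per_gene = pg)
}

#' Write / read a gene-barcode reference table
#'
#' The reference table (columns \code{gene_id}, \code{barcode}) is the
#' serialised form of a code's assignment, always written alongside
#' results so decodes are reproducible.
#'
#' @param code \code{barcode_code} with assignment.
#' @param path TSV path.
#' @return for write, invisibly the path; for read, a
#'   \code{barcode_code} rebuilt from the table.
#' @export
write_barcode_table <- function(code, path) {
  if (is.null(code$assignment)) stop("code has no gene assignment")
  utils::write.table(
    data.frame(gene_id = names(code$assignment),
               barcode = unname(code$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_table
#' @param min_dist design distance recorded on read-back (default 3).
#' @export
read_barcode_table <- function(path, min_dist = 3) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  L <- nchar(tab$barcode[1])
  bcs <- tab$barcode
  names(bcs) <- NULL
  code <- structure(list(barcodes = bcs, length = L,
                         min_dist = min_dist, n_words = 4L^L,
                         assignment = NULL),
                    class = "barcode_code")
  asn <- tab$barcode
  names(asn) <- tab$gene_id
  code$assignment <- asn
  code
}
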