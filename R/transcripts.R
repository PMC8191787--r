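#' Read target transcript sequences from FASTA
#'
#' Reads a transcript FASTA, normalises sequences to uppercase DNA
#' (U converted to T) and parses headers into transcript and gene
#' identifiers. The expected header layout is
#' \code{transcript_id<delim>gene_id}; when the delimiter is absent the
#' gene id defaults to the transcript id.
#'
#' @param fasta_path path to a FASTA file.
#' @param id_delim delimiter between transcript id and gene id in the
#'   header (default \code{"|"}).
#' @return data.frame with columns \code{transcript_id}, \code{gene_id},
#'   \code{sequence}.
#' @export
read_transcripts <- function(fasta_path, id_delim = "|") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path)
  headers <- names(seqs)
  seq_chr <- toupper(as.character(seqs))
  seq_chr <- chartr("U", "T", seq_chr)
  bad <- grepl("[^ACGT]", seq_chr)
  if (any(bad))
    stop("record(s) with non-ACGTU characters: ",
         paste(utils::head(headers[bad], 5), collapse = ", "))
  parts <- strsplit(headers, id_delim, fixed = TRUE)
  transcript_id <- vapply(parts, `[`, character(1), 1L)
  gene_id <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L],
                    character(1))
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             sequence = unname(seq_chr), stringsAsFactors = FALSE)
}

#' Write transcripts to FASTA
#'
#' @param transcripts data.frame as returned by [read_transcripts()].
#' @param path output FASTA path.
#' @param id_delim delimiter used to join transcript and gene ids in the
#'   header.
#' @return invisibly, `path`.
#' @export
write_transcripts <- function(transcripts, path, id_delim = "|") {
  set <- Biostrings::DNAStringSet(transcripts$sequence)
  names(set) <- paste(transcripts$transcript_id, transcripts$gene_id,
                      sep = id_delim)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene-level expression table
#'
#' Reads a TSV with columns \code{gene_id} and \code{baseMean} (the
#' DESeq2-style mean of normalised counts used for reference filtering).
#'
#' @param path TSV path.
#' @return data.frame with columns \code{gene_id}, \code{base_mean}.
#' @export
read_expression_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("gene_id", "basemean") %in% names(tab)))
    stop("expression table must have columns gene_id and baseMean")
  out <- data.frame(gene_id = tab$gene_id,
                    base_mean = as.numeric(tab$basemean),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicated gene_id in expression table")
  if (any(out$base_mean < 0)) stop("negative baseMean")
  out
}

#' Restrict transcripts to an expressed reference set
#'
#' Builds the off-target reference by removing genes whose expression
#' baseMean falls below a threshold. Removal is strict: a gene at exactly
#' the threshold is kept. Genes absent from the table are treated as
#' baseMean 0 and dropped with a warning under the default policy, or
#' retained under \code{missing = "keep"}.
#'
#' @param transcripts data.frame from [read_transcripts()].
#' @param expression data.frame with \code{gene_id}, \code{base_mean}.
#' @param min_base_mean expression floor (default 10).
#' @param missing policy for genes absent from the table: \code{"drop"}
#'   (default) or \code{"keep"}.
#' @return the retained subset of `transcripts`.
#' @export
filter_reference <- function(transcripts, expression, min_base_mean = 10,
                             missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  bm <- expression$base_mean[match(transcripts$gene_id, expression$gene_id)]
  absent <- is.na(bm)
  if (any(absent)) {
    if (missing == "drop") {
      warning(sum(absent), " gene(s) missing from expression table; dropped")
      bm[absent] <- 0
    } else {
      bm[absent] <- Inf
    }
  }
  transcripts[bm >= min_base_mean, , drop = FALSE]
}
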