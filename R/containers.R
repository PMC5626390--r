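#' Gene model set
#'
#' One record per gene: identifier, chromosome, strand, transcript span and
#' transcriptional start site (TSS). Coordinates are BED-native 0-based
#' half-open throughout the package; the TSS of a minus-strand gene is
#' `end - 1`, the last covered base.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end 0-based half-open transcript span (`start < end`).
#' @return A data frame of class `"gene_models"` with columns `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, sorted by
#'   (`chrom`, `start`, `gene_id`).
#' @export
#' @examples
#' gene_models("geneA", "chr1", "+", 100, 600)$tss  # 100
#' gene_models("geneB", "chr1", "-", 100, 600)$tss  # 599
gene_models <- function(gene_id, chrom, strand, start, end) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(start) == n, length(end) == n)
  bad_strand <- which(!strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop_input("unknown strand '%s' for gene '%s' (record %d)",
               strand[bad_strand[1L]], gene_id[bad_strand[1L]], bad_strand[1L])
  }
  bad_coord <- which(!(start < end) | start < 0)
  if (length(bad_coord)) {
    i <- bad_coord[1L]
    stop_input("malformed coordinates for gene '%s' (record %d): start=%s end=%s",
               gene_id[i], i, format(start[i]), format(end[i]))
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop_input("duplicate gene_id within gene model set: %s",
               paste(unique(dup), collapse = ", "))
  }
  tss <- ifelse(strand == "+", start, end - 1)
  out <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    start = start, end = end, tss = tss,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Scored peak set
#'
#' A named collection of scored genomic intervals for one factor/condition.
#' The per-peak `amplitude` is the tag count (signal height) used for the
#' top-quartile "high amplitude" criterion. Coordinates are 0-based half-open.
#'
#' @param chrom,start,end interval coordinates (`start < end`).
#' @param peak_id optional peak identifiers; missing/empty entries are
#'   auto-assigned `"peak_<n>"`.
#' @param amplitude non-negative tag count per peak.
#' @param name label for the set (e.g. condition).
#' @return A data frame of class `"peak_set"` with attribute `set_name`.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL, amplitude,
                     name = "peaks") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  chrom <- rep_len(as.character(chrom), n)
  amplitude <- rep_len(as.numeric(amplitude), n)
  stopifnot(length(end) == n)
  bad <- which(!(start < end) | start < 0)
  if (length(bad)) {
    stop_input("zero-length or malformed interval at record %d: %s:%s-%s",
               bad[1L], chrom[bad[1L]], format(start[bad[1L]]),
               format(end[bad[1L]]))
  }
  if (anyNA(amplitude) || any(amplitude < 0)) {
    stop_input("peak amplitude must be non-negative")
  }
  if (is.null(peak_id)) peak_id <- rep(NA_character_, n)
  peak_id <- as.character(peak_id)
  auto <- is.na(peak_id) | peak_id == "" | peak_id == "."
  peak_id[auto] <- paste0("peak_", seq_len(n)[auto])
  dup <- peak_id[duplicated(peak_id)]
  if (length(dup)) {
    stop_input("duplicate peak_id: %s", paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    peak_id = peak_id, amplitude = amplitude,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "set_name") <- name
  class(out) <- c("peak_set", "data.frame")
  out
}

# 1-based closed GRanges view of 0-based half-open records; a shared
# seqlevel universe avoids cross-set comparison warnings
as_granges0 <- function(chrom, start, end, seqlevels = unique(chrom)) {
  GenomicRanges::GRanges(factor(chrom, levels = seqlevels),
                         IRanges::IRanges(start + 1, end))
}

#' Expression table
#'
#' Genes-by-samples RPKM values with sample condition labels, optionally raw
#' counts and precomputed per-contrast p-values. Rows are keyed by
#' (`gene_id`, `transcript_id`); after [collapse_transcripts()] there is one
#' row per gene.
#'
#' @param rpkm numeric matrix (rows = transcripts, columns = samples) of
#'   non-negative RPKM values.
#' @param samples data frame with columns `sample` and `condition`, one row
#'   per column of `rpkm`.
#' @param genes data frame with columns `gene_id` and `transcript_id`
#'   parallel to the rows of `rpkm`; defaults to treating row names as both.
#' @param counts optional raw count matrix with the same dimensions.
#' @param pvalues optional named list, one numeric vector per contrast key
#'   (see [contrast_key()]), aligned to rows.
#' @return An object of class `"expression_table"`.
#' @export
expression_table <- function(rpkm, samples, genes = NULL, counts = NULL,
                             pvalues = NULL) {
  rpkm <- as.matrix(rpkm)
  if (!is.numeric(rpkm)) stop_input("'rpkm' must be numeric")
  if (anyNA(rpkm) || any(rpkm < 0)) {
    stop_input("RPKM values must be non-negative and non-missing")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(samples))) {
    stop_input("'samples' needs columns 'sample' and 'condition'")
  }
  if (nrow(samples) != ncol(rpkm)) {
    stop_input("'samples' must describe every column of 'rpkm'")
  }
  colnames(rpkm) <- samples$sample
  if (is.null(genes)) {
    ids <- rownames(rpkm) %||% as.character(seq_len(nrow(rpkm)))
    genes <- data.frame(gene_id = ids, transcript_id = ids,
                        stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$transcript_id)) genes$transcript_id <- genes$gene_id
  if (nrow(genes) != nrow(rpkm)) {
    stop_input("'genes' must describe every row of 'rpkm'")
  }
  key <- paste(genes$gene_id, genes$transcript_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop_input("duplicate (gene_id, transcript_id) rows in expression table")
  }
  rownames(rpkm) <- genes$transcript_id
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    stopifnot(dim(counts) == dim(rpkm))
    if (anyNA(counts) || any(counts < 0)) {
      stop_input("counts must be non-negative")
    }
    dimnames(counts) <- dimnames(rpkm)
  }
  if (!is.null(pvalues)) {
    stopifnot(is.list(pvalues), !is.null(names(pvalues)))
    for (k in names(pvalues)) {
      if (length(pvalues[[k]]) != nrow(rpkm)) {
        stop_input("p-value vector '%s' does not match the number of rows", k)
      }
    }
  }
  structure(list(rpkm = rpkm, counts = counts,
                 genes = genes[, c("gene_id", "transcript_id")],
                 samples = samples[, c("sample", "condition")],
                 pvalues = pvalues, offset = NULL,
                 collapsed = !anyDuplicated(genes$gene_id)),
            class = "expression_table")
}

# per-condition mean RPKM matrix; raw = subtract the applied offset first
condition_means <- function(table, raw = TRUE) {
  x <- table$rpkm
  if (raw && !is.null(table$offset)) x <- x - table$offset
  conds <- unique(table$samples$condition)
  out <- vapply(conds, function(cc) {
    rowMeans(x[, table$samples$condition == cc, drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), conds))
  out
}
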