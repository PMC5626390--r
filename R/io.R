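# Readers and writers for the external formats the pipeline touches.
# Everything is validated on read and stored 0-based half-open internally,
# regardless of the input dialect (BED is native; the TSV gene-model dialect
# is 1-based inclusive and converted by subtracting 1 from starts).

read_tab <- function(path, ...) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

#' Read gene models from BED12 or a tabular gene file
#'
#' @param path input file.
#' @param format `"bed12"` (0-based half-open; columns chrom, start, end,
#'   name, score, strand, ...) or `"tsv"` (header with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`; 1-based inclusive coordinates,
#'   converted on read).
#' @return A [gene_models] object.
#' @export
read_gene_models <- function(path, format = c("bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "bed12") {
    x <- read_tab(path, header = FALSE)
    if (ncol(x) < 6L) {
      stop_input("BED12 gene file '%s' needs at least 6 columns", path)
    }
    bad <- which(!(x[[2L]] < x[[3L]]))
    if (length(bad)) {
      stop_input("%s line %d: start >= end", path, bad[1L])
    }
    gene_models(gene_id = x[[4L]], chrom = x[[1L]], strand = x[[6L]],
                start = x[[2L]], end = x[[3L]])
  } else {
    x <- read_tab(path, header = TRUE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      stop_input("gene TSV '%s' lacks columns: %s", path,
                 paste(miss, collapse = ", "))
    }
    bad <- which(!(x$start - 1 < x$end))
    if (length(bad)) stop_input("%s line %d: start >= end", path, bad[1L] + 1L)
    gene_models(gene_id = x$gene_id, chrom = x$chrom, strand = x$strand,
                start = x$start - 1, end = x$end)
  }
}

#' Write gene models as BED12
#'
#' @param genes a [gene_models] object.
#' @param path output file.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  len <- genes$end - genes$start
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0,
                    genes$strand, genes$start, genes$end, "0", 1,
                    len, 0)
  utils::write.table(format(bed, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks from BED6 or narrowPeak
#'
#' Peak amplitude (tag count) is taken from the score column for BED6 and
#' from `signalValue` (column 7) for ENCODE narrowPeak.
#'
#' @param path input file.
#' @param format `"bed6"` or `"narrowPeak"`.
#' @param name label for the returned set (defaults to the file name).
#' @return A [peak_set] object.
#' @export
read_peaks <- function(path, format = c("bed6", "narrowPeak"),
                       name = basename(path)) {
  format <- match.arg(format)
  x <- read_tab(path, header = FALSE)
  if (format == "bed6" && ncol(x) < 5L) {
    stop_input("BED6 peak file '%s' needs at least 5 columns", path)
  }
  if (format == "narrowPeak" && ncol(x) < 10L) {
    stop_input("narrowPeak file '%s' needs 10 columns", path)
  }
  bad <- which(!(x[[2L]] < x[[3L]]))
  if (length(bad)) stop_input("%s line %d: zero-length interval", path, bad[1L])
  amp <- if (format == "bed6") as.numeric(x[[5L]]) else as.numeric(x[[7L]])
  bad_amp <- which(is.na(amp) | amp < 0)
  if (length(bad_amp)) {
    stop_input("%s line %d: negative or missing score", path, bad_amp[1L])
  }
  peak_set(chrom = x[[1L]], start = x[[2L]], end = x[[3L]],
           peak_id = x[[4L]], amplitude = amp, name = name)
}

#' Write a peak set as BED6 or narrowPeak
#'
#' @param peaks a [peak_set].
#' @param path output file.
#' @param format `"bed6"` (amplitude in the score column) or `"narrowPeak"`
#'   (amplitude in `signalValue`).
#' @export
write_peaks <- function(peaks, path, format = c("bed6", "narrowPeak")) {
  format <- match.arg(format)
  stopifnot(inherits(peaks, "peak_set"))
  out <- if (format == "bed6") {
    data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
               peaks$amplitude, ".")
  } else {
    data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id, 0, ".",
               peaks$amplitude, -1, -1, -1)
  }
  utils::write.table(format(out, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# sample columns are "<condition>__<replicate>"; p-value columns are
# "pvalue__<treated>_vs_<reference>"
parse_sample_header <- function(nms) {
  cond <- sub("__[^_]*$", "", nms)
  bad <- which(cond == nms | cond == "")
  if (length(bad)) {
    stop_input(paste0("cannot resolve condition for sample column '%s'; ",
                      "use '<condition>__<replicate>' names or pass 'samples'"),
               nms[bad[1L]])
  }
  data.frame(sample = nms, condition = cond, stringsAsFactors = FALSE)
}

#' Read an expression table from TSV
#'
#' The file must have a `gene_id` column, an optional `transcript_id` column,
#' one or more numeric sample columns and optional precomputed p-value
#' columns named `pvalue__<treated>_vs_<reference>`. Sample-to-condition
#' mapping is taken from the `samples` argument when given, otherwise from
#' the header convention `<condition>__<replicate>`.
#'
#' @param path TSV file of RPKM values.
#' @param samples optional data frame with columns `sample`, `condition`.
#' @param counts_path optional TSV of raw counts with the same layout.
#' @return An [expression_table].
#' @export
read_expression <- function(path, samples = NULL, counts_path = NULL) {
  x <- read_tab(path, header = TRUE, check.names = FALSE)
  if (is.null(x$gene_id)) stop_input("expression TSV needs a 'gene_id' column")
  id_cols <- intersect(c("gene_id", "transcript_id"), names(x))
  pv_cols <- grep("^pvalue__", names(x), value = TRUE)
  sm_cols <- setdiff(names(x), c(id_cols, pv_cols))
  if (!length(sm_cols)) stop_input("expression TSV has no sample columns")
  rpkm <- as.matrix(x[, sm_cols, drop = FALSE])
  if (!is.numeric(rpkm)) stop_input("sample columns must be numeric")
  if (anyNA(rpkm) || any(rpkm < 0)) {
    stop_input("negative or missing RPKM value in '%s'", path)
  }
  if (is.null(samples)) {
    samples <- parse_sample_header(sm_cols)
  } else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    miss <- setdiff(sm_cols, samples$sample)
    if (length(miss)) {
      stop_input("no condition given for samples: %s",
                 paste(miss, collapse = ", "))
    }
    samples <- samples[match(sm_cols, samples$sample), c("sample", "condition")]
  }
  genes <- data.frame(gene_id = as.character(x$gene_id),
                      transcript_id = as.character(x$transcript_id %||%
                                                     x$gene_id),
                      stringsAsFactors = FALSE)
  pvalues <- NULL
  if (length(pv_cols)) {
    pvalues <- lapply(pv_cols, function(cc) as.numeric(x[[cc]]))
    names(pvalues) <- sub("^pvalue__", "", pv_cols)
  }
  counts <- NULL
  if (!is.null(counts_path)) {
    y <- read_tab(counts_path, header = TRUE, check.names = FALSE)
    counts <- as.matrix(y[, sm_cols, drop = FALSE])
  }
  expression_table(rpkm, samples = samples, genes = genes, counts = counts,
                   pvalues = pvalues)
}

#' Write an expression table as TSV
#'
#' Columns follow the conventions of [read_expression()], so a write/read
#' round trip reproduces the object.
#'
#' @param table an [expression_table].
#' @param path output TSV.
#' @param what `"rpkm"` or `"counts"`.
#' @export
write_expression <- function(table, path, what = c("rpkm", "counts")) {
  what <- match.arg(what)
  m <- table[[what]]
  if (is.null(m)) stop_input("table carries no '%s' matrix", what)
  out <- data.frame(gene_id = table$genes$gene_id,
                    transcript_id = table$genes$transcript_id,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$pvalues) && what == "rpkm") {
    for (k in names(table$pvalues)) {
      out[[paste0("pvalue__", k)]] <- table$pvalues[[k]]
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are collapsed; a line with fewer than 3 fields or a
#' set that is empty after cleanup is an error.
#'
#' @param path GMT file.
#' @return Named list of character vectors, class `"gene_set_collection"`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_input("%s line %d: GMT record has fewer than 3 fields", path, i)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_input("%s line %d: empty gene set", path, i)
    sets[[f[[1L]]]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write / read a derived signature as TSV
#'
#' Columns: `gene_id`, `tier`, `fold_change`, `p_value`, `best_peak_id`,
#' `best_amplitude`, `direction`, sorted by `gene_id`. An empty signature
#' writes a header-only file.
#'
#' @param sig a `tf_signature` (see [derive_full_signature()]).
#' @param path TSV path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "tf_signature"))
  cols <- c("gene_id", "tier", "fold_change", "p_value", "best_peak_id",
            "best_amplitude", "direction")
  out <- as.data.frame(sig)[, cols, drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @return `read_signature()` returns the signature data frame with class
#'   `"tf_signature"` and the tier recovered from the `tier` column.
#' @export
read_signature <- function(path) {
  x <- read_tab(path, header = TRUE, check.names = FALSE,
                colClasses = c(gene_id = "character",
                               best_peak_id = "character"))
  tier <- if (nrow(x)) unique(x$tier) else NA_character_
  x <- x[order(x$gene_id), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, tier = tier, class = c("tf_signature", "data.frame"))
}

#' Write a result object as TSV or JSON
#'
#' Data frames go to TSV; list-like reports go to JSON with scalar unboxing.
#'
#' @param obj data frame or list.
#' @param path output path.
#' @param format `"tsv"` or `"json"`; default guessed from the extension.
#' @export
write_report <- function(obj, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path)) "json" else "tsv"
  }
  if (format == "json") {
    obj <- strip_report(obj)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(obj))
    utils::write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# drop function-unfriendly attributes/classes before JSON serialisation
strip_report <- function(obj) {
  if (is.data.frame(obj)) return(as.data.frame(obj))
  if (is.list(obj)) {
    obj <- lapply(obj, strip_report)
  }
  attributes(obj) <- attributes(obj)["names"]
  obj
}
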