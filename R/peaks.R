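# Interval computations on peak sets. Overlap = >= 1 bp intersection in
# half-open coordinates; the interval index is GenomicRanges/IRanges, with
# the all-pairs brute-force scan reserved for the test oracle.

#' Assign peaks to genes by gene-body overlap or TSS proximity
#'
#' A (peak, gene) pair is included iff the peak overlaps the gene body
#' (transcript span, introns included) by at least 1 bp, or the minimum
#' distance from any base covered by the peak to the gene's TSS is strictly
#' below `window` (both directions). A peak may map to several genes and
#' vice versa; a pair satisfying both criteria is recorded once with
#' relation `"in_body"`.
#'
#' @param peaks a [peak_set].
#' @param genes a [gene_models] set sharing the peak chromosome namespace.
#' @param window TSS window in bp (default 50000, i.e. < 50 kb).
#' @return Data frame of class `"peak_assignment"` with columns `peak_id`,
#'   `gene_id`, `relation` (`in_body`/`near_tss`), `distance` (signed bp from
#'   peak to TSS, 0 if the peak spans the TSS, positive downstream relative
#'   to the gene strand) and `amplitude`. Attribute `n_unassignable_chrom`
#'   counts peaks on chromosomes absent from the gene models.
#' @export
assign_peaks_to_genes <- function(peaks, genes, window = 50000) {
  stopifnot(inherits(peaks, "peak_set"), inherits(genes, "gene_models"))
  if (!is.numeric(window) || window <= 0) stop_input("'window' must be > 0")
  n_off <- sum(!peaks$chrom %in% unique(genes$chrom))

  empty <- data.frame(peak_id = character(), gene_id = character(),
                      relation = character(), distance = numeric(),
                      amplitude = numeric(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) {
    return(structure(empty, window = window,
                     n_unassignable_chrom = n_off,
                     class = c("peak_assignment", "data.frame")))
  }
  lv <- unique(c(peaks$chrom, genes$chrom))
  pk <- as_granges0(peaks$chrom, peaks$start, peaks$end, lv)
  body <- as_granges0(genes$chrom, genes$start, genes$end, lv)
  # 0-based positions within distance < window of the TSS: [tss-w+1, tss+w-1]
  win <- as_granges0(genes$chrom, pmax(0, genes$tss - window + 1),
                     genes$tss + window, lv)
  hb <- GenomicRanges::findOverlaps(pk, body)
  hw <- GenomicRanges::findOverlaps(pk, win)
  pairs <- unique(rbind(
    data.frame(p = S4Vectors::queryHits(hb), g = S4Vectors::subjectHits(hb),
               body = rep(TRUE, length(hb))),
    data.frame(p = S4Vectors::queryHits(hw), g = S4Vectors::subjectHits(hw),
               body = rep(FALSE, length(hw)))))
  if (nrow(pairs)) {
    in_body <- tapply(pairs$body, paste(pairs$p, pairs$g), any)
    key <- paste(pairs$p, pairs$g)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs$body <- as.logical(in_body[paste(pairs$p, pairs$g)])
  }
  ps <- peaks$start[pairs$p]; pe <- peaks$end[pairs$p]
  tss <- genes$tss[pairs$g]
  d0 <- ifelse(pe - 1 < tss, pe - 1 - tss, ifelse(ps > tss, ps - tss, 0))
  signed <- ifelse(genes$strand[pairs$g] == "-", -d0, d0)
  out <- data.frame(peak_id = peaks$peak_id[pairs$p],
                    gene_id = genes$gene_id[pairs$g],
                    relation = ifelse(pairs$body, "in_body", "near_tss"),
                    distance = signed,
                    amplitude = peaks$amplitude[pairs$p],
                    stringsAsFactors = FALSE)
  out <- out[order(out$peak_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, window = window, n_unassignable_chrom = n_off,
            class = c("peak_assignment", "data.frame"))
}

#' Compare two condition peak sets
#'
#' A peak of set A is "shared" iff it overlaps at least one peak of set B by
#' >= 1 bp (and symmetrically for B); because overlaps can be many-to-one,
#' `shared_a` and `shared_b` may differ.
#'
#' @param peaks_a,peaks_b non-empty [peak_set]s.
#' @return List of class `"overlap_report"` with counts, fractions and
#'   per-peak shared flags.
#' @export
classify_condition_overlap <- function(peaks_a, peaks_b) {
  stopifnot(inherits(peaks_a, "peak_set"), inherits(peaks_b, "peak_set"))
  if (nrow(peaks_a) == 0L || nrow(peaks_b) == 0L) {
    stop_input("both peak sets must be non-empty")
  }
  lv <- unique(c(peaks_a$chrom, peaks_b$chrom))
  ga <- as_granges0(peaks_a$chrom, peaks_a$start, peaks_a$end, lv)
  gb <- as_granges0(peaks_b$chrom, peaks_b$start, peaks_b$end, lv)
  fa <- GenomicRanges::countOverlaps(ga, gb) > 0
  fb <- GenomicRanges::countOverlaps(gb, ga) > 0
  structure(list(
    n_a = nrow(peaks_a), n_b = nrow(peaks_b),
    shared_a = sum(fa), unique_a = sum(!fa),
    shared_b = sum(fb), unique_b = sum(!fb),
    frac_shared_a = mean(fa), frac_shared_b = mean(fb),
    flags_a = stats::setNames(fa, peaks_a$peak_id),
    flags_b = stats::setNames(fb, peaks_b$peak_id)),
    class = "overlap_report")
}

#' Genes exclusively associated with one condition's peaks
#'
#' Partitions the union of the two assignments' gene universes into genes
#' associated only with A-peaks, only with B-peaks, or with both.
#'
#' @param assign_a,assign_b `peak_assignment`s built against the same gene
#'   models.
#' @return List of class `"exclusivity_report"` with the three gene vectors,
#'   counts, and fractions relative to the union.
#' @export
gene_association_exclusivity <- function(assign_a, assign_b) {
  ga <- unique(assign_a$gene_id)
  gb <- unique(assign_b$gene_id)
  both <- sort(intersect(ga, gb))
  a_only <- sort(setdiff(ga, gb))
  b_only <- sort(setdiff(gb, ga))
  n_union <- length(both) + length(a_only) + length(b_only)
  frac <- function(k) if (n_union) k / n_union else 0
  structure(list(a_only = a_only, b_only = b_only, both = both,
                 n_a_only = length(a_only), n_b_only = length(b_only),
                 n_both = length(both), n_union = n_union,
                 frac_a_only = frac(length(a_only)),
                 frac_b_only = frac(length(b_only)),
                 frac_both = frac(length(both))),
            class = "exclusivity_report")
}

#' TSS-distance profile of assigned peaks
#'
#' Each assigned peak contributes once at its absolute distance to the
#' nearest assigned TSS; per bin, the fraction of assigned peaks and the
#' mean peak amplitude are reported. Bins are half-open `[lo, hi)`; empty
#' bins report fraction 0 and `NA` amplitude.
#'
#' @param assignment a `peak_assignment`.
#' @param bin_edges strictly increasing numeric vector of bin edges (bp).
#' @return Data frame of class `"tss_profile"` with columns `bin_lo`,
#'   `bin_hi`, `n`, `fraction`, `mean_amplitude`.
#' @export
tss_distance_profile <- function(assignment, bin_edges) {
  stopifnot(inherits(assignment, "peak_assignment"))
  if (nrow(assignment) == 0L) stop_input("assignment is empty")
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop_input("'bin_edges' must be strictly increasing with >= 2 values")
  }
  d <- abs(assignment$distance)
  nearest <- tapply(d, assignment$peak_id, min)
  amp <- tapply(assignment$amplitude, assignment$peak_id, function(x) x[1L])
  n_peaks <- length(nearest)
  idx <- findInterval(nearest, bin_edges, rightmost.closed = FALSE)
  inside <- idx >= 1L & idx < length(bin_edges)
  nb <- length(bin_edges) - 1L
  n_in <- tabulate(idx[inside], nbins = nb)
  mean_amp <- vapply(seq_len(nb), function(b) {
    v <- amp[inside & idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1L],
                    n = n_in, fraction = n_in / n_peaks,
                    mean_amplitude = mean_amp)
  structure(out, n_peaks = n_peaks,
            class = c("tss_profile", "data.frame"))
}

#' Flag high-amplitude peaks by quantile
#'
#' A peak is "high amplitude" iff its amplitude is at or above the
#' `q`-quantile of all amplitudes in the set (linear-interpolation quantile,
#' R type 7). The "top 25 %" rule of the compact signature corresponds to
#' the default `q = 0.75`.
#'
#' @param peaks a non-empty [peak_set].
#' @param q quantile in \[0, 1\] (default 0.75).
#' @return Named logical vector (by `peak_id`) with attributes `threshold`
#'   and `q`.
#' @export
amplitude_quantile_flag <- function(peaks, q = 0.75) {
  stopifnot(inherits(peaks, "peak_set"))
  if (nrow(peaks) == 0L) stop_input("peak set is empty")
  check_prob(q, "q")
  thr <- unname(stats::quantile(peaks$amplitude, probs = q, type = 7))
  structure(stats::setNames(peaks$amplitude >= thr, peaks$peak_id),
            threshold = thr, q = q)
}

#' Two-factor co-occupancy
#'
#' Fraction of A-peaks overlapping at least one B-peak, plus, for each
#' A-peak, the signed distance from its midpoint to the nearest B-peak
#' midpoint (for co-localisation histograms; `NA` when the chromosome has
#' no B-peak).
#'
#' @param peaks_a,peaks_b non-empty [peak_set]s (e.g. STAT5 and T-bet).
#' @return List of class `"cooccupancy_report"`: `fraction`, per-peak
#'   `flags`, `midpoint_distance`.
#' @export
cooccupancy <- function(peaks_a, peaks_b) {
  ov <- classify_condition_overlap(peaks_a, peaks_b)
  mid_a <- (peaks_a$start + peaks_a$end) / 2
  mid_b <- (peaks_b$start + peaks_b$end) / 2
  dist <- rep(NA_real_, nrow(peaks_a))
  for (cc in unique(peaks_a$chrom)) {
    ia <- which(peaks_a$chrom == cc)
    ib <- which(peaks_b$chrom == cc)
    if (!length(ib)) next
    mb <- sort(mid_b[ib])
    pos <- findInterval(mid_a[ia], mb)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(mb))
    d_lo <- mb[lo] - mid_a[ia]
    d_hi <- mb[hi] - mid_a[ia]
    dist[ia] <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
  }
  structure(list(fraction = ov$frac_shared_a,
                 n_a = ov$n_a, shared_a = ov$shared_a,
                 flags = ov$flags_a,
                 midpoint_distance = stats::setNames(dist, peaks_a$peak_id)),
            class = "cooccupancy_report")
}
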