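# RPKM preprocessing and differential-expression calling.
#
# Fixed pipeline order: collapse transcripts -> filter low abundance (on raw
# per-condition means) -> add the pooled-median offset -> fold changes / DEG
# calls. The offset (the second quartile, i.e. median, of all RPKM cells)
# damps fold-change artifacts from low-abundance transcripts.

#' Collapse transcripts to one row per gene
#'
#' When several transcripts are detected for a gene, only the most abundant
#' one (highest mean RPKM across all samples) is kept. Exact ties are broken
#' by the lexicographically smallest `transcript_id`, so the result is
#' deterministic; the operation is idempotent.
#'
#' @param table an [expression_table].
#' @return The collapsed [expression_table].
#' @export
collapse_transcripts <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  m <- rowMeans(table$rpkm)
  ord <- order(table$genes$gene_id, -m, table$genes$transcript_id)
  keep_ord <- ord[!duplicated(table$genes$gene_id[ord])]
  keep <- sort(keep_ord)  # preserve original row order
  subset_rows(table, keep, collapsed = TRUE)
}

subset_rows <- function(table, keep, collapsed = table$collapsed) {
  table$rpkm <- table$rpkm[keep, , drop = FALSE]
  if (!is.null(table$counts)) {
    table$counts <- table$counts[keep, , drop = FALSE]
  }
  table$genes <- table$genes[keep, , drop = FALSE]
  rownames(table$genes) <- NULL
  if (!is.null(table$pvalues)) {
    table$pvalues <- lapply(table$pvalues, function(p) p[keep])
  }
  table$collapsed <- collapsed
  table
}

#' Add the pooled-median offset to all RPKM values
#'
#' The offset equals the median (second quartile) of all RPKM cells, pooled
#' across genes and samples, and is added to every cell. Applying it twice
#' is an error; the offset is recorded on the table.
#'
#' @param table an [expression_table] (offset not yet applied).
#' @return The table with `offset` set and every cell incremented.
#' @export
add_offset <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  if (!is.null(table$offset)) {
    stop_input("offset already applied (offset = %g)", table$offset)
  }
  off <- stats::median(as.numeric(table$rpkm))
  table$rpkm <- table$rpkm + off
  table$offset <- off
  table
}

#' Drop genes below an abundance floor in every condition
#'
#' A gene is retained iff its mean RPKM reaches `min_rpkm` in at least one
#' condition. Operates on raw (pre-offset) values; call before
#' [add_offset()].
#'
#' @param table an [expression_table].
#' @param min_rpkm abundance floor (default 1).
#' @return The filtered table.
#' @export
filter_low_abundance <- function(table, min_rpkm = 1) {
  stopifnot(inherits(table, "expression_table"))
  if (!is.null(table$offset)) {
    stop_input("filter_low_abundance() must run before add_offset()")
  }
  cm <- condition_means(table, raw = TRUE)
  keep <- which(apply(cm, 1L, max) >= min_rpkm)
  subset_rows(table, keep)
}

#' Per-gene fold changes for a treated-vs-reference contrast
#'
#' FC = mean(treated RPKM) / mean(reference RPKM) on offset-added values;
#' the offset must have been applied (it prevents fold-change artifacts from
#' low-abundance transcripts). A gene whose reference mean is zero
#' post-offset (possible only at offset 0) gets `NA` and is flagged.
#'
#' @param table a collapsed [expression_table] with the offset applied.
#' @param contrast `c(treated, reference)` condition labels.
#' @return Data frame with `gene_id`, `fold_change`, `log2_fc` and
#'   `undefined` flag.
#' @export
compute_fold_changes <- function(table, contrast) {
  stopifnot(inherits(table, "expression_table"))
  if (is.null(table$offset)) {
    stop_input("apply add_offset() before computing fold changes")
  }
  if (!table$collapsed) {
    stop_input("collapse_transcripts() first: fold changes are per gene")
  }
  conds <- unique(table$samples$condition)
  miss <- setdiff(contrast, conds)
  if (length(miss)) {
    stop_input("condition(s) not in table: %s", paste(miss, collapse = ", "))
  }
  m_tr <- rowMeans(table$rpkm[, table$samples$condition == contrast[1L],
                              drop = FALSE])
  m_ref <- rowMeans(table$rpkm[, table$samples$condition == contrast[2L],
                               drop = FALSE])
  fc <- ifelse(m_ref > 0, m_tr / m_ref, NA_real_)
  data.frame(gene_id = table$genes$gene_id, fold_change = fc,
             log2_fc = log2(fc), undefined = m_ref == 0,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff its fold change exceeds `fc_threshold` in either
#' direction (strictly: `fc > t` or `fc < 1/t`) and its p-value is strictly
#' below `p_threshold`. P-values come either from a precomputed column
#' (stored under the contrast key) or from the built-in exact conditional
#' negative-binomial test on raw counts ([nb_exact_test()]) with a common
#' method-of-moments dispersion. No multiple-testing correction is applied.
#'
#' @inheritParams compute_fold_changes
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param p_source `"precomputed"` or `"builtin"`.
#' @param dispersion optional common NB dispersion for the built-in test;
#'   estimated from the counts when `NULL`.
#' @return Data frame of class `"deg_result"` with columns `gene_id`,
#'   `fold_change`, `log2_fc`, `p_value`, `is_deg`, `direction`.
#' @export
call_degs <- function(table, contrast, fc_threshold = 1.5, p_threshold = 0.05,
                      p_source = c("precomputed", "builtin"),
                      dispersion = NULL) {
  p_source <- match.arg(p_source)
  stopifnot(fc_threshold >= 1, p_threshold > 0)
  fc <- compute_fold_changes(table, contrast)
  key <- contrast_key(contrast)
  if (p_source == "precomputed") {
    if (is.null(table$pvalues[[key]])) {
      stop_input("no precomputed p-values for contrast '%s' (available: %s)",
                 key, paste(names(table$pvalues) %||% "none", collapse = ", "))
    }
    p <- table$pvalues[[key]]
  } else {
    if (is.null(table$counts)) {
      stop_input("builtin test needs raw counts in the table")
    }
    ia <- which(table$samples$condition == contrast[1L])
    ib <- which(table$samples$condition == contrast[2L])
    if (length(ia) < 2L || length(ib) < 2L) {
      stop_input("builtin test needs >= 2 replicates per group")
    }
    if (is.null(dispersion)) {
      dispersion <- common_dispersion(table$counts, ia, ib)
    }
    p <- vapply(seq_len(nrow(table$counts)), function(g) {
      nb_exact_test(table$counts[g, ia], table$counts[g, ib],
                    dispersion = dispersion)
    }, numeric(1))
  }
  is_deg <- !is.na(fc$fold_change) & !is.na(p) &
    (fc$fold_change > fc_threshold | fc$fold_change < 1 / fc_threshold) &
    p < p_threshold
  direction <- ifelse(fc$fold_change > 1, "up",
                      ifelse(fc$fold_change < 1, "down", NA_character_))
  out <- data.frame(gene_id = fc$gene_id, fold_change = fc$fold_change,
                    log2_fc = fc$log2_fc, p_value = p, is_deg = is_deg,
                    direction = direction, stringsAsFactors = FALSE)
  structure(out, contrast = contrast, fc_threshold = fc_threshold,
            p_threshold = p_threshold, p_source = p_source,
            dispersion = if (p_source == "builtin") dispersion,
            class = c("deg_result", "data.frame"))
}

# method-of-moments common dispersion: per-gene, per-group (var - mean)/mean^2
# averaged over all finite estimates, floored at 1e-6
common_dispersion <- function(counts, idx_a, idx_b, floor = 1e-6) {
  phi_of <- function(idx) {
    m <- rowMeans(counts[, idx, drop = FALSE])
    v <- apply(counts[, idx, drop = FALSE], 1L, stats::var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  phis <- c(phi_of(idx_a), phi_of(idx_b))
  phis <- phis[is.finite(phis)]
  max(floor, if (length(phis)) mean(phis) else floor)
}

#' Exact conditional negative-binomial test for two small count groups
#'
#' Two-sided test of equal means between two groups of non-negative integer
#' counts under a negative-binomial model with a common dispersion.
#' Conditional on the total count, the group-A sum follows the distribution
#' proportional to `dnbinom(s; nA*mu, nA/phi) * dnbinom(T-s; nB*mu, nB/phi)`;
#' the p-value sums the probabilities of all outcomes no more likely than
#' the observed one. A simple small-replicate stand-in for a full empirical
#' Bayes dispersion machinery, sufficient for simulated data; dispersion
#' defaults to the method-of-moments estimate from the two groups, floored
#' at `1e-6` (the Poisson limit).
#'
#' @param counts_a,counts_b non-negative integer count vectors (>= 2 each).
#' @param dispersion optional common NB dispersion.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' nb_exact_test(c(5, 5), c(5, 5))          # 1
#' nb_exact_test(c(100, 110), c(10, 12))    # << 0.01
nb_exact_test <- function(counts_a, counts_b, dispersion = NULL) {
  a <- as.numeric(counts_a); b <- as.numeric(counts_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_input("need at least 2 counts per group")
  }
  if (anyNA(c(a, b)) || any(c(a, b) < 0) || any(c(a, b) != floor(c(a, b)))) {
    stop_input("counts must be non-negative integers")
  }
  na <- length(a); nb <- length(b)
  sa <- sum(a); tot <- sa + sum(b)
  if (tot == 0) return(1)
  if (is.null(dispersion)) {
    dispersion <- common_dispersion(rbind(c(a, b)), seq_len(na),
                                    na + seq_len(nb))
  }
  if (dispersion <= 0) dispersion <- 1e-6
  mu <- tot / (na + nb)
  s <- 0:tot
  lp <- stats::dnbinom(s, size = na / dispersion, mu = na * mu, log = TRUE) +
    stats::dnbinom(tot - s, size = nb / dispersion, mu = nb * mu, log = TRUE)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p <- sum(pr[pr <= pr[sa + 1L] * (1 + 1e-10)])
  min(1, max(p, .Machine$double.xmin))
}
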