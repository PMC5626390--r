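# Integration of peak assignments with DEG results: the two-tier target-gene
# signature and the bound-versus-responsive summary statistics.

sig_members <- function(bound_genes, degs, table, fc_threshold, p_threshold,
                        min_mean_rpkm) {
  responsive <- degs$gene_id[!is.na(degs$fold_change) & !is.na(degs$p_value) &
                               (degs$fold_change > fc_threshold |
                                  degs$fold_change < 1 / fc_threshold) &
                               degs$p_value < p_threshold]
  members <- intersect(bound_genes, responsive)
  if (!is.null(min_mean_rpkm) && min_mean_rpkm > 0) {
    cm <- condition_means(table, raw = TRUE)
    expressed <- table$genes$gene_id[apply(cm, 1L, max) > min_mean_rpkm]
    members <- intersect(members, expressed)
  }
  sort(members)
}

build_signature <- function(members, assignment, degs, tier, thresholds) {
  if (length(members)) {
    asg <- assignment[assignment$gene_id %in% members, , drop = FALSE]
    # best peak = maximum amplitude among assigned peaks; ties -> smallest id
    asg <- asg[order(asg$gene_id, -asg$amplitude, asg$peak_id), , drop = FALSE]
    best <- asg[!duplicated(asg$gene_id), , drop = FALSE]
    best <- best[match(members, best$gene_id), , drop = FALSE]
    di <- match(members, degs$gene_id)
    out <- data.frame(gene_id = members, tier = tier,
                      fold_change = degs$fold_change[di],
                      p_value = degs$p_value[di],
                      direction = degs$direction[di],
                      best_peak_id = best$peak_id,
                      best_amplitude = best$amplitude,
                      relation = best$relation,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(gene_id = character(), tier = character(),
                      fold_change = numeric(), p_value = numeric(),
                      direction = character(), best_peak_id = character(),
                      best_amplitude = numeric(), relation = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, tier = tier, thresholds = thresholds,
            class = c("tf_signature", "data.frame"))
}

check_universes <- function(assignment, degs) {
  if (!length(intersect(unique(assignment$gene_id), degs$gene_id)) &&
      nrow(assignment) && nrow(degs)) {
    stop_input(paste0("assignment and DEG gene universes are disjoint; ",
                      "likely a gene ID-space mismatch"))
  }
}

#' Derive the full target-gene signature
#'
#' A gene enters the full signature iff it is bound (at least one assigned
#' peak from the treated-condition set), transcriptionally responsive
#' (strictly more than `fc_threshold`-fold change in either direction with
#' `p < p_threshold`) and expressed (mean RPKM strictly above
#' `min_mean_rpkm` in at least one condition, computed on pre-offset
#' values). Evidence records the highest-amplitude assigned peak.
#'
#' @param assignment `peak_assignment` built from the treated-condition
#'   peaks.
#' @param degs `deg_result` for the treated-vs-reference contrast.
#' @param table the collapsed [expression_table] the DEGs came from.
#' @param fc_threshold fold-change bound (default 2: "more than twofold").
#' @param p_threshold p-value bound (default 0.05).
#' @param min_mean_rpkm expression floor (default 2); `NULL` or 0 disables.
#' @return A `tf_signature` data frame (tier `"full"`).
#' @export
derive_full_signature <- function(assignment, degs, table, fc_threshold = 2,
                                  p_threshold = 0.05, min_mean_rpkm = 2) {
  stopifnot(inherits(assignment, "peak_assignment"),
            inherits(degs, "deg_result"))
  check_universes(assignment, degs)
  bound <- unique(assignment$gene_id)
  members <- sig_members(bound, degs, table, fc_threshold, p_threshold,
                         min_mean_rpkm)
  build_signature(members, assignment, degs, "full",
                  list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                       min_mean_rpkm = min_mean_rpkm))
}

#' Derive the compact target-gene signature
#'
#' As [derive_full_signature()] but with stricter criteria: binding must be
#' through at least one high-amplitude peak (top-quartile tag count, see
#' [amplitude_quantile_flag()]) and the fold change must exceed
#' `fc_threshold` (default 3: "more than threefold"). At the default
#' thresholds the compact signature is a subset of the full one.
#'
#' @inheritParams derive_full_signature
#' @param amplitude_flags named logical vector from
#'   [amplitude_quantile_flag()] computed on the same peak set that built
#'   `assignment`.
#' @return A `tf_signature` data frame (tier `"compact"`).
#' @export
derive_compact_signature <- function(assignment, degs, table, amplitude_flags,
                                     fc_threshold = 3, p_threshold = 0.05,
                                     min_mean_rpkm = 2) {
  stopifnot(inherits(assignment, "peak_assignment"),
            inherits(degs, "deg_result"), is.logical(amplitude_flags))
  check_universes(assignment, degs)
  miss <- setdiff(unique(assignment$peak_id), names(amplitude_flags))
  if (length(miss)) {
    stop_input(paste0("amplitude_flags lack %d assigned peak(s); compute ",
                      "them on the peak set used for the assignment"),
               length(miss))
  }
  high <- assignment$peak_id %in% names(amplitude_flags)[amplitude_flags]
  bound_high <- unique(assignment$gene_id[high])
  members <- sig_members(bound_high, degs, table, fc_threshold, p_threshold,
                         min_mean_rpkm)
  build_signature(members, assignment, degs, "compact",
                  list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                       min_mean_rpkm = min_mean_rpkm,
                       amplitude_q = attr(amplitude_flags, "q")))
}

#' Bound-versus-responsive summary (donut statistics)
#'
#' Counts and fractions relating factor-bound genes (any assigned peak) and
#' transcriptionally responsive genes (DEGs), with the up/down split among
#' the responsive genes.
#'
#' @param assignment a `peak_assignment`.
#' @param degs a `deg_result` on the same gene universe.
#' @return List of class `"fraction_report"`: `n_bound`, `n_responsive`,
#'   `n_bound_and_responsive`, `frac_bound_that_respond`,
#'   `frac_responsive_that_are_bound`, `n_up`, `n_down`.
#' @export
bound_responsive_fractions <- function(assignment, degs) {
  stopifnot(inherits(assignment, "peak_assignment"),
            inherits(degs, "deg_result"))
  bound <- unique(assignment$gene_id)
  resp <- degs$gene_id[degs$is_deg]
  inter <- intersect(bound, resp)
  up <- sum(degs$is_deg & degs$direction == "up", na.rm = TRUE)
  down <- sum(degs$is_deg & degs$direction == "down", na.rm = TRUE)
  out <- list(n_bound = length(bound), n_responsive = length(resp),
              n_bound_and_responsive = length(inter),
              frac_bound_that_respond =
                if (length(bound)) length(inter) / length(bound) else 0,
              frac_responsive_that_are_bound =
                if (length(resp)) length(inter) / length(resp) else 0,
              n_up = up, n_down = down)
  stopifnot(out$n_bound_and_responsive <= min(out$n_bound, out$n_responsive),
            out$n_up + out$n_down == out$n_responsive)
  structure(out, class = "fraction_report")
}

#' Collapse statistics for a consumed gene set
#'
#' For each member of `gene_set` found in the DEG table, classifies the gene
#' as reduced (fold change below 1), enhanced (above 1) or unchanged.
#' In `"significance"` mode the DEG-style gates apply (fold change beyond
#' `fc_threshold` in the relevant direction and `p < p_threshold`); in
#' `"raw_fc"` mode any deviation from 1 counts. Members absent from the
#' expression universe are counted separately.
#'
#' @param gene_set character vector of gene ids (non-empty).
#' @param degs a `deg_result` (e.g. knockout vs wild type).
#' @param mode `"significance"` or `"raw_fc"`.
#' @param fc_threshold,p_threshold gates for `"significance"` mode.
#' @return List of class `"collapse_stats"`: `n_reduced`, `n_enhanced`,
#'   `n_unchanged`, `n_absent`, plus a per-gene data frame.
#' @export
signature_collapse_stats <- function(gene_set, degs,
                                     mode = c("significance", "raw_fc"),
                                     fc_threshold = 1.5, p_threshold = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(degs, "deg_result"))
  gene_set <- unique(as.character(gene_set))
  if (!length(gene_set)) stop_input("'gene_set' is empty")
  idx <- match(gene_set, degs$gene_id)
  absent <- gene_set[is.na(idx)]
  present <- gene_set[!is.na(idx)]
  fc <- degs$fold_change[idx[!is.na(idx)]]
  p <- degs$p_value[idx[!is.na(idx)]]
  status <- if (mode == "significance") {
    ifelse(!is.na(fc) & fc < 1 / fc_threshold & p < p_threshold, "reduced",
           ifelse(!is.na(fc) & fc > fc_threshold & p < p_threshold,
                  "enhanced", "unchanged"))
  } else {
    ifelse(!is.na(fc) & fc < 1, "reduced",
           ifelse(!is.na(fc) & fc > 1, "enhanced", "unchanged"))
  }
  structure(list(n_reduced = sum(status == "reduced"),
                 n_enhanced = sum(status == "enhanced"),
                 n_unchanged = sum(status == "unchanged"),
                 n_absent = length(absent), mode = mode,
                 per_gene = data.frame(gene_id = present, fold_change = fc,
                                       p_value = p, status = status,
                                       stringsAsFactors = FALSE)),
            class = "collapse_stats")
}
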