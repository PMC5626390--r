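# Compact show methods for the package's result classes.

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(x, 5))
  invisible(x)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks, amplitude range [%.3g, %.3g]\n",
              attr(x, "set_name") %||% "peaks", nrow(x),
              if (nrow(x)) min(x$amplitude) else NA,
              if (nrow(x)) max(x$amplitude) else NA))
  if (nrow(x)) print.data.frame(utils::head(x, 5))
  invisible(x)
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d rows x %d samples (%s)\n",
              nrow(x$rpkm), ncol(x$rpkm),
              paste(unique(x$samples$condition), collapse = ", ")))
  cat(sprintf("  collapsed: %s | offset: %s | counts: %s | p-values: %s\n",
              x$collapsed,
              if (is.null(x$offset)) "none" else format(x$offset),
              !is.null(x$counts),
              paste(names(x$pvalues) %||% "none", collapse = ", ")))
  invisible(x)
}

#' @export
print.deg_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("deg_result %s vs %s: %d/%d DEGs (%d up, %d down)\n",
              ct[1L], ct[2L], sum(x$is_deg), nrow(x),
              sum(x$is_deg & x$direction == "up", na.rm = TRUE),
              sum(x$is_deg & x$direction == "down", na.rm = TRUE)))
  invisible(x)
}

#' @export
print.peak_assignment <- function(x, ...) {
  cat(sprintf(
    "peak_assignment: %d pairs (%d peaks -> %d genes), window %g bp\n",
    nrow(x), length(unique(x$peak_id)), length(unique(x$gene_id)),
    attr(x, "window")))
  invisible(x)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: |A| = %d (%.1f%% shared), |B| = %d (%.1f%% shared)\n",
              x$n_a, 100 * x$frac_shared_a, x$n_b, 100 * x$frac_shared_b))
  invisible(x)
}

#' @export
print.tf_signature <- function(x, ...) {
  cat(sprintf("tf_signature (%s tier): %d genes\n",
              attr(x, "tier") %||% "?", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.tf_signature <- function(object, ...) {
  n <- nrow(object)
  up <- sum(object$direction == "up")
  cat(sprintf("tf_signature (%s): %d genes, %d up / %d down\n",
              attr(object, "tier") %||% "?", n, up, n - up))
  if (n) {
    cat(sprintf("  |log2FC| median %.2f, best amplitude median %.3g\n",
                stats::median(abs(log2(object$fold_change))),
                stats::median(object$best_amplitude)))
  }
  invisible(object)
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf(paste0("bound/responsive: %d bound, %d responsive ",
                     "(%d up, %d down), %d both\n"),
              x$n_bound, x$n_responsive, x$n_up, x$n_down,
              x$n_bound_and_responsive))
  cat(sprintf("  %.1f%% of bound genes respond; %.1f%% of responsive genes are bound\n",
              100 * x$frac_bound_that_respond,
              100 * x$frac_responsive_that_are_bound))
  invisible(x)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: %d set(s), %d permutations\n",
              nrow(x), attr(x, "n_perm")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("sim_truth: %d genes | %d bound, %d responsive ",
                     "(%d down) | true signatures: %d full, %d compact\n"),
              length(x$genes), length(x$bound), length(x$responsive),
              sum(x$direction == "down"), length(x$signature_full),
              length(x$signature_compact)))
  invisible(x)
}

#' @export
print.signature_analysis <- function(x, ...) {
  cat("signature_analysis\n")
  cat(sprintf("  offset %.4g | %d DEGs | %d bound genes\n",
              x$log$offset, x$log$n_degs, x$log$n_bound_genes))
  cat(sprintf("  signatures: %d full, %d compact\n",
              x$log$n_signature_full, x$log$n_signature_compact))
  print(x$fractions)
  invisible(x)
}
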