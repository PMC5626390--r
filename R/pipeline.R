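# End-to-end chain: expression preprocessing -> DEG calling -> peak-to-gene
# assignment -> two-tier signature derivation -> summary statistics ->
# optional condition comparison and gene-set enrichment. Stage-by-stage
# in/out counts are logged so filter survivorship is auditable, and
# write_pipeline_outputs() emits a manifest sufficient to reproduce a run.

#' Run the full signature-derivation pipeline
#'
#' @param genes a [gene_models] set.
#' @param peaks_treated treated-condition [peak_set] (drives binding).
#' @param table an [expression_table] (raw: not collapsed, no offset).
#' @param contrast `c(treated, reference)` condition labels.
#' @param peaks_reference optional reference-condition [peak_set]; when
#'   given, the condition overlap report and gene-association exclusivity
#'   are computed.
#' @param gene_sets optional gene-set collection for enrichment analysis
#'   of the contrast ranking.
#' @param window TSS assignment window (bp).
#' @param min_rpkm abundance filter floor.
#' @param deg_fc,deg_p DEG thresholds.
#' @param full_fc,compact_fc,sig_p,min_mean_rpkm signature thresholds; the
#'   compact fold-change threshold must be at least the full one (subset
#'   guard rail).
#' @param amplitude_q high-amplitude quantile.
#' @param p_source `"builtin"` or `"precomputed"` (see [call_degs()]).
#' @param n_perm,seed enrichment permutation controls (seed required when
#'   `gene_sets` is given).
#' @return List of class `"signature_analysis"` with elements `table`,
#'   `degs`, `assignment`, `amplitude_flags`, `signature_full`,
#'   `signature_compact`, `fractions`, `overlap`, `exclusivity`, `gsea`,
#'   `log`, `params`.
#' @export
run_signature_pipeline <- function(genes, peaks_treated, table, contrast,
                                   peaks_reference = NULL, gene_sets = NULL,
                                   window = 50000, min_rpkm = 1,
                                   deg_fc = 1.5, deg_p = 0.05,
                                   full_fc = 2, compact_fc = 3,
                                   sig_p = 0.05, min_mean_rpkm = 2,
                                   amplitude_q = 0.75,
                                   p_source = c("builtin", "precomputed"),
                                   n_perm = 1000, seed = NULL) {
  p_source <- match.arg(p_source)
  for (th in c(window = window, deg_fc = deg_fc, deg_p = deg_p,
               full_fc = full_fc, compact_fc = compact_fc, sig_p = sig_p)) {
    if (!is.numeric(th) || th <= 0) stop_input("thresholds must be positive")
  }
  if (compact_fc < full_fc) {
    stop_input(paste0("compact_fc (%g) must be at least full_fc (%g): the ",
                      "compact signature is a subset of the full one"),
               compact_fc, full_fc)
  }
  log <- list(n_transcripts_in = nrow(table$rpkm))
  tb <- collapse_transcripts(table)
  log$n_genes_collapsed <- nrow(tb$rpkm)
  tb <- filter_low_abundance(tb, min_rpkm = min_rpkm)
  log$n_genes_filtered <- nrow(tb$rpkm)
  tb <- add_offset(tb)
  log$offset <- tb$offset
  degs <- call_degs(tb, contrast, fc_threshold = deg_fc, p_threshold = deg_p,
                    p_source = p_source)
  log$n_degs <- sum(degs$is_deg)
  assignment <- assign_peaks_to_genes(peaks_treated, genes, window = window)
  log$n_assigned_pairs <- nrow(assignment)
  log$n_bound_genes <- length(unique(assignment$gene_id))
  flags <- amplitude_quantile_flag(peaks_treated, q = amplitude_q)
  sig_full <- derive_full_signature(assignment, degs, tb,
                                    fc_threshold = full_fc,
                                    p_threshold = sig_p,
                                    min_mean_rpkm = min_mean_rpkm)
  sig_compact <- derive_compact_signature(assignment, degs, tb, flags,
                                          fc_threshold = compact_fc,
                                          p_threshold = sig_p,
                                          min_mean_rpkm = min_mean_rpkm)
  log$n_signature_full <- nrow(sig_full)
  log$n_signature_compact <- nrow(sig_compact)
  fractions <- bound_responsive_fractions(assignment, degs)
  overlap <- exclusivity <- NULL
  if (!is.null(peaks_reference)) {
    overlap <- classify_condition_overlap(peaks_treated, peaks_reference)
    assignment_ref <- assign_peaks_to_genes(peaks_reference, genes,
                                            window = window)
    exclusivity <- gene_association_exclusivity(assignment, assignment_ref)
  }
  enr <- NULL
  if (!is.null(gene_sets)) {
    if (is.null(seed)) stop_input("'seed' is required when running GSEA")
    ranked <- rank_genes(degs)
    enr <- gsea(ranked, gene_sets, n_perm = n_perm, seed = seed)
  }
  params <- list(contrast = contrast, window = window, min_rpkm = min_rpkm,
                 deg_fc = deg_fc, deg_p = deg_p, full_fc = full_fc,
                 compact_fc = compact_fc, sig_p = sig_p,
                 min_mean_rpkm = min_mean_rpkm, amplitude_q = amplitude_q,
                 p_source = p_source, n_perm = n_perm, seed = seed)
  structure(list(table = tb, degs = degs, assignment = assignment,
                 amplitude_flags = flags, signature_full = sig_full,
                 signature_compact = sig_compact, fractions = fractions,
                 overlap = overlap, exclusivity = exclusivity, gsea = enr,
                 log = log, params = params),
            class = "signature_analysis")
}

#' Write pipeline outputs and a reproducibility manifest
#'
#' Emits `degs.tsv`, `assignment.tsv`, `signature_full.tsv`,
#' `signature_compact.tsv`, `fractions.json`, optional `overlap.json` and
#' `gsea.tsv`, plus `manifest.json` recording every parameter actually
#' used, the seed, the package version, the stage log and the md5
#' checksums of every written file. No timestamps: two runs with the same
#' inputs produce byte-identical manifests.
#'
#' @param result a `signature_analysis`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "signature_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(obj, name, fun = write_report) {
    p <- file.path(dir, name)
    fun(obj, p)
    paths[[name]] <<- p
  }
  wr(as.data.frame(result$degs), "degs.tsv")
  wr(as.data.frame(result$assignment), "assignment.tsv")
  wr(result$signature_full, "signature_full.tsv", write_signature)
  wr(result$signature_compact, "signature_compact.tsv", write_signature)
  wr(result$fractions, "fractions.json")
  if (!is.null(result$overlap)) {
    ov <- result$overlap
    ov$flags_a <- NULL; ov$flags_b <- NULL
    wr(ov, "overlap.json")
  }
  if (!is.null(result$exclusivity)) wr(result$exclusivity, "exclusivity.json")
  if (!is.null(result$gsea)) wr(as.data.frame(result$gsea), "gsea.tsv")
  manifest <- list(parameters = result$params, log = result$log,
                   package_version =
                     as.character(utils::packageVersion("tfsig")),
                   files = as.list(tools::md5sum(unname(unlist(paths)))))
  names(manifest$files) <- names(paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
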