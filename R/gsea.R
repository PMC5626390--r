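# Weighted Kolmogorov-Smirnov gene-set enrichment with a gene-set
# permutation null. With 2-3 replicates per group a phenotype permutation
# is degenerate, so the null is built from random same-size gene sets drawn
# from the ranked universe.

#' Rank genes by a contrast metric
#'
#' Produces a descending ranked list with deterministic lexicographic
#' tie-breaking. `x` may be a `deg_result` (preferred) or an
#' [expression_table] plus a contrast.
#'
#' @param x a `deg_result` or [expression_table].
#' @param metric `"log2fc"` or `"signed_log10p"`
#'   (`sign(log2fc) * -log10(p)`).
#' @param contrast for the table method, `c(treated, reference)`.
#' @param ... passed between methods.
#' @return Data frame of class `"ranked_list"` with columns `gene_id`,
#'   `metric`, in descending metric order.
#' @export
rank_genes <- function(x, ...) UseMethod("rank_genes")

#' @rdname rank_genes
#' @export
rank_genes.deg_result <- function(x, metric = c("log2fc", "signed_log10p"),
                                  ...) {
  metric <- match.arg(metric)
  keep <- !is.na(x$fold_change)
  if (!any(keep)) stop_input("no genes with defined fold change to rank")
  val <- if (metric == "log2fc") x$log2_fc[keep] else {
    sign(x$log2_fc[keep]) * -log10(pmax(x$p_value[keep],
                                        .Machine$double.xmin))
  }
  out <- data.frame(gene_id = x$gene_id[keep], metric = val,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metric = metric, class = c("ranked_list", "data.frame"))
}

#' @rdname rank_genes
#' @export
rank_genes.expression_table <- function(x, contrast,
                                        metric = c("log2fc",
                                                   "signed_log10p"), ...) {
  metric <- match.arg(metric)
  fc <- compute_fold_changes(x, contrast)
  p <- x$pvalues[[contrast_key(contrast)]]
  if (metric == "signed_log10p" && is.null(p)) {
    stop_input("metric 'signed_log10p' needs precomputed p-values")
  }
  fake <- data.frame(gene_id = fc$gene_id, fold_change = fc$fold_change,
                     log2_fc = fc$log2_fc,
                     p_value = p %||% rep(NA_real_, nrow(fc)),
                     stringsAsFactors = FALSE)
  class(fake) <- c("deg_result", "data.frame")
  rank_genes(fake, metric = metric)
}

# running-sum machinery shared by enrichment_score() and the permutations.
# hit increments are |metric|^p normalised to 1 over hits; miss decrements
# are 1/(N - Nh); ES is the signed extremum of the running sum.
es_core <- function(metric, hit, weight_p) {
  n <- length(metric)
  nh <- sum(hit)
  w <- abs(metric[hit])^weight_p
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  step <- numeric(n)
  step[hit] <- inc
  if (n > nh) step[!hit] <- -1 / (n - nh)
  run <- cumsum(step)
  i <- which.max(abs(run))
  list(es = run[i], run = run, arg = i, nh = nh)
}

#' Enrichment score of a gene set in a ranked list
#'
#' @param ranked a `ranked_list` from [rank_genes()].
#' @param gene_set character vector of gene ids; must intersect the list.
#' @param weight_p exponent on |metric| for hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @return List of class `"es_result"`: `es` in \[-1, 1\], `running_sum`,
#'   `leading_edge` (gene ids), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$gene_id %in% gene_set
  if (!any(hit)) stop_input("gene set does not intersect the ranked list")
  core <- es_core(ranked$metric, hit, weight_p)
  le <- if (core$es >= 0) {
    ranked$gene_id[hit & seq_along(hit) <= core$arg]
  } else {
    ranked$gene_id[hit & seq_along(hit) >= core$arg]
  }
  structure(list(es = core$es, running_sum = core$run,
                 leading_edge = le, n_hits = core$nh),
            class = "es_result")
}

#' Gene-set enrichment analysis with a permutation null
#'
#' For every set in `collection`, computes the weighted enrichment score,
#' normalises it against a null of `n_perm` random same-size gene sets
#' drawn from the ranked universe (NES = ES divided by the mean |null ES|
#' of matching sign), an add-one-smoothed nominal p-value over same-sign
#' null scores, and an FDR q-value by pooling observed and null NES of
#' matching sign. Fully reproducible for a given `seed`; sets sharing a
#' size share the same null draws.
#'
#' @param ranked a `ranked_list`.
#' @param collection named list of gene sets (see [read_gene_sets()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed (required).
#' @param weight_p hit-weight exponent (default 1).
#' @return Data frame of class `"gsea_result"`: `set`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `leading_edge_n`.
#' @export
gsea <- function(ranked, collection, n_perm = 1000, seed, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (missing(seed)) stop_input("'seed' is required for the permutation null")
  if (n_perm < 100) stop_input("'n_perm' must be at least 100")
  if (is.null(names(collection)) || any(names(collection) == "")) {
    stop_input("'collection' must be a named list of gene sets")
  }
  n <- nrow(ranked)
  universe <- ranked$gene_id
  restricted <- lapply(collection, intersect, x = universe)
  too_big <- lengths(collection) > n
  if (any(too_big)) {
    stop_input("gene set(s) larger than the ranked universe: %s",
               paste(names(collection)[too_big], collapse = ", "))
  }
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning("skipping set(s) with no genes in the ranked list: ",
            paste(names(collection)[empty], collapse = ", "), call. = FALSE)
  }
  keep <- names(collection)[!empty]
  sizes <- lengths(restricted[keep])

  res <- data.frame(set = keep, size = unname(sizes), es = NA_real_,
                    nes = NA_real_, p_value = NA_real_, q_value = NA_real_,
                    leading_edge_n = NA_integer_, stringsAsFactors = FALSE)
  if (!nrow(res)) {
    return(structure(res, class = c("gsea_result", "data.frame")))
  }
  metric <- ranked$metric
  for (i in seq_len(nrow(res))) {
    e <- enrichment_score(ranked, restricted[[res$set[i]]], weight_p)
    res$es[i] <- e$es
    res$leading_edge_n[i] <- length(e$leading_edge)
  }
  # one shared null per distinct set size
  null_by_size <- with_seed(seed, {
    lapply(stats::setNames(nm = sort(unique(res$size))), function(k) {
      vapply(seq_len(n_perm), function(j) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        es_core(metric, hit, weight_p)$es
      }, numeric(1))
    })
  })
  null_nes_pool <- numeric(0)
  for (k in names(null_by_size)) {
    nul <- null_by_size[[k]]
    pos_mean <- mean(nul[nul > 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    null_nes_pool <- c(null_nes_pool,
                       ifelse(nul > 0, nul / pos_mean, nul / neg_mean))
    sel <- res$size == as.numeric(k)
    for (i in which(sel)) {
      es <- res$es[i]
      same <- if (es >= 0) nul[nul >= 0] else nul[nul < 0]
      b <- sum(abs(same) >= abs(es))
      res$p_value[i] <- (b + 1) / (length(same) + 1)
      denom <- if (es >= 0) pos_mean else neg_mean
      res$nes[i] <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    }
  }
  null_nes_pool <- null_nes_pool[is.finite(null_nes_pool)]
  for (i in seq_len(nrow(res))) {
    nes <- res$nes[i]
    if (!is.finite(nes)) next
    if (nes >= 0) {
      frac_null <- mean(null_nes_pool[null_nes_pool >= 0] >= nes)
      frac_obs <- mean(res$nes[res$nes >= 0] >= nes, na.rm = TRUE)
    } else {
      frac_null <- mean(null_nes_pool[null_nes_pool < 0] <= nes)
      frac_obs <- mean(res$nes[res$nes < 0] <= nes, na.rm = TRUE)
    }
    res$q_value[i] <- min(1, frac_null / max(frac_obs, .Machine$double.eps))
  }
  structure(res, n_perm = n_perm, seed = seed, weight_p = weight_p,
            class = c("gsea_result", "data.frame"))
}
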