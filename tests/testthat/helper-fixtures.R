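# Shared fixture builders and independent oracles used across test files.

# all-pairs brute-force peak-to-gene assignment (the independent oracle for
# the interval-index implementation); returns sorted "peak\rgene" keys
brute_force_assign <- function(peaks, genes, window = 50000) {
  keys <- character()
  for (i in seq_len(nrow(peaks))) {
    same <- genes$chrom == peaks$chrom[i]
    if (!any(same)) next
    g <- genes[same, , drop = FALSE]
    body <- peaks$start[i] < g$end & g$start < peaks$end[i]
    dmin <- ifelse(peaks$end[i] - 1 < g$tss, g$tss - (peaks$end[i] - 1),
                   ifelse(peaks$start[i] > g$tss, peaks$start[i] - g$tss, 0))
    hit <- body | dmin < window
    if (any(hit)) {
      keys <- c(keys, paste(peaks$peak_id[i], g$gene_id[hit], sep = "\r"))
    }
  }
  sort(keys)
}

assignment_keys <- function(assignment) {
  sort(paste(assignment$peak_id, assignment$gene_id, sep = "\r"))
}

random_instance <- function(n_peaks = 200, n_genes = 50, span = 5e6,
                            chroms = c("c1", "c2")) {
  gs <- sort(sample.int(span, n_genes))
  genes <- gene_models(sprintf("g%03d", seq_len(n_genes)),
                       sample(chroms, n_genes, replace = TRUE),
                       sample(c("+", "-"), n_genes, replace = TRUE),
                       gs, gs + sample(2000:30000, n_genes, replace = TRUE))
  ps <- sample.int(span, n_peaks)
  peaks <- peak_set(sample(chroms, n_peaks, replace = TRUE), ps,
                    ps + sample(100:1500, n_peaks, replace = TRUE),
                    amplitude = runif(n_peaks, 0, 100))
  list(peaks = peaks, genes = genes)
}

# build a small expression table from an RPKM matrix; condition labels are
# taken from column-name prefixes "<condition>__<rep>"
tiny_table <- function(rpkm, counts = NULL, pvalues = NULL,
                       gene_id = rownames(rpkm), transcript_id = gene_id) {
  samples <- data.frame(sample = colnames(rpkm),
                        condition = sub("__[^_]*$", "", colnames(rpkm)),
                        stringsAsFactors = FALSE)
  expression_table(rpkm, samples = samples,
                   genes = data.frame(gene_id = gene_id,
                                      transcript_id = transcript_id,
                                      stringsAsFactors = FALSE),
                   counts = counts, pvalues = pvalues)
}

mat <- function(..., ncol, cn) {
  m <- matrix(c(...), ncol = ncol, byrow = TRUE)
  colnames(m) <- cn
  m
}

# hand-made deg_result for unit tests of downstream set logic
fake_degs <- function(gene_id, fold_change, p_value,
                      fc_threshold = 1.5, p_threshold = 0.05) {
  is_deg <- (fold_change > fc_threshold | fold_change < 1 / fc_threshold) &
    p_value < p_threshold
  out <- data.frame(gene_id = gene_id, fold_change = fold_change,
                    log2_fc = log2(fold_change), p_value = p_value,
                    is_deg = is_deg,
                    direction = ifelse(fold_change > 1, "up",
                                       ifelse(fold_change < 1, "down",
                                              NA_character_)),
                    stringsAsFactors = FALSE)
  structure(out, contrast = c("treated", "reference"),
            fc_threshold = fc_threshold, p_threshold = p_threshold,
            class = c("deg_result", "data.frame"))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# independent conditional NB enumeration: group-sum pmfs by explicit
# convolution of per-library pmfs (no closed-form sum shortcut)
nb_cond_pvalue_oracle <- function(a, b, phi) {
  tot <- sum(a) + sum(b)
  lib_pmf <- function(mu) dnbinom(0:tot, size = 1 / phi, mu = mu)
  conv <- function(p, q) {
    out <- numeric(tot + 1)
    for (k in 0:tot) {
      out[k + 1] <- sum(p[seq_len(k + 1)] * q[k + 1 - seq_len(k + 1) + 1])
    }
    out
  }
  mu <- tot / (length(a) + length(b))
  pa <- Reduce(conv, replicate(length(a), lib_pmf(mu), simplify = FALSE))
  pb <- Reduce(conv, replicate(length(b), lib_pmf(mu), simplify = FALSE))
  joint <- pa * rev(pb)
  joint <- joint / sum(joint)
  obs <- joint[sum(a) + 1]
  sum(joint[joint <= obs * (1 + 1e-10)])
}
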