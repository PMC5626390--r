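# Synthetic genomes, peak sets and expression tables with planted ground
# truth. The generator exists so every pipeline stage - and the end-to-end
# signature derivation - can be validated against a known answer without
# any external data. Its defaults define the simulation study conditions;
# see the methods vignette for the rationale behind each choice.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, validated. Counts must be
#' non-negative, probabilities in \[0, 1\], and a `seed` is mandatory:
#' every downstream `simulate_*` step is fully deterministic given the
#' config (each stage uses its own child seed, so stages can be re-run
#' independently).
#'
#' @param seed master RNG seed (required).
#' @param n_genes number of genes.
#' @param gene_length,gene_spacing genomic span per gene and minimum gap
#'   between genes, bp.
#' @param chrom_sizes named numeric vector of chromosome sizes, bp.
#' @param transcript_length effective transcript length used for RPKM, bp.
#' @param n_bound,n_responsive planted set sizes.
#' @param overlap_rho enrichment of responsive genes among bound genes
#'   (sampling-weight ratio; 1 = independent, `Inf` forces
#'   responsive within bound).
#' @param lfc_min,lfc_meanlog,lfc_sdlog planted |log2 fold change| =
#'   `lfc_min` + a lognormal draw.
#' @param frac_down fraction of responsive genes that are down-regulated
#'   (default 0.6, mirroring a negatively-regulated majority).
#' @param mu_meanlog_regulated,mu_sdlog_regulated lognormal baseline NB
#'   mean for bound/responsive genes.
#' @param mu_meanlog_background,mu_sdlog_background same for background
#'   genes.
#' @param frac_silent fraction of background genes that are near-silent.
#' @param mu_silent NB mean of near-silent genes.
#' @param dispersion common NB dispersion (> 0).
#' @param n_rep replicates per condition (>= 2).
#' @param cond_reference,cond_treated condition labels.
#' @param peak_width peak width, bp.
#' @param peaks_per_bound_extra extra peaks per bound gene are
#'   Poisson(`peaks_per_bound_extra`) on top of the guaranteed one.
#' @param tss_dist_sd s.d. of the normal TSS-offset of bound-gene peaks
#'   (truncated to the assignment window).
#' @param amp_meanlog_bound,amp_sdlog_bound lognormal amplitude of
#'   bound-gene peaks.
#' @param amp_meanlog_background,amp_sdlog_background same for background
#'   peaks.
#' @param frac_high_amp fraction of bound genes designated high-amplitude.
#' @param amp_high_factor amplitude multiplier for those genes.
#' @param treated_amp_factor extra amplitude factor for treated-condition
#'   peaks.
#' @param n_background_peaks background peaks per condition.
#' @param shared_frac_treated probability a treated peak is also present
#'   (as an overlapping twin) in the reference condition.
#' @param shared_frac_exvivo target fraction of reference-condition peaks
#'   that are shared with the treated condition.
#' @param assignment_window peak-to-gene TSS window, bp.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_genes = 1000,
                       gene_length = 10000,
                       gene_spacing = 10000,
                       chrom_sizes = c(chr1 = 3e8),
                       transcript_length = 1000,
                       n_bound = 120,
                       n_responsive = 100,
                       overlap_rho = 4,
                       lfc_min = 2,
                       lfc_meanlog = log(0.25),
                       lfc_sdlog = 0.4,
                       frac_down = 0.6,
                       mu_meanlog_regulated = log(200),
                       mu_sdlog_regulated = 0.5,
                       mu_meanlog_background = log(40),
                       mu_sdlog_background = 1,
                       frac_silent = 0.35,
                       mu_silent = 0.05,
                       dispersion = 0.05,
                       n_rep = 3,
                       cond_reference = "exvivo",
                       cond_treated = "il15",
                       peak_width = 400,
                       peaks_per_bound_extra = 0.5,
                       tss_dist_sd = 15000,
                       amp_meanlog_bound = log(50),
                       amp_sdlog_bound = 0.6,
                       amp_meanlog_background = log(10),
                       amp_sdlog_background = 0.6,
                       frac_high_amp = 0.3,
                       amp_high_factor = 4,
                       treated_amp_factor = 1.5,
                       n_background_peaks = 30,
                       shared_frac_treated = 0.25,
                       shared_frac_exvivo = 0.5,
                       assignment_window = 50000) {
  if (missing(seed)) stop_input("'seed' is mandatory in sim_config()")
  cfg <- as.list(environment())
  for (nm in c("n_genes", "n_bound", "n_responsive", "n_rep",
               "n_background_peaks")) {
    check_count(cfg[[nm]], nm)
  }
  for (nm in c("frac_down", "frac_silent", "frac_high_amp",
               "shared_frac_treated", "shared_frac_exvivo")) {
    check_prob(cfg[[nm]], nm)
  }
  if (cfg$dispersion <= 0) stop_input("'dispersion' must be positive")
  if (cfg$n_bound > cfg$n_genes || cfg$n_responsive > cfg$n_genes) {
    stop_input("planted set sizes cannot exceed n_genes")
  }
  if (!(is.numeric(cfg$overlap_rho) && (cfg$overlap_rho > 0))) {
    stop_input("'overlap_rho' must be positive (possibly Inf)")
  }
  if (is.null(names(cfg$chrom_sizes))) {
    names(cfg$chrom_sizes) <- paste0("chr", seq_along(cfg$chrom_sizes))
  }
  if (cfg$n_genes > 0 &&
      cfg$n_genes * (cfg$gene_length + cfg$gene_spacing) >
      sum(cfg$chrom_sizes)) {
    stop_input("gene footprint (%d x %g bp) does not fit the chromosomes",
               cfg$n_genes, cfg$gene_length + cfg$gene_spacing)
  }
  structure(cfg, class = "sim_config")
}

#' Preset simulation configurations
#'
#' `"strong_effect"`: 1000 genes, 120 bound, 100 responsive,
#' |log2FC| >= 2, 3 replicates - the planted-signature recovery setting.
#' `"nk_cytokine"`: 4000 genes, 1000 bound, 400 responsive with the
#' bound/responsive overlap tuned so that roughly 20 % of bound genes are
#' responsive and roughly half of responsive genes are bound, a 60 %
#' down-regulated majority, and condition-sharing set so that about a
#' quarter of treated peaks and half of reference peaks are shared.
#'
#' @param name preset name.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("strong_effect", "nk_cytokine"), seed, ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- if (name == "nk_cytokine") {
    list(n_genes = 4000, chrom_sizes = c(chr1 = 1.2e9), n_bound = 1000,
         n_responsive = 400, overlap_rho = 3, lfc_min = 1,
         n_background_peaks = 200)
  } else {
    list()
  }
  args <- c(list(seed = seed), utils::modifyList(base, over))
  do.call(sim_config, args)
}

sim_gene_ids <- function(config) {
  if (config$n_genes == 0L) return(character())
  sprintf("g%0*d", max(4L, nchar(config$n_genes)), seq_len(config$n_genes))
}

#' Plant the simulation ground truth
#'
#' Samples the bound gene set, the responsive gene set (with bound genes
#' over-weighted by `overlap_rho`), per-gene true log2 fold changes and
#' directions, the high-amplitude designation among bound genes, and the
#' implied true signatures: full = bound genes with |log2FC| above the
#' twofold threshold, compact = high-amplitude bound genes above the
#' threefold threshold.
#'
#' @param config a [sim_config].
#' @return List of class `"sim_truth"`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  with_seed(child_seed(config$seed, 2), {
    bound <- sort(sample(ids, config$n_bound))
    if (is.infinite(config$overlap_rho)) {
      if (config$n_responsive > config$n_bound) {
        stop_input("overlap_rho = Inf needs n_responsive <= n_bound")
      }
      responsive <- sort(sample(bound, config$n_responsive))
    } else {
      w <- ifelse(ids %in% bound, config$overlap_rho, 1)
      responsive <- sort(sample(ids, config$n_responsive, prob = w))
    }
    mag <- config$lfc_min +
      stats::rlnorm(config$n_responsive, config$lfc_meanlog, config$lfc_sdlog)
    down <- stats::runif(config$n_responsive) < config$frac_down
    log2fc <- stats::setNames(ifelse(down, -mag, mag), responsive)
    n_high <- round(config$frac_high_amp * length(bound))
    high <- sort(sample(bound, n_high))
    sig_full <- sort(intersect(bound, responsive[mag > log2(2)]))
    sig_compact <- sort(intersect(high, responsive[mag > log2(3)]))
    structure(list(genes = ids, bound = bound, responsive = responsive,
                   log2fc = log2fc,
                   direction = stats::setNames(
                     ifelse(down, "down", "up"), responsive),
                   high_amp_bound = high,
                   signature_full = sig_full,
                   signature_compact = sig_compact),
              class = "sim_truth")
  })
}

#' Write / read simulation truth as JSON
#'
#' The truth round-trips exactly: `read_truth(write_truth(x, f))` equals
#' `x` field for field.
#'
#' @param truth a `sim_truth`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- unclass(truth)
  # named vectors become JSON objects so names survive the round trip
  x$log2fc <- as.list(x$log2fc)
  x$direction <- as.list(x$direction)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$log2fc <- unlist(x$log2fc) %||% stats::setNames(numeric(), character())
  x$direction <- unlist(x$direction) %||%
    stats::setNames(character(), character())
  for (nm in c("genes", "bound", "responsive", "high_amp_bound",
               "signature_full", "signature_compact")) {
    x[[nm]] <- as.character(x[[nm]] %||% character())
  }
  structure(x[c("genes", "bound", "responsive", "log2fc", "direction",
                "high_amp_bound", "signature_full", "signature_compact")],
            class = "sim_truth")
}

#' Simulate non-overlapping gene models
#'
#' Genes are packed into chromosome slots with at least `gene_spacing` bp
#' between consecutive genes, random within-slot jitter and random strands.
#' Deterministic under the config seed; an infeasible packing is an error.
#'
#' @param config a [sim_config].
#' @return A [gene_models] set of `n_genes` genes.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  if (!length(ids)) {
    return(gene_models(character(), character(), character(), numeric(),
                       numeric()))
  }
  sizes <- config$chrom_sizes
  # allocate genes to chromosomes proportionally to size
  alloc <- floor(config$n_genes * sizes / sum(sizes))
  rem <- config$n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  foot <- config$gene_length + config$gene_spacing
  if (any(alloc * foot > sizes)) {
    stop_input("gene packing infeasible on chromosome '%s'",
               names(sizes)[which(alloc * foot > sizes)[1L]])
  }
  with_seed(child_seed(config$seed, 1), {
    chrom <- rep(names(sizes), alloc)
    start <- numeric(config$n_genes)
    k <- 0L
    for (cc in names(sizes)) {
      n_c <- alloc[[cc]]
      if (n_c == 0L) next
      slot <- floor(sizes[[cc]] / n_c)
      jitter_max <- slot - foot
      jit <- if (jitter_max > 0) {
        sample.int(jitter_max + 1L, n_c, replace = TRUE) - 1L
      } else rep(0L, n_c)
      start[k + seq_len(n_c)] <- (seq_len(n_c) - 1L) * slot + jit
      k <- k + n_c
    }
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gene_models(ids, chrom, strand, start, start + config$gene_length)
  })
}

overlaps_any <- function(chrom, start, end, other) {
  if (nrow(other) == 0L) return(rep(FALSE, length(chrom)))
  lv <- unique(c(chrom, other$chrom))
  GenomicRanges::countOverlaps(
    as_granges0(chrom, start, end, lv),
    as_granges0(other$chrom, other$start, other$end, lv)) > 0
}

#' Simulate condition peak sets with planted binding
#'
#' Every bound gene receives at least one treated-condition peak whose
#' whole extent lies within the assignment window of its TSS, so every
#' planted bound gene is recovered by [assign_peaks_to_genes()] by
#' construction. Each treated peak (bound-gene or background) gains an
#' overlapping reference-condition twin with probability
#' `shared_frac_treated` (shifted by less than half the peak width);
#' reference-only peaks are added, placed disjoint from every treated
#' peak, so that the reference-side shared fraction matches
#' `shared_frac_exvivo`. Treated amplitudes are scaled by
#' `treated_amp_factor`.
#'
#' @param genes a [gene_models] set.
#' @param truth a `sim_truth` with `truth$bound` drawn from `genes`.
#' @param config the [sim_config].
#' @return List with [peak_set]s `treated` and `reference` and a
#'   `provenance` data frame (`peak_id`, `condition`, `class`, `gene_id`,
#'   `twin_of`).
#' @export
simulate_peaks <- function(genes, truth, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (!all(truth$bound %in% genes$gene_id)) {
    stop_input("truth$bound contains genes absent from the gene models")
  }
  w <- config$assignment_window
  pw <- config$peak_width
  if (w + pw >= min(config$chrom_sizes)) {
    stop_input("assignment window (%g bp) inconsistent with chromosome sizes",
               w)
  }
  with_seed(child_seed(config$seed, 3), {
    gi <- match(truth$bound, genes$gene_id)
    n_extra <- stats::rpois(length(gi), config$peaks_per_bound_extra)
    gene_rep <- rep(gi, 1L + n_extra)
    n_bp <- length(gene_rep)
    # centre offset truncated so the whole peak stays inside the TSS window
    max_off <- w - pw - 1
    off <- pmin(pmax(round(stats::rnorm(n_bp, 0, config$tss_dist_sd)),
                     -max_off), max_off)
    centre <- genes$tss[gene_rep] + off
    csize <- config$chrom_sizes[genes$chrom[gene_rep]]
    centre <- pmin(pmax(centre, ceiling(pw / 2)), csize - ceiling(pw / 2))
    b_start <- centre - floor(pw / 2)
    b_chrom <- genes$chrom[gene_rep]
    is_high <- genes$gene_id[gene_rep] %in% truth$high_amp_bound
    b_amp <- stats::rlnorm(n_bp,
                           config$amp_meanlog_bound +
                             log(config$amp_high_factor) * is_high,
                           config$amp_sdlog_bound)
    # uniform background peaks for the treated condition
    n_bg <- config$n_background_peaks
    bg_chrom <- sample(names(config$chrom_sizes), n_bg, replace = TRUE,
                       prob = config$chrom_sizes / sum(config$chrom_sizes))
    bg_start <- floor(stats::runif(n_bg, 0, config$chrom_sizes[bg_chrom] - pw))
    bg_amp <- stats::rlnorm(n_bg, config$amp_meanlog_background,
                            config$amp_sdlog_background)
    tr_chrom <- c(b_chrom, bg_chrom)
    tr_start <- c(b_start, bg_start)
    tr_amp <- c(b_amp, bg_amp) * config$treated_amp_factor
    tr_class <- c(rep("bound", n_bp), rep("background", n_bg))
    tr_gene <- c(genes$gene_id[gene_rep], rep(NA_character_, n_bg))
    n_tr <- length(tr_start)
    tr_id <- sprintf("tpk_%05d", seq_len(n_tr))
    treated <- peak_set(tr_chrom, tr_start, tr_start + pw, tr_id, tr_amp,
                        name = config$cond_treated)
    # reference twins: shifted by < half the width so overlap is guaranteed
    twin <- stats::runif(n_tr) < config$shared_frac_treated
    n_twin <- sum(twin)
    shift_max <- max(1L, floor(pw / 2) - 1L)
    shift <- sample(seq(-shift_max, shift_max), n_twin, replace = TRUE)
    rf_chrom <- tr_chrom[twin]
    rf_start <- pmax(0, tr_start[twin] + shift)
    rf_amp <- c(b_amp, bg_amp)[twin]
    rf_class <- rep("shared_twin", n_twin)
    rf_gene <- tr_gene[twin]
    rf_twin_of <- tr_id[twin]
    # reference-only peaks, placed disjoint from every treated peak
    n_ref_only <- if (n_twin > 0 && config$shared_frac_exvivo > 0) {
      round(n_twin * (1 / config$shared_frac_exvivo - 1))
    } else {
      config$n_background_peaks
    }
    if (n_ref_only > 0) {
      ro_chrom <- character(n_ref_only)
      ro_start <- numeric(n_ref_only)
      near_gene <- stats::runif(n_ref_only) < 0.5 & nrow(genes) > 0
      for (j in seq_len(n_ref_only)) {
        for (try in 1:200) {
          if (near_gene[j]) {
            g <- sample.int(nrow(genes), 1L)
            cand_chrom <- genes$chrom[g]
            cand_start <- genes$tss[g] +
              min(max(round(stats::rnorm(1, 0, config$tss_dist_sd)),
                      -max_off), max_off) - floor(pw / 2)
            cand_start <- min(max(cand_start, 0),
                              config$chrom_sizes[cand_chrom] - pw)
          } else {
            cand_chrom <- sample(names(config$chrom_sizes), 1L,
                                 prob = config$chrom_sizes /
                                   sum(config$chrom_sizes))
            cand_start <- floor(stats::runif(
              1, 0, config$chrom_sizes[cand_chrom] - pw))
          }
          if (!overlaps_any(cand_chrom, cand_start, cand_start + pw,
                            treated)) break
        }
        ro_chrom[j] <- cand_chrom
        ro_start[j] <- cand_start
      }
      ro_amp <- stats::rlnorm(n_ref_only, config$amp_meanlog_background,
                              config$amp_sdlog_background)
      rf_chrom <- c(rf_chrom, ro_chrom)
      rf_start <- c(rf_start, ro_start)
      rf_amp <- c(rf_amp, ro_amp)
      rf_class <- c(rf_class, rep("reference_only", n_ref_only))
      rf_gene <- c(rf_gene, rep(NA_character_, n_ref_only))
      rf_twin_of <- c(rf_twin_of, rep(NA_character_, n_ref_only))
    }
    rf_id <- sprintf("rpk_%05d", seq_along(rf_start))
    reference <- peak_set(rf_chrom, rf_start, rf_start + pw, rf_id, rf_amp,
                          name = config$cond_reference)
    provenance <- data.frame(
      peak_id = c(tr_id, rf_id),
      condition = c(rep(config$cond_treated, n_tr),
                    rep(config$cond_reference, length(rf_id))),
      class = c(tr_class, rf_class),
      gene_id = c(tr_gene, rf_gene),
      twin_of = c(rep(NA_character_, n_tr), rf_twin_of),
      stringsAsFactors = FALSE)
    list(treated = treated, reference = reference, provenance = provenance)
  })
}

#' Simulate an expression table with planted fold changes
#'
#' Counts are negative binomial with a common dispersion around per-gene
#' baseline means; responsive genes carry their planted fold change in the
#' treated condition. Bound/responsive genes draw baselines from the
#' high-expression lognormal, background genes from a lower one with a
#' near-silent fraction (so the pooled-median RPKM offset stays small, as
#' in real skewed expression data). RPKM is computed from the counts via
#' the effective transcript length and per-sample sequencing depth.
#'
#' @param genes a [gene_models] set.
#' @param truth a `sim_truth`.
#' @param config the [sim_config].
#' @return An [expression_table] carrying both counts and RPKM.
#' @export
simulate_expression <- function(genes, truth, config) {
  stopifnot(inherits(genes, "gene_models"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (config$n_rep < 2L) stop_input("need at least 2 replicates")
  if (config$dispersion <= 0) stop_input("'dispersion' must be positive")
  ids <- genes$gene_id[order(genes$gene_id)]
  n <- length(ids)
  with_seed(child_seed(config$seed, 4), {
    regulated <- ids %in% union(truth$bound, truth$responsive)
    silent <- !regulated & stats::runif(n) < config$frac_silent
    mu <- numeric(n)
    mu[regulated] <- stats::rlnorm(sum(regulated),
                                   config$mu_meanlog_regulated,
                                   config$mu_sdlog_regulated)
    mu[!regulated & !silent] <- stats::rlnorm(sum(!regulated & !silent),
                                              config$mu_meanlog_background,
                                              config$mu_sdlog_background)
    mu[silent] <- config$mu_silent * stats::rlnorm(sum(silent), 0, 0.3)
    fc <- rep(1, n)
    ri <- match(names(truth$log2fc), ids)
    fc[ri] <- 2^truth$log2fc
    size <- 1 / config$dispersion
    nr <- config$n_rep
    counts <- matrix(0, nrow = n, ncol = 2L * nr)
    for (r in seq_len(nr)) {
      counts[, r] <- stats::rnbinom(n, size = size, mu = mu)
      counts[, nr + r] <- stats::rnbinom(n, size = size, mu = mu * fc)
    }
    samples <- data.frame(
      sample = c(paste0(config$cond_reference, "__", seq_len(nr)),
                 paste0(config$cond_treated, "__", seq_len(nr))),
      condition = rep(c(config$cond_reference, config$cond_treated),
                      each = nr),
      stringsAsFactors = FALSE)
    depth <- pmax(colSums(counts), 1)
    rpkm <- sweep(counts / (config$transcript_length / 1000), 2L,
                  depth / 1e6, "/")
    expression_table(rpkm, samples = samples,
                     genes = data.frame(gene_id = ids,
                                        transcript_id = paste0(ids, ".1"),
                                        stringsAsFactors = FALSE),
                     counts = counts)
  })
}

#' Simulate a co-occupying partner peak set
#'
#' Builds a second-factor peak set in which a fraction of the input peaks
#' receive an overlapping partner (midpoint shifted by a small normal
#' offset), and the remaining partner peaks are placed disjoint from the
#' input set.
#'
#' @param peaks the anchor [peak_set].
#' @param config a [sim_config] (chromosome sizes, peak width, amplitudes).
#' @param frac_overlap fraction of anchor peaks given an overlapping
#'   partner.
#' @param shift_sd s.d. (bp) of the partner midpoint offset.
#' @param n_unique number of partner-only peaks.
#' @param seed RNG seed.
#' @return A [peak_set].
#' @export
simulate_cooccupant_peaks <- function(peaks, config, frac_overlap = 0.63,
                                      shift_sd = 100, n_unique = 100,
                                      seed) {
  stopifnot(inherits(peaks, "peak_set"), inherits(config, "sim_config"))
  check_prob(frac_overlap, "frac_overlap")
  pw <- config$peak_width
  with_seed(seed, {
    pick <- stats::runif(nrow(peaks)) < frac_overlap
    shift_max <- max(1L, floor(pw / 2) - 1L)
    shift <- pmin(pmax(round(stats::rnorm(sum(pick), 0, shift_sd)),
                       -shift_max), shift_max)
    p_chrom <- peaks$chrom[pick]
    p_start <- pmax(0, peaks$start[pick] + shift)
    u_chrom <- character(n_unique)
    u_start <- numeric(n_unique)
    for (j in seq_len(n_unique)) {
      for (try in 1:200) {
        cand_chrom <- sample(names(config$chrom_sizes), 1L,
                             prob = config$chrom_sizes /
                               sum(config$chrom_sizes))
        cand_start <- floor(stats::runif(
          1, 0, config$chrom_sizes[cand_chrom] - pw))
        if (!overlaps_any(cand_chrom, cand_start, cand_start + pw, peaks)) {
          break
        }
      }
      u_chrom[j] <- cand_chrom
      u_start[j] <- cand_start
    }
    chrom <- c(p_chrom, u_chrom)
    start <- c(p_start, u_start)
    amp <- stats::rlnorm(length(start), config$amp_meanlog_bound,
                         config$amp_sdlog_bound)
    peak_set(chrom, start, start + pw,
             sprintf("cpk_%05d", seq_along(start)), amp,
             name = "cooccupant")
  })
}

#' Simulate a complete dataset with planted truth
#'
#' Chains [simulate_genome()], [make_truth()], [simulate_peaks()] and
#' [simulate_expression()].
#'
#' @param config a [sim_config].
#' @return List of class `"sim_dataset"`: `config`, `genes`, `truth`,
#'   `peaks` (treated/reference/provenance), `table`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- simulate_genome(config)
  truth <- make_truth(config)
  peaks <- simulate_peaks(genes, truth, config)
  table <- simulate_expression(genes, truth, config)
  structure(list(config = config, genes = genes, truth = truth,
                 peaks = peaks, table = table),
            class = "sim_dataset")
}

#' Write a simulated dataset as a ready-to-run directory
#'
#' Emits exactly the formats the package readers consume: `genes.bed`
#' (BED12), `peaks_<condition>.narrowPeak`, `expression.tsv`, `counts.tsv`,
#' `truth.json`, and a `manifest.json` with the parameters, seed, package
#' version and file checksums.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- ds$config
  paths <- c(
    genes = file.path(dir, "genes.bed"),
    peaks_treated = file.path(
      dir, paste0("peaks_", cfg$cond_treated, ".narrowPeak")),
    peaks_reference = file.path(
      dir, paste0("peaks_", cfg$cond_reference, ".narrowPeak")),
    expression = file.path(dir, "expression.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json"))
  write_gene_models(ds$genes, paths[["genes"]])
  write_peaks(ds$peaks$treated, paths[["peaks_treated"]], "narrowPeak")
  write_peaks(ds$peaks$reference, paths[["peaks_reference"]], "narrowPeak")
  write_expression(ds$table, paths[["expression"]], "rpkm")
  write_expression(ds$table, paths[["counts"]], "counts")
  write_truth(ds$truth, paths[["truth"]])
  manifest <- list(
    parameters = unclass(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tfsig")),
    files = stats::setNames(as.list(unname(tools::md5sum(unname(paths)))),
                            basename(unname(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
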