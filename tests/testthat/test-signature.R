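# shared micro-fixture: five genes, peaks on g1..g3 (g3 via a weak peak)
sig_fixture <- function() {
  g <- gene_models(paste0("g", 1:5), "c1", "+",
                   seq(0, by = 2e6, length.out = 5),
                   seq(0, by = 2e6, length.out = 5) + 1e4)
  pk <- peak_set("c1",
                 c(g$start[1] + 100, g$start[2] + 100, g$start[2] + 300,
                   g$start[3] + 100),
                 c(g$start[1] + 500, g$start[2] + 500, g$start[2] + 700,
                   g$start[3] + 500),
                 c("pk1", "pk2a", "pk2b", "pk3"),
                 c(100, 60, 80, 5))
  asg <- assign_peaks_to_genes(pk, g)
  rp <- matrix(rep(c(10, 10, 30, 30), 5), nrow = 5, byrow = TRUE)
  colnames(rp) <- c("exvivo__1", "exvivo__2", "il15__1", "il15__2")
  rownames(rp) <- paste0("g", 1:5)
  tb <- add_offset(tiny_table(rp))
  list(genes = g, peaks = pk, asg = asg, table = tb)
}

test_that("full signature requires binding, strong response and expression", {
  fx <- sig_fixture()
  degs <- fake_degs(paste0("g", 1:5),
                    c(2.5, 2.0, 8.0, 8.0, 1.1),
                    c(0.01, 0.01, 1e-6, 1e-6, 0.5))
  sig <- derive_full_signature(fx$asg, degs, fx$table)
  # g1: bound, FC 2.5, p 0.01 -> member; g2: FC exactly 2 -> excluded
  # g3: bound, FC 8 -> member; g4: unbound despite FC 8 -> excluded
  expect_equal(sig$gene_id, c("g1", "g3"))
  expect_equal(sig$direction, c("up", "up"))
  # evidence: highest-amplitude assigned peak
  expect_equal(sig$best_peak_id[sig$gene_id == "g1"], "pk1")
  expect_equal(sig$best_amplitude[sig$gene_id == "g1"], 100)
})

test_that("best-peak ties break to the smallest peak id", {
  fx <- sig_fixture()
  pk <- peak_set("c1", c(100, 300), c(500, 700), c("pkB", "pkA"), c(50, 50))
  asg <- assign_peaks_to_genes(pk, fx$genes)
  degs <- fake_degs("g1", 4, 0.001)
  sig <- derive_full_signature(asg, degs, fx$table)
  expect_equal(sig$best_peak_id, "pkA")
})

test_that("expression floor excludes low-RPKM genes from the signature", {
  fx <- sig_fixture()
  rp <- matrix(rep(c(0.4, 0.4, 1.5, 1.5), 5), nrow = 5, byrow = TRUE)
  colnames(rp) <- c("exvivo__1", "exvivo__2", "il15__1", "il15__2")
  rownames(rp) <- paste0("g", 1:5)
  low <- add_offset(tiny_table(rp))
  degs <- fake_degs(paste0("g", 1:5), rep(4, 5), rep(0.001, 5))
  expect_equal(nrow(derive_full_signature(fx$asg, degs, low)), 0)
  expect_equal(derive_full_signature(fx$asg, degs, low,
                                     min_mean_rpkm = NULL)$gene_id,
               c("g1", "g2", "g3"))
})

test_that("compact signature needs a top-quartile peak and a stronger response", {
  fx <- sig_fixture()
  flags <- amplitude_quantile_flag(fx$peaks, 0.75)
  expect_equal(names(flags)[flags], "pk1")  # threshold 95: only pk1
  degs <- fake_degs(paste0("g", 1:5),
                    c(3.5, 5.0, 5.0, 5.0, 1.0),
                    c(0.01, 0.01, 0.01, 0.01, 0.9))
  sig <- derive_compact_signature(fx$asg, degs, fx$table, flags)
  # g1 has the only high-amplitude peak; g2 responds 5x but its peaks are
  # below threshold; g3's peak is weak; g4 unbound
  expect_equal(sig$gene_id, "g1")

  bad_flags <- flags[1]
  expect_error(derive_compact_signature(fx$asg, degs, fx$table, bad_flags),
               "amplitude_flags")
})

test_that("disjoint assignment and DEG universes raise an ID-space error", {
  fx <- sig_fixture()
  degs <- fake_degs(c("x1", "x2"), c(4, 4), c(0.01, 0.01))
  expect_error(derive_full_signature(fx$asg, degs, fx$table), "disjoint")
})

test_that("bound/responsive fractions mirror the donut arithmetic", {
  g <- gene_models(paste0("g", 1:12), "c1", "+",
                   seq(0, by = 2e6, length.out = 12),
                   seq(0, by = 2e6, length.out = 12) + 1e4)
  bound_idx <- 1:10
  pk <- peak_set("c1", g$start[bound_idx] + 100, g$start[bound_idx] + 500,
                 amplitude = rep(1, 10))
  asg <- assign_peaks_to_genes(pk, g)
  degs <- fake_degs(paste0("g", 1:12),
                    ifelse(1:12 %in% c(1, 2, 11, 12), 3, 1),
                    ifelse(1:12 %in% c(1, 2, 11, 12), 0.01, 0.9))
  fr <- bound_responsive_fractions(asg, degs)
  expect_equal(fr$n_bound, 10)
  expect_equal(fr$n_responsive, 4)
  expect_equal(fr$frac_bound_that_respond, 0.2)
  expect_equal(fr$frac_responsive_that_are_bound, 0.5)
  expect_equal(fr$n_up + fr$n_down, fr$n_responsive)

  none <- fake_degs(paste0("g", 1:12), rep(1.01, 12), rep(0.9, 12))
  fr0 <- bound_responsive_fractions(asg, none)
  expect_equal(fr0$frac_bound_that_respond, 0)
  expect_equal(fr0$frac_responsive_that_are_bound, 0)

  all_bound <- fake_degs(paste0("g", bound_idx), rep(3, 10), rep(0.01, 10))
  fr1 <- bound_responsive_fractions(asg, all_bound)
  expect_equal(fr1$frac_bound_that_respond, 1)
  expect_equal(fr1$frac_responsive_that_are_bound, 1)
})

test_that("collapse statistics classify a gene set per mode", {
  degs <- fake_degs(c("a", "b", "c", "d"),
                    c(0.4, 2.2, 1.0, 0.9),
                    c(0.01, 0.01, 0.5, 0.5))
  st <- signature_collapse_stats(c("a", "b", "c"), degs, "significance")
  expect_equal(c(st$n_reduced, st$n_enhanced, st$n_unchanged), c(1, 1, 1))

  all_down <- fake_degs(c("a", "b"), c(0.3, 0.5), c(0.01, 0.01))
  st2 <- signature_collapse_stats(c("a", "b"), all_down, "significance")
  expect_equal(st2$n_reduced, 2)

  st3 <- signature_collapse_stats(c("d", "b"), degs, "raw_fc")
  expect_equal(c(st3$n_reduced, st3$n_enhanced, st3$n_unchanged), c(1, 1, 0))

  st4 <- signature_collapse_stats(c("a", "zz"), degs, "raw_fc")
  expect_equal(st4$n_absent, 1)
  expect_error(signature_collapse_stats(character(), degs), "empty")
})

test_that("signature size is monotone in its thresholds", {
  set.seed(71)
  ds <- simulate_dataset(sim_config(seed = 71, n_genes = 300, n_bound = 60,
                                    n_responsive = 50, lfc_min = 0.5,
                                    chrom_sizes = c(chr1 = 9e7),
                                    n_background_peaks = 20))
  tb <- add_offset(filter_low_abundance(collapse_transcripts(ds$table)))
  degs <- call_degs(tb, c("il15", "exvivo"), p_source = "builtin")
  asg <- assign_peaks_to_genes(ds$peaks$treated, ds$genes)
  n_of <- function(fc, rpkm, window = 50000) {
    a <- if (window == 50000) asg else
      assign_peaks_to_genes(ds$peaks$treated, ds$genes, window)
    nrow(derive_full_signature(a, degs, tb, fc_threshold = fc,
                               min_mean_rpkm = rpkm))
  }
  expect_gte(n_of(1.5, 2), n_of(2, 2))
  expect_gte(n_of(2, 2), n_of(3, 2))
  expect_gte(n_of(2, 0), n_of(2, 2))
  expect_gte(n_of(2, 2), n_of(2, 20))
  expect_gte(n_of(2, 2), n_of(2, 2, window = 10000))
})
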