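test_that("peaks assign by TSS window or body overlap with one record per pair", {
  g <- gene_models("gA", "chr1", "+", 100000, 110000)
  near <- peak_set("chr1", 140000, 140500, "p_near", 10)
  far <- peak_set("chr1", 160000, 160400, "p_far", 10)
  body <- peak_set("chr1", 105000, 105200, "p_body", 10)

  a1 <- assign_peaks_to_genes(near, g)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$relation, "near_tss")
  expect_equal(a1$distance, 40000)  # downstream, plus strand

  expect_equal(nrow(assign_peaks_to_genes(far, g)), 0)  # 60 kb >= window

  a3 <- assign_peaks_to_genes(body, g)  # body overlap AND within window
  expect_equal(nrow(a3), 1)
  expect_equal(a3$relation, "in_body")
})

test_that("signed TSS distance is downstream-positive relative to strand", {
  g <- gene_models(c("gp", "gm"), "chr1", c("+", "-"),
                   c(100000, 500000), c(110000, 510000))
  # 10 kb to the right of each TSS (gp tss = 100000, gm tss = 509999)
  pk <- peak_set("chr1", c(112000, 520000), c(112400, 520399),
                 c("a", "b"), c(1, 1))
  asg <- assign_peaks_to_genes(pk, g)
  expect_equal(asg$distance[asg$peak_id == "a"], 12000)
  expect_equal(asg$distance[asg$peak_id == "b"], -(520000 - 509999))
  # a peak spanning the TSS has distance 0
  span <- peak_set("chr1", 99900, 100200, "s", 1)
  expect_equal(assign_peaks_to_genes(span, g)$distance, 0)
})

test_that("shrinking the window never adds assignments", {
  set.seed(61)
  for (i in 1:10) {
    inst <- random_instance(n_peaks = 80, n_genes = 25)
    keys <- lapply(c(60000, 50000, 20000, 5000), function(w) {
      assignment_keys(assign_peaks_to_genes(inst$peaks, inst$genes, w))
    })
    for (k in 2:4) expect_true(all(keys[[k]] %in% keys[[k - 1]]))
  }
})

test_that("assignment matches the all-pairs brute force on random instances", {
  set.seed(62)
  for (i in 1:20) {
    inst <- random_instance(n_peaks = 120, n_genes = 40)
    expect_identical(
      assignment_keys(assign_peaks_to_genes(inst$peaks, inst$genes, 50000)),
      brute_force_assign(inst$peaks, inst$genes, 50000))
  }
})

test_that("condition overlap counts shared and unique peaks per side", {
  a <- peak_set("c1", 100, 200, "a1", 1)
  b <- peak_set("c1", 150, 250, "b1", 1)
  ov <- classify_condition_overlap(a, b)
  expect_equal(ov$shared_a, 1)
  expect_equal(ov$unique_a, 0)

  b2 <- peak_set("c1", 300, 400, "b1", 1)
  expect_equal(classify_condition_overlap(a, b2)$shared_a, 0)

  # many-to-one overlap makes the report asymmetric
  a3 <- peak_set("c1", c(100, 210), c(200, 300), c("a1", "a2"), c(1, 1))
  b3 <- peak_set("c1", 150, 260, "b1", 1)
  ov3 <- classify_condition_overlap(a3, b3)
  expect_equal(ov3$shared_a, 2)
  expect_equal(ov3$shared_b, 1)
  expect_equal(ov3$shared_a + ov3$unique_a, ov3$n_a)

  self <- classify_condition_overlap(a3, a3)
  expect_equal(self$frac_shared_a, 1)
  expect_error(classify_condition_overlap(a3, a3[0, ]), "non-empty")
})

test_that("gene-association exclusivity partitions the gene union", {
  g <- gene_models(paste0("g", 1:3), "c1", "+",
                   c(0, 2e6, 4e6), c(0, 2e6, 4e6) + 1e4)
  pk_of <- function(genes, ids) {
    i <- match(genes, g$gene_id)
    peak_set("c1", g$start[i] + 100, g$start[i] + 500, ids, rep(1, length(i)))
  }
  a <- assign_peaks_to_genes(pk_of(c("g1", "g2"), c("p1", "p2")), g)
  b <- assign_peaks_to_genes(pk_of(c("g2", "g3"), c("q1", "q2")), g)
  ex <- gene_association_exclusivity(a, b)
  expect_equal(ex$a_only, "g1")
  expect_equal(ex$both, "g2")
  expect_equal(ex$b_only, "g3")
  expect_equal(ex$frac_a_only + ex$frac_b_only + ex$frac_both, 1)

  same <- gene_association_exclusivity(a, a)
  expect_equal(same$n_a_only + same$n_b_only, 0)
  dis <- gene_association_exclusivity(
    a, assign_peaks_to_genes(pk_of("g3", "r1"), g))
  expect_equal(dis$n_both, 0)
})

test_that("TSS profile bins nearest distances and averages amplitude", {
  g <- gene_models("gA", "chr1", "+", 1e6, 1.01e6)
  pk <- peak_set("chr1", c(1e6 + 1000, 1e6 + 40000),
                 c(1e6 + 1200, 1e6 + 40200), c("p1", "p2"), c(10, 30))
  asg <- assign_peaks_to_genes(pk, g)
  prof <- tss_distance_profile(asg, c(0, 10000, 50000))
  expect_equal(prof$fraction, c(0.5, 0.5))
  expect_equal(sum(prof$fraction), 1)

  one_bin <- tss_distance_profile(asg, c(0, 50000))
  expect_equal(one_bin$mean_amplitude, 20)

  shuf <- asg[rev(seq_len(nrow(asg))), ]
  class(shuf) <- class(asg)
  expect_equal(as.data.frame(tss_distance_profile(shuf, c(0, 10000, 50000))),
               as.data.frame(prof))
  expect_error(tss_distance_profile(asg, c(10000, 0)), "increasing")
})

test_that("amplitude flags use the linear-interpolation quantile with >=", {
  pk <- peak_set("c1", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
                 paste0("p", 1:4), c(1, 2, 3, 4))
  fl <- amplitude_quantile_flag(pk, q = 0.75)
  # independent computation of the chosen convention
  expect_equal(attr(fl, "threshold"),
               unname(quantile(c(1, 2, 3, 4), 0.75, type = 7)))
  expect_equal(attr(fl, "threshold"), 3.25)
  expect_equal(as.vector(fl), c(FALSE, FALSE, FALSE, TRUE))

  eq <- amplitude_quantile_flag(
    peak_set("c1", c(0, 1000), c(500, 1500), amplitude = c(7, 7)), 0.75)
  expect_true(all(eq))  # threshold equals the common value, >= passes
  expect_true(all(amplitude_quantile_flag(pk, q = 0)))
})

test_that("co-occupancy reports overlap fraction and midpoint distances", {
  a <- peak_set("c1", c(0, 5000), c(1000, 6000), c("a1", "a2"), c(1, 1))
  self <- cooccupancy(a, a)
  expect_equal(self$fraction, 1)
  expect_equal(unname(self$midpoint_distance), c(0, 0))

  b <- peak_set("c2", c(0, 5000), c(1000, 6000), c("b1", "b2"), c(1, 1))
  dis <- cooccupancy(a, b)
  expect_equal(dis$fraction, 0)
  expect_true(all(is.na(dis$midpoint_distance)))

  # 100 peaks of 1 kb; partner set shifted +200 bp -> all shared, mode +200
  st <- seq(0, by = 5000, length.out = 100)
  pa <- peak_set("c1", st, st + 1000, amplitude = rep(1, 100))
  pb <- peak_set("c1", st + 200, st + 1200, amplitude = rep(1, 100))
  co <- cooccupancy(pa, pb)
  expect_equal(co$fraction, 1)
  expect_equal(unname(co$midpoint_distance), rep(200, 100))
})
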