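cn4 <- c("exvivo__1", "exvivo__2", "il15__1", "il15__2")

test_that("transcript collapse keeps the most abundant transcript per gene", {
  rp <- mat(5, 5, 5, 5,
            7, 7, 7, 7,
            2, 2, 2, 2, ncol = 4, cn = cn4)
  tb <- tiny_table(rp, gene_id = c("gX", "gX", "gY"),
                   transcript_id = c("t1", "t2", "t3"))
  out <- collapse_transcripts(tb)
  expect_equal(out$genes$transcript_id, c("t2", "t3"))  # t2: higher mean
  expect_true(out$collapsed)

  # exact tie -> lexicographically smallest transcript id
  rp2 <- mat(5, 5, 5, 5,
             5, 5, 5, 5, ncol = 4, cn = cn4)
  tb2 <- tiny_table(rp2, gene_id = c("gX", "gX"),
                    transcript_id = c("t2", "t1"))
  expect_equal(collapse_transcripts(tb2)$genes$transcript_id, "t1")

  # idempotent; single-transcript genes unchanged
  expect_equal(collapse_transcripts(out), out)
})

test_that("offset equals the pooled median and is applied exactly once", {
  rp <- matrix(0:4, nrow = 1)
  colnames(rp) <- c("a__1", "a__2", "a__3", "a__4", "a__5")
  tb <- add_offset(tiny_table(rp, gene_id = "g1"))
  expect_equal(tb$offset, 2)
  expect_equal(as.numeric(tb$rpkm), 2:6)
  expect_error(add_offset(tb), "already applied")

  # even cell count: midpoint of the central pair
  rp2 <- mat(1, 2, 3, 4, ncol = 4, cn = cn4)
  expect_equal(add_offset(tiny_table(rp2, gene_id = "g"))$offset, 2.5)

  # all-zero table: offset 0, values unchanged
  rp3 <- mat(0, 0, 0, 0, ncol = 4, cn = cn4)
  tb3 <- add_offset(tiny_table(rp3, gene_id = "g"))
  expect_equal(tb3$offset, 0)
  expect_equal(as.numeric(tb3$rpkm), rep(0, 4))
})

test_that("offset is invariant to row and column permutation", {
  set.seed(21)
  rp <- matrix(rexp(60), nrow = 10)
  colnames(rp) <- paste0(rep(c("a", "b"), each = 3), "__", 1:3)
  rownames(rp) <- paste0("g", 1:10)
  base <- add_offset(tiny_table(rp))$offset
  perm <- rp[sample(10), sample(6)]
  expect_equal(add_offset(tiny_table(perm))$offset, base)
})

test_that("low-abundance filter keeps genes reaching the floor in one condition", {
  rp <- mat(0.2, 0.2, 0.8, 0.8,
            0.2, 0.2, 1.0, 1.0,
            5.0, 5.0, 0.1, 0.1, ncol = 4, cn = cn4)
  rownames(rp) <- c("gA", "gB", "gC")
  tb <- tiny_table(rp)
  out <- filter_low_abundance(tb)
  expect_equal(out$genes$gene_id, c("gB", "gC"))  # gA: all means < 1

  expect_equal(filter_low_abundance(tb, min_rpkm = 0)$genes$gene_id,
               c("gA", "gB", "gC"))
  expect_equal(filter_low_abundance(out), out)  # idempotent
  expect_error(filter_low_abundance(add_offset(tb)), "before add_offset")
})

test_that("fold changes use post-offset replicate means", {
  rp <- mat(3, 5, 8, 10, ncol = 4, cn = cn4) - 1  # means 3 and 8 pre-offset
  rownames(rp) <- "g1"
  tb <- tiny_table(rp)
  tb$offset <- 1  # pretend-offset for a controlled 4 vs 9 example
  tb$rpkm <- tb$rpkm + 1
  fc <- compute_fold_changes(tb, c("il15", "exvivo"))
  expect_equal(fc$fold_change, 9 / 4)

  rp2 <- mat(4, 4, 4, 4, ncol = 4, cn = cn4)
  rownames(rp2) <- "g1"
  expect_equal(compute_fold_changes(add_offset(tiny_table(rp2)),
                                    c("il15", "exvivo"))$fold_change, 1)
  expect_error(compute_fold_changes(tiny_table(rp2), c("il15", "exvivo")),
               "add_offset")
})

test_that("the offset damps fold-change artifacts from low-abundance genes", {
  # raw means 0.1 vs 0.001 would give FC 100; with offset 1 it is ~1.099
  rp <- mat(0.001, 0.001, 0.1, 0.1, ncol = 4, cn = cn4)
  rownames(rp) <- "g1"
  tb <- tiny_table(rp)
  tb$rpkm <- tb$rpkm + 1
  tb$offset <- 1
  fc <- compute_fold_changes(tb, c("il15", "exvivo"))
  expect_equal(fc$fold_change, 1.1 / 1.001)
})

test_that("fold changes are anti-symmetric in the contrast", {
  set.seed(31)
  rp <- matrix(rexp(120, 1 / 20), nrow = 20)
  colnames(rp) <- cn4[c(1, 2, 3, 4, 3, 4)]
  colnames(rp) <- paste0(rep(c("exvivo", "il15"), each = 3), "__", 1:3)
  rownames(rp) <- paste0("g", 1:20)
  tb <- add_offset(tiny_table(rp))
  ab <- compute_fold_changes(tb, c("il15", "exvivo"))$fold_change
  ba <- compute_fold_changes(tb, c("exvivo", "il15"))$fold_change
  expect_equal(ab, 1 / ba)
})

test_that("DEG calling applies strict fold-change and p-value gates", {
  rp <- mat(10, 10, 15, 15,    # FC exactly 1.5
            10, 10, 4, 4,      # FC 0.4 -> down DEG
            10, 10, 30, 30,    # FC 3
            ncol = 4, cn = cn4)
  rownames(rp) <- c("g1", "g2", "g3")
  tb <- tiny_table(rp, pvalues = list(il15_vs_exvivo = c(0.01, 0.01, 0.06)))
  tb$offset <- 0  # zero offset: keep the textbook fold changes exact
  degs <- call_degs(tb, c("il15", "exvivo"), p_source = "precomputed")
  expect_equal(degs$is_deg, c(FALSE, TRUE, FALSE))  # strict >, p gate
  expect_equal(degs$direction[2], "down")
})

test_that("DEG sets shrink as thresholds tighten", {
  set.seed(41)
  n <- 200
  rp <- matrix(rexp(n * 6, 1 / 50), nrow = n)
  colnames(rp) <- paste0(rep(c("exvivo", "il15"), each = 3), "__", 1:3)
  rownames(rp) <- sprintf("g%03d", 1:n)
  tb <- add_offset(tiny_table(
    rp, pvalues = list(il15_vs_exvivo = runif(n)^2)))
  n_deg <- function(fc, p) {
    sum(call_degs(tb, c("il15", "exvivo"), fc_threshold = fc,
                  p_threshold = p, p_source = "precomputed")$is_deg)
  }
  for (fc in c(1.2, 1.5, 2, 3)) {
    expect_gte(n_deg(fc, 0.05), n_deg(fc * 1.5, 0.05))
    expect_gte(n_deg(fc, 0.05), n_deg(fc, 0.01))
  }
})

test_that("precomputed DEG flags reproduce a table's own calls", {
  set.seed(51)
  n <- 100
  rp <- matrix(rexp(n * 4, 1 / 20), nrow = n)
  colnames(rp) <- cn4
  rownames(rp) <- sprintf("g%03d", 1:n)
  pv <- runif(n)
  tb <- add_offset(tiny_table(rp, pvalues = list(il15_vs_exvivo = pv)))
  fc <- compute_fold_changes(tb, c("il15", "exvivo"))$fold_change
  own_flag <- (fc > 1.5 | fc < 1 / 1.5) & pv < 0.05
  degs <- call_degs(tb, c("il15", "exvivo"), p_source = "precomputed")
  expect_equal(degs$is_deg, own_flag)
})

test_that("NB exact test matches an independent conditional enumeration", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5)), 1)
  expect_lt(nb_exact_test(c(100, 110), c(10, 12)), 0.01)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0)), 1)
  expect_error(nb_exact_test(c(5), c(5, 5)), "2 counts per group")
  expect_error(nb_exact_test(c(5.5, 2), c(5, 5)), "integers")

  cases <- list(list(a = c(12, 18, 9), b = c(4, 2, 7), phi = 0.1),
                list(a = c(30, 25), b = c(28, 33), phi = 0.05),
                list(a = c(0, 3, 1), b = c(9, 12, 7), phi = 0.2))
  for (cs in cases) {
    expect_equal(nb_exact_test(cs$a, cs$b, dispersion = cs$phi),
                 nb_cond_pvalue_oracle(cs$a, cs$b, cs$phi),
                 tolerance = 1e-8)
  }
})

test_that("NB exact test reduces to the binomial split test at the Poisson limit", {
  a <- c(30, 25, 40); b <- c(10, 12, 8)
  expect_equal(nb_exact_test(a, b, dispersion = 1e-6),
               edgeR::binomTest(sum(a), sum(b), n1 = 1e7, n2 = 1e7),
               tolerance = 1e-3)
})

test_that("builtin DEG route needs counts and enough replicates", {
  rp <- mat(10, 10, 30, 30, ncol = 4, cn = cn4)
  rownames(rp) <- "g1"
  tb <- add_offset(tiny_table(rp))
  expect_error(call_degs(tb, c("il15", "exvivo"), p_source = "builtin"),
               "raw counts")
  rp2 <- matrix(c(10, 30), nrow = 1)
  colnames(rp2) <- c("exvivo__1", "il15__1")
  tb2 <- add_offset(tiny_table(rp2, counts = rp2, gene_id = "g1"))
  expect_error(call_degs(tb2, c("il15", "exvivo"), p_source = "builtin"),
               "2 replicates")
})
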