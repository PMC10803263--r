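test_that("read counting applies strict quality, overlap and strand rules", {
  genes <- data.frame(gene = "gA", start = 1000, end = 2000, strand = "+")
  read <- function(start, end, strand = "-", mapq = 30) {
    data.frame(start = start, end = end, strand = strand, mapq = mapq)
  }
  # reverse-stranded library: a - read matches a + gene
  expect_equal(unname(count_reads(read(1100, 1200), genes)), 1L)
  # mapping quality exactly 10 is excluded ("above ten" is strict)
  expect_equal(unname(count_reads(read(1100, 1200, mapq = 10), genes)), 0L)
  expect_equal(unname(count_reads(read(1100, 1200, mapq = 11), genes)), 1L)
  # overlap fraction exactly 0.5 is excluded ("above 0.5" is strict)
  expect_equal(unname(count_reads(read(950, 1050), genes)), 0L)
  expect_equal(unname(count_reads(read(951, 1051), genes)), 1L)
  # strand modes
  expect_equal(unname(count_reads(read(1100, 1200, strand = "+"), genes)), 0L)
  expect_equal(unname(count_reads(read(1100, 1200, strand = "+"), genes,
                                  strandedness = "forward")), 1L)
  expect_equal(unname(count_reads(read(1100, 1200, strand = "+"), genes,
                                  strandedness = "unstranded")), 1L)
  expect_error(count_reads(read(1, 2), genes, strandedness = "sideways"))
})

test_that("reads matching several genes are discarded as ambiguous", {
  genes <- data.frame(gene = c("gA", "gB"), start = c(0, 0),
                      end = c(500, 500), strand = c("+", "+"))
  r <- data.frame(start = 100, end = 200, strand = "-", mapq = 30)
  expect_equal(unname(count_reads(r, genes)), c(0L, 0L))
})

test_that("read counting matches a per-read brute-force oracle", {
  withr::with_seed(71, {
    genes <- data.frame(gene = paste0("g", 1:8),
                        start = seq(0, 7000, 1000),
                        end = seq(0, 7000, 1000) + sample(400:900, 8),
                        strand = sample(c("+", "-"), 8, TRUE))
    reads <- data.frame(start = sample(0:7900, 1000, TRUE),
                        strand = sample(c("+", "-"), 1000, TRUE),
                        mapq = sample(0:60, 1000, TRUE))
    reads$end <- reads$start + sample(50:150, 1000, TRUE)
    got <- count_reads(reads, genes, strandedness = "reverse")
    want <- stats::setNames(integer(8), genes$gene)
    for (i in seq_len(nrow(reads))) {
      if (reads$mapq[i] <= 10) next
      hits <- character(0)
      for (j in seq_len(nrow(genes))) {
        ov <- max(0, min(reads$end[i], genes$end[j]) -
                     max(reads$start[i], genes$start[j]))
        if (ov / (reads$end[i] - reads$start[i]) > 0.5 &&
            reads$strand[i] != genes$strand[j]) {
          hits <- c(hits, genes$gene[j])
        }
      }
      if (length(hits) == 1) want[hits] <- want[hits] + 1L
    }
    expect_equal(got, want)
  })
})

test_that("variance stabilization has unit size factors for identical samples", {
  counts <- matrix(rep(c(10L, 200L, 3000L), 4), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  v <- normalize_vst(counts, gene_lengths = c(500, 1000, 2000))
  expect_equal(unname(v$size_factors), rep(1, 4))
  expect_equal(v$mat[, 1], v$mat[, 4])
  expect_error(normalize_vst(counts, c(0, 1000, 2000)), "length")
})

test_that("the generalized log matches its closed form and asymptote", {
  c0 <- 8
  expect_equal(glog2(0, c0), log2(c0 / 2))             # finite at zero
  x <- c0 * c(10, 50, 1000)
  expect_true(all(abs(glog2(x, c0) - log2(x)) / log2(x) < 0.01))
  expect_lt(abs(glog2(10 * c0, c0) - log2(10 * c0)), 0.005)
})

test_that("per-gene two-way ANOVA equals the aov decomposition", {
  withr::with_seed(41, {
    d <- toy_design(3)
    for (rep in 1:5) {
      mat <- matrix(rnorm(10 * nrow(d), mean = 8), nrow = 10,
                    dimnames = list(paste0("g", 1:10), NULL))
      mat[1, d$strain == "dcedA"] <- mat[1, d$strain == "dcedA"] + 2
      got <- factorial_anova(mat, d$strain, d$treatment)
      for (g in 1:10) {
        want <- oracle_anova_gene(mat[g, ], d$strain, d$treatment)
        expect_equal(c(got$F_strain[g], got$F_treatment[g],
                       got$F_interaction[g]), want$F, tolerance = 1e-10)
        expect_equal(c(got$p_strain[g], got$p_treatment[g],
                       got$p_interaction[g]), want$p, tolerance = 1e-10)
      }
    }
  })
})

test_that("ANOVA on a hand-checkable balanced table gives the textbook F", {
  # 2 strains x 2 treatments x 2 reps with known cell means
  strain <- rep(c("A", "B"), each = 4)
  treatment <- rep(rep(c("c", "t"), each = 2), 2)
  y <- c(1, 3, 5, 7, 3, 5, 9, 11)
  # cell means: A/c=2, A/t=6, B/c=4, B/t=10; grand mean 5.5
  # SS_strain = 8*(1.5^2)/... strain means 4, 7 -> SS = 4*(1.5^2)*2 = 18
  # treatment means 3, 8 -> SS = 4*(2.5^2)*2 = 50; interaction SS = 2
  # residual: each cell sd^2 = 2 -> SS_res = 4 cells * 2 * 1df = 8, df = 4
  got <- factorial_anova(matrix(y, nrow = 1), strain, treatment)
  expect_equal(got$F_strain, (18 / 1) / (8 / 4))
  expect_equal(got$F_treatment, (50 / 1) / (8 / 4))
  expect_equal(got$F_interaction, (2 / 1) / (8 / 4))
})

test_that("null matrices give uniform p-values and a strong shift is detected", {
  withr::with_seed(42, {
    d <- toy_design(3)
    mat <- matrix(rnorm(500 * nrow(d)), nrow = 500)
    rownames(mat) <- paste0("g", 1:500)
    de <- factorial_anova(mat, d$strain, d$treatment)
    expect_gt(stats::ks.test(de$p_strain, "punif")$p.value, 0.01)
    expect_gt(stats::ks.test(de$p_interaction, "punif")$p.value, 0.01)

    shifted <- mat[1, , drop = FALSE]
    shifted[, d$strain == "dcedA"] <- shifted[, d$strain == "dcedA"] + 5
    de1 <- factorial_anova(shifted, d$strain, d$treatment)
    expect_lt(de1$p_strain, 1e-3)
  })
})

test_that("unreplicated designs drop the interaction with a warning", {
  d <- toy_design(1)
  mat <- matrix(rnorm(3 * nrow(d)), nrow = 3)
  rownames(mat) <- paste0("g", 1:3)
  expect_warning(de <- factorial_anova(mat, d$strain, d$treatment),
                 "replication")
  expect_true(all(is.na(de$F_interaction)))
  expect_true(all(is.finite(de$p_overall)))
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.4), 0.4)              # m = 1: q = p
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
  withr::with_seed(55, {
    for (i in 1:10) {
      p <- runif(sample(5:200, 1))^2
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p))
      expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p order
    }
  })
})

test_that("fold changes against the reference strain recover planted shifts", {
  d <- toy_design(2)
  mat <- matrix(5, nrow = 2, ncol = nrow(d),
                dimnames = list(c("g1", "g2"), NULL))
  sel <- d$strain == "dcedA" & d$treatment == "rifampicin"
  mat["g1", sel] <- 5 + 1.5
  mat["g2", d$strain == "dcedA_pCedA"] <- 5 - 2
  lfc <- lfc_vs_reference(mat, d$strain, d$treatment)
  expect_equal(lfc["g1", "dcedA_rifampicin"], 1.5)
  expect_equal(lfc["g1", "dcedA_control"], 0)
  expect_equal(lfc["g2", "dcedA_pCedA_control"], -2)
  expect_equal(lfc["g2", "dcedA_pCedA_rifampicin"], -2)
  expect_error(lfc_vs_reference(mat, d$strain, d$treatment, ref_strain = "zz"),
               "reference")
})

test_that("DE filtering applies strict thresholds with signed directions", {
  lfc <- matrix(c(0.6, 0.4, -0.7, 0.51), nrow = 4,
                dimnames = list(paste0("g", 1:4), "dcedA_rifampicin"))
  q <- stats::setNames(c(0.005, 0.005, 0.0099, 0.01), paste0("g", 1:4))
  calls <- de_filter(q, lfc, q_max = 0.01, lfc_min = 0.5)
  expect_equal(calls$gene, c("g1", "g3"))      # g2: lfc 0.4; g4: q = 0.01 exact
  expect_equal(calls$direction, c("up", "down"))
  expect_equal(calls$strain, rep("dcedA", 2))
  expect_equal(calls$treatment, rep("rifampicin", 2))
})

test_that("promoter cross-referencing intersects DE calls with assigned genes", {
  calls <- data.frame(gene = c("g1", "g2", "g3"),
                      strain = "dcedA", treatment = "rifampicin",
                      lfc = c(-1, -2, 1), q = 1e-4, direction = "down")
  lfc <- matrix(c(-1, -2, 1, 0.2, 0.4, 0.1), nrow = 3,
                dimnames = list(c("g1", "g2", "g3"),
                                c("dcedA_rifampicin", "dcedA_pCedA_rifampicin")))
  out <- crossref_promoters(calls, c("g1", "g3"), lfc)
  expect_equal(out$gene, c("g1", "g3"))        # g2 has no assigned peak
  expect_equal(out$lfc_dcedA, c(-1, 1))
  expect_equal(out$lfc_dcedA_pCedA, c(0.2, 0.1))
  empty <- crossref_promoters(calls, character(0), lfc)
  expect_equal(nrow(empty), 0)
})
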