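# replication timing, RFD, strand assignment and bias statistics

test_that("timing interpolation is exact against the piecewise-linear form", {
  tr <- genomic_track(data.frame(chrom = "chr1",
                                 pos = c(1000, 2000, 4000),
                                 value = c(0.2, 0.6, 0.0)), "timing")
  expect_equal(timing_at(tr, "chr1", 1500), 0.4)
  expect_equal(timing_at(tr, "chr1", 1000), 0.2)
  expect_equal(timing_at(tr, "chr1", 100), 0.2)     # clamped
  expect_equal(timing_at(tr, "chr1", 9000), 0.0)    # clamped
  expect_true(is.na(timing_at(tr, "chr2", 1500)))

  set.seed(15)
  knots_x <- sort(sample(1000:100000, 40))
  knots_y <- rnorm(40)
  tr2 <- genomic_track(data.frame(chrom = "chr1", pos = knots_x,
                                  value = knots_y), "timing")
  q <- runif(100, min(knots_x), max(knots_x))
  closed_form <- vapply(q, function(x) {
    i <- max(which(knots_x <= x))
    if (i == length(knots_x)) return(knots_y[i])
    w <- (x - knots_x[i]) / (knots_x[i + 1] - knots_x[i])
    (1 - w) * knots_y[i] + w * knots_y[i + 1]
  }, numeric(1))
  expect_equal(timing_at(tr2, "chr1", q), closed_form, tolerance = 1e-12)
})

test_that("decile bins follow empirical quantiles and partition evenly", {
  cuts <- decile_bins(1:100)
  o <- sort(1:100)
  want <- vapply(seq(0.1, 0.9, 0.1), function(p) {
    # type-7 empirical quantile by sort-and-index
    h <- (100 - 1) * p + 1
    lo <- floor(h)
    o[lo] + (h - lo) * (o[lo + 1] - o[lo])
  }, numeric(1))
  expect_equal(cuts, want)
  expect_equal(cuts[1], 10.9)

  expect_error(decile_bins(rep(1, 50)), "distinct")

  set.seed(21)
  x <- runif(5000)
  d <- assign_decile(x, decile_bins(x))
  expect_true(all(d %in% 1:10))
  expect_true(all(abs(table(d) - 500) <= 1))
  # left-closed bins: a score equal to a cut goes to the upper bin
  expect_equal(assign_decile(cuts[1], cuts), 2L)
})

test_that("RFD computation and window lookup behave", {
  ok <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                   end = c(1000, 2000, 3000),
                   rightward = c(30, 10, 0), leftward = c(10, 10, 0))
  tr <- compute_rfd(ok)
  expect_equal(tr$data$chr1$value, c(0.5, 0))
  expect_equal(attr(tr, "n_missing"), 1)
  expect_equal(rfd_at(tr, "chr1", 600), 0.5)
  expect_true(is.na(rfd_at(tr, "chr1", 2500)))   # empty window is a gap
  ok$rightward[1] <- -1
  expect_error(compute_rfd(ok), "negative")
})

test_that("replication strand follows the fork-direction rule and involutes", {
  expect_equal(replication_strand("C", 0.8), "lagging")
  expect_equal(replication_strand("C", -0.8), "leading")
  expect_equal(replication_strand("C", 0), "unassigned")
  expect_equal(replication_strand("G", 0.8), "leading")  # pyrimidine on minus
  # complementing the reference base flips the call
  for (b in c("A", "C", "G", "T")) {
    for (r in c(-0.5, 0.5)) {
      a <- replication_strand(b, r)
      bcomp <- chartr("ACGT", "TGCA", b)
      expect_equal(replication_strand(bcomp, r),
                   setNames(c("lagging", "leading"),
                            c("leading", "lagging"))[[a]])
    }
  }
})

test_that("transcription strand distinguishes template, ambiguous, intergenic", {
  genes <- data.frame(chrom = "chr1", start = c(100, 400, 450),
                      end = c(500, 800, 470),
                      gene_id = c("gp", "gm", "gp2"),
                      strand = c("+", "-", "+"))
  # C on plus strand inside plus-strand gene: template is minus
  expect_equal(transcription_strand("chr1", 200, "C", genes), "untranscribed")
  expect_equal(transcription_strand("chr1", 700, "C", genes), "transcribed")
  expect_equal(transcription_strand("chr1", 460, "C", genes), "ambiguous")
  expect_equal(transcription_strand("chr1", 900, "C", genes), "intergenic")
  # purine ref flips the call relative to the pyrimidine case
  expect_equal(transcription_strand("chr1", 200, "G", genes), "transcribed")
  expect_equal(transcription_strand("chr1", 700, "G", genes), "untranscribed")
})

test_that("strand bias test matches the closed-form one-df chi-square", {
  t0 <- strand_bias_test(50, 50)
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  t1 <- strand_bias_test(60, 40)
  expect_equal(t1$chi2, 4.0)
  expect_equal(t1$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t1$p, 0.0455, tolerance = 1e-3)
  expect_error(strand_bias_test(0, 0), "no mutations")
})

test_that("replication-linked bias masquerades as transcription bias outside the neutral RFD stratum", {
  # planted confounding: mutation strand depends solely on RFD sign, and
  # genes are placed co-directional with the local fork
  L <- 200000
  ff <- gen_fork_field(L, wavelength = 50000, reads_per_window = 500,
                       seed = 33)
  tr <- compute_rfd(ff$ok_counts)
  set.seed(34)
  pos <- sample(2000:(L - 2000), 3000)
  rfd <- rfd_at(tr, "chr1", pos)
  # T>C mutations whose pyrimidine strand follows the local fork direction
  # with fidelity proportional to the fork preference: regions of weak
  # preference host forks of both directions, diluting the strand link
  s_true <- ff$rfd_true_fun(pos)
  lagging_plus <- runif(length(pos)) < (1 + s_true) / 2
  ref <- ifelse(lagging_plus, "T", "A")
  alt <- ifelse(lagging_plus, "C", "G")
  rec <- mutation_records("s", "chr1", pos, ref, alt, vaf = 0.5)
  # genes co-directional with forks: plus-strand genes where RFD > 0
  starts <- seq(1, L - 10000, by = 10000)
  gstrand <- ifelse(ff$rfd_true_fun(starts + 5000) > 0, "+", "-")
  genes <- data.frame(chrom = "chr1", start = starts, end = starts + 9999,
                      gene_id = paste0("g", seq_along(starts)),
                      strand = gstrand)
  res <- rfd_stratified_bias(rec, tr, genes)
  res_tc <- res[res$sbs_class == "T>C", ]
  side <- res_tc[grepl("RFD<=|RFD>=", res_tc$stratum), ]
  mid <- res_tc[grepl("<RFD<", res_tc$stratum), ]
  # strong apparent bias in the strong-RFD strata
  expect_true(all(side$p < 1e-6))
  # counts across strata sum to all strand-assignable assigned mutations
  total <- sum(res$transcribed + res$untranscribed)
  ann <- annotate_context(rec, rfd_track = tr, genes = genes)
  expect_equal(total, sum(!is.na(ann$rfd) & ann$transcription_strand %in%
                            c("transcribed", "untranscribed")))
  # the neutral stratum shows no such bias (balanced counts)
  if (mid$transcribed + mid$untranscribed > 0) {
    expect_gt(mid$p, 0.001)
  }
})

test_that("genic and intergenic densities use the interval union", {
  genes <- data.frame(chrom = "chr1", start = c(1, 200, 100),
                      end = c(300, 600, 250),
                      gene_id = c("a", "b", "c"), strand = c("+", "-", "+"))
  rec <- mutation_records(rep("s", 4), "chr1", c(50, 250, 590, 900),
                          "C", "T", vaf = 0.5)
  d <- genic_density(rec, genes, c(chr1 = 1000))
  # union is [1,600]: 600 bp genic, 400 bp intergenic
  expect_equal(d$length_bp, c(600, 400))
  expect_equal(d$mutations, c(3, 1))
  expect_equal(d$density_per_mb, c(3 / 6e-4, 1 / 4e-4))

  # uniform mutations: genic and intergenic densities agree within 10%
  set.seed(55)
  L <- 100000
  gstart <- seq(1, L - 5000, by = 10000)
  genes2 <- data.frame(chrom = "chr1", start = gstart, end = gstart + 2999,
                       gene_id = paste0("g", seq_along(gstart)),
                       strand = "+")
  rec2 <- mutation_records(rep("s", 10000), "chr1", sample.int(L, 10000),
                           "C", "T", vaf = 0.5)
  d2 <- genic_density(rec2, genes2, c(chr1 = L))
  expect_lt(abs(d2$density_per_mb[1] / d2$density_per_mb[2] - 1), 0.1)
  expect_error(genic_density(rec2, genes2[0, ], c(chr1 = L)), "territory")
})
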