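# isogenic unique-mutation calling, Fisher scoring and threshold calibration

make_counts <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], chrom = r[[2]], pos = as.numeric(r[[3]]),
               ref = r[[4]], cov = as.numeric(r[[5]]),
               nA = as.numeric(r[[6]]), nC = as.numeric(r[[7]]),
               nG = as.numeric(r[[8]]), nT = as.numeric(r[[9]]),
               n_ins = as.numeric(r[[10]]), n_del = as.numeric(r[[11]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("candidate filter applies the three inequalities", {
  # 4 samples; s1 carries 10 alt reads of 20 at a C site
  tab <- make_counts(
    list("s1", "chr1", 100, "C", 20, 10, 10, 0, 0, 0, 0),
    list("s2", "chr1", 100, "C", 20, 0, 20, 0, 0, 0, 0),
    list("s3", "chr1", 100, "C", 20, 0, 20, 0, 0, 0, 0),
    list("s4", "chr1", 100, "C", 20, 0, 20, 0, 0, 0, 0))
  rec <- call_candidates(tab)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$sample_id, "s1")
  expect_equal(rec$vaf, 0.5)
  expect_equal(rec$alt, "A")

  # all pure reference: nothing
  tab$nA[1] <- 0; tab$nC[1] <- 20
  expect_equal(nrow(call_candidates(tab)), 0)

  # another sample's reference AF below 0.93 vetoes the call
  tab2 <- make_counts(
    list("s1", "chr1", 100, "C", 20, 10, 10, 0, 0, 0, 0),
    list("s2", "chr1", 100, "C", 30, 3, 27, 0, 0, 0, 0),  # ref AF 0.90
    list("s3", "chr1", 100, "C", 20, 0, 20, 0, 0, 0, 0))
  expect_equal(nrow(call_candidates(tab2)), 0)

  # reference mismatch between rows is a validation error
  tab3 <- tab
  tab3$ref[2] <- "T"; tab3$nT[2] <- 20; tab3$nC[2] <- 0
  expect_error(call_candidates(tab3), "mismatch")
})

test_that("candidate filter equals the literal three-inequality oracle", {
  set.seed(202)
  samples <- paste0("s", 1:4)
  n_pos <- 600
  rows <- expand.grid(sample = samples, pos = seq_len(n_pos),
                      stringsAsFactors = FALSE)
  refs <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
  rows$chrom <- "chr1"
  rows$ref <- refs[rows$pos]
  cov <- rpois(nrow(rows), 25)
  # noisy background plus scattered planted alleles of every kind
  alt <- rbinom(nrow(rows), cov, 0.02)
  alt[sample.int(nrow(rows), 80)] <- rbinom(80, 25, 0.5)
  altbase <- vapply(rows$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  rows$cov <- cov
  for (b in c("A", "C", "G", "T")) rows[[paste0("n", b)]] <- 0
  for (i in seq_len(nrow(rows))) {
    rows[[paste0("n", altbase[i])]][i] <- min(alt[i], cov[i])
    rows[[paste0("n", rows$ref[i])]][i] <-
      cov[i] - rows[[paste0("n", altbase[i])]][i]
  }
  rows$n_ins <- rbinom(nrow(rows), 3, 0.05)
  rows$n_del <- rbinom(nrow(rows), 3, 0.05)
  got <- call_candidates(rows)
  want <- oracle_filter(rows)
  got_key <- sort(paste(got$sample_id, got$pos))
  want_key <- sort(paste(want$sample_id, want$pos))
  expect_identical(got_key, want_key)
  # no position yields records for two samples
  expect_false(any(duplicated(paste(got$chrom, got$pos))))
})

test_that("fisher score equals direct hypergeometric tail enumeration", {
  for (cm in c(5, 12, 20)) {
    for (co in c(5, 14, 20)) {
      for (am in 0:cm) {
        for (ao in c(0, 1, 3)) {
          if (ao > co) next
          p <- oracle_fisher_p(am, cm, ao, co)
          s <- as.numeric(fisher_score(am, cm, ao, co))
          expect_equal(s, max(0, -log10(p)), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("fisher score is monotone in the mutant alt count and flags degenerate input", {
  s <- as.numeric(fisher_score(0:20, rep(20, 21), rep(0, 21), rep(20, 21)))
  expect_true(all(diff(s) >= 0))
  d <- fisher_score(0, 0, 5, 20)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
  expect_error(fisher_score(21, 20, 0, 20), "exceed")
})

test_that("threshold calibration scans observed scores and bounds ancestral calls", {
  anc <- data.frame(ancestor = "anc", descendant = "d1")
  # ancestor clean: minimal candidate threshold (0) is returned
  rec <- mutation_records(rep("d1", 5), "chr1", 1:5, "C", "T",
                          vaf = 0.5, score = c(1, 2, 3, 4, 5))
  expect_equal(calibrate_threshold(rec, anc, "SBS"), 0)

  # synthetic scores: ancestor {4, 2}, descendant 300 calls with scores >= 3
  set.seed(1)
  rec2 <- mutation_records(
    c(rep("anc", 2), rep("d1", 300)), "chr1", 1:302, "C", "T", vaf = 0.5,
    score = c(4, 2, runif(300, 3, 10)))
  got <- calibrate_threshold(rec2, anc, "SBS")
  # brute-force scan over candidate thresholds
  cand <- sort(unique(c(0, rec2$score)))
  ok <- vapply(cand, function(t) {
    na <- sum(rec2$score >= t & rec2$sample_id == "anc")
    nd <- sum(rec2$score >= t & rec2$sample_id == "d1")
    na <= 0.01 * nd
  }, logical(1))
  expect_equal(got, min(cand[ok]))
  # at the calibrated threshold the 1% bound holds
  surv_a <- sum(rec2$score >= got & rec2$sample_id == "anc")
  surv_d <- sum(rec2$score >= got & rec2$sample_id == "d1")
  expect_lte(surv_a, 0.01 * surv_d)

  # indel calibration caps absolute ancestral events
  rec3 <- mutation_records(
    c(rep("anc", 8), rep("d1", 10)), "chr1", 1:18,
    rep("CA", 18), rep("C", 18), vaf = 0.5,
    score = c(1:8 / 2, rep(9, 10)))
  thr <- calibrate_threshold(rec3, anc, "DEL")
  expect_lte(sum(rec3$score >= thr & rec3$sample_id == "anc"), 5)

  # impossible constraint: +Inf with a warning
  rec4 <- mutation_records(rep("anc", 3), "chr1", 1:3, "C", "T",
                           vaf = 0.5, score = c(5, 5, 5))
  anc4 <- data.frame(ancestor = "anc", descendant = "d1")
  rec4b <- rbind(rec4, mutation_records("d1", "chr1", 9, "CA", "C",
                                        vaf = 0.5, score = 1))
  expect_warning(thr4 <- calibrate_threshold(rec4b, anc4, "SBS"), "Inf")
  expect_equal(thr4, Inf)
})

test_that("identical inputs give byte-identical VCF output", {
  g <- gen_genome(5000, seed = 31)
  sim <- gen_isogenic_counts(g, n_descendants = 2, n_sbs = 20, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(call_mutations(sim$counts)$records, f1)
  write_vcf(call_mutations(sim$counts)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 7)
})

test_that("calibrated calling recovers planted mutations with high precision", {
  g <- gen_genome(30000, seed = 3)
  sim <- gen_isogenic_counts(g, n_descendants = 3, n_sbs = 50, n_ins = 5,
                             n_del = 5, seed = 7)
  res <- call_mutations(sim$counts, ancestry = sim$ancestry)
  tr <- paste(sim$truth$sample_id, sim$truth$pos)
  cl <- paste(res$records$sample_id, res$records$pos)
  expect_gte(mean(tr %in% cl), 0.95)
  expect_gte(mean(cl %in% tr), 0.99)
})
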