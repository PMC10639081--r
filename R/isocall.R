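# IsoMut-style unique-mutation calling within an isogenic sample set.
#
# A candidate is emitted for sample s at a position iff (i) s's most frequent
# non-reference allele has frequency >= min_alt_vaf, (ii) s's coverage is
# >= min_cov, and (iii) every other sample's reference-allele frequency is
# >= min_other_ref_af (coverage 0 fails the test: absence of evidence must not
# support a unique call). Candidates are scored with a one-tailed Fisher exact
# probability against the other sample with the lowest reference-allele
# frequency, and score thresholds are either fixed or calibrated against
# ancestral clones.

#' Caller configuration
#'
#' Defaults reproduce an optimised isogenic-WGS filter set: minimum mutated
#' allele frequency 0.2, minimum coverage 5, minimum reference allele
#' frequency of all other samples 0.93, Fisher-score thresholds 3.5 (SBS),
#' 2.1 (insertions), 3.1 (deletions), and ancestral false-positive bounds of
#' 1% of each descendant's SBS count or at most 5 indel events.
#'
#' @param min_alt_vaf minimum variant allele frequency in the mutated sample.
#' @param min_cov minimum coverage of the mutated sample.
#' @param min_other_ref_af minimum reference allele frequency in every other
#'   sample.
#' @param score_threshold_sbs,score_threshold_ins,score_threshold_del
#'   per-class Fisher-score thresholds.
#' @param ancestral_fp_fraction calibration bound: ancestral SBS calls may not
#'   exceed this fraction of any descendant's calls.
#' @param ancestral_indel_cap calibration bound: maximum ancestral indel calls.
#' @return a list of class `caller_config`.
#' @export
caller_config <- function(min_alt_vaf = 0.2, min_cov = 5L,
                          min_other_ref_af = 0.93,
                          score_threshold_sbs = 3.5,
                          score_threshold_ins = 2.1,
                          score_threshold_del = 3.1,
                          ancestral_fp_fraction = 0.01,
                          ancestral_indel_cap = 5L) {
  cfg <- list(min_alt_vaf = min_alt_vaf, min_cov = min_cov,
              min_other_ref_af = min_other_ref_af,
              score_threshold_sbs = score_threshold_sbs,
              score_threshold_ins = score_threshold_ins,
              score_threshold_del = score_threshold_del,
              ancestral_fp_fraction = ancestral_fp_fraction,
              ancestral_indel_cap = ancestral_indel_cap)
  stopifnot(cfg$min_alt_vaf > 0, cfg$min_alt_vaf <= 1,
            cfg$min_other_ref_af > 0, cfg$min_other_ref_af <= 1,
            cfg$min_cov >= 0,
            cfg$score_threshold_sbs >= 0, cfg$score_threshold_ins >= 0,
            cfg$score_threshold_del >= 0,
            cfg$ancestral_fp_fraction >= 0, cfg$ancestral_indel_cap >= 0)
  class(cfg) <- "caller_config"
  cfg
}

ALLELE_CODES <- c("A", "C", "G", "T", "INS", "DEL")

#' Fisher quality score for a candidate mutation
#'
#' The score is `-log10` of the one-tailed Fisher exact probability
#' (hypergeometric upper tail) that the mutated sample's alt count is as or
#' more extreme on the 2x2 table `[alt, ref] x [mutated, other]`, where the
#' other sample is the non-called sample with the lowest reference allele
#' frequency at the position. Zero coverage in either sample yields score 0
#' (flagged in the `"degenerate"` attribute).
#'
#' @param alt_mut,cov_mut alt count and coverage of the mutated sample.
#' @param alt_other,cov_other alt count and coverage of the comparison sample.
#' @return non-negative numeric scores (vectorised).
#' @export
fisher_score <- function(alt_mut, cov_mut, alt_other, cov_other) {
  n <- length(alt_mut)
  stopifnot(length(cov_mut) == n, length(alt_other) == n,
            length(cov_other) == n)
  if (any(alt_mut > cov_mut | alt_other > cov_other)) {
    stop("alt counts exceed coverage")
  }
  if (any(alt_mut < 0 | alt_other < 0 | cov_mut < 0 | cov_other < 0)) {
    stop("negative counts")
  }
  deg <- cov_mut == 0 | cov_other == 0
  m <- alt_mut + alt_other                      # total alt reads
  nn <- (cov_mut - alt_mut) + (cov_other - alt_other)  # total ref reads
  lp <- stats::phyper(alt_mut - 1, m, nn, cov_mut,
                      lower.tail = FALSE, log.p = TRUE)
  s <- pmax(0, -lp / log(10))
  s[deg] <- 0
  attr(s, "degenerate") <- deg
  s
}

#' Call candidate unique mutations from an isogenic counts table
#'
#' Applies the three filter inequalities (see module notes) at every position
#' present in the table; positions missing a row for some sample are treated
#' as coverage 0 for that sample, which fails the reference-frequency test.
#' Exactly one alternate allele (the most frequent; ties broken A < C < G < T
#' then INS, DEL) is reported per record, with VAF and Fisher score attached.
#' Indel alleles are represented with anchored placeholder sequences since
#' count tables do not carry inserted/deleted bases.
#'
#' @param counts counts data frame (see [read_counts_table()]).
#' @param cfg a [caller_config()].
#' @return mutation-record data frame sorted by (chrom, pos).
#' @export
call_candidates <- function(counts, cfg = caller_config()) {
  validate_counts(counts)
  empty <- mutation_records(character(0), character(0), integer(0),
                            character(0), character(0))
  if (nrow(counts) == 0L) return(empty)
  counts$ref <- toupper(counts$ref)
  key <- paste(counts$chrom, counts$pos, sep = "\r")
  ukey <- unique(key)
  usam <- sort(unique(counts$sample))
  nk <- length(ukey)
  ns <- length(usam)
  i <- match(key, ukey)
  j <- match(counts$sample, usam)
  kchrom <- counts$chrom[!duplicated(key)]
  kpos <- counts$pos[!duplicated(key)]
  refs <- counts$ref[!duplicated(key)]
  mism <- which(counts$ref != refs[i])
  if (length(mism)) {
    stop("reference base mismatch between rows at ",
         counts$chrom[mism[1]], ":", counts$pos[mism[1]])
  }
  fill <- function(col) {
    m <- matrix(0, nk, ns)
    m[cbind(i, j)] <- counts[[col]]
    m
  }
  cov <- fill("cov")
  arr <- array(0, dim = c(nk, ns, 6L))
  for (b in 1:4) arr[, , b] <- fill(paste0("n", BASES[b]))
  arr[, , 5] <- fill("n_ins")
  arr[, , 6] <- fill("n_del")
  refidx <- match(refs, BASES)
  nref <- matrix(0, nk, ns)
  for (b in 1:4) {
    rows <- refidx == b
    if (any(rows)) nref[rows, ] <- arr[rows, , b, drop = FALSE]
  }
  nonref_bases <- arr[, , 1] + arr[, , 2] + arr[, , 3] + arr[, , 4] - nref
  ref_support <- pmax(cov - nonref_bases - arr[, , 5] - arr[, , 6], 0)
  refaf <- ifelse(cov > 0, ref_support / cov, 0)
  # candidate alt allele per (position, sample): mask the reference base
  cand <- arr
  for (b in 1:4) {
    rows <- refidx == b
    if (any(rows)) cand[rows, , b] <- -1
  }
  flat <- matrix(cand, nk * ns, 6L)
  top <- max.col(flat, ties.method = "first")
  topcount <- matrix(flat[cbind(seq_len(nk * ns), top)], nk, ns)
  topallele <- matrix(top, nk, ns)
  vaf <- ifelse(cov > 0, pmax(topcount, 0) / cov, 0)
  fail <- refaf < cfg$min_other_ref_af
  nfail <- rowSums(fail)
  others_ok <- (nfail - fail) == 0          # failures among the other samples
  hit <- topcount > 0 & vaf >= cfg$min_alt_vaf & cov >= cfg$min_cov &
    others_ok
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  k <- idx[, 1]
  s <- idx[, 2]
  code <- topallele[cbind(k, s)]
  refb <- refs[k]
  alt <- ifelse(code <= 4, ALLELE_CODES[code],
                ifelse(code == 5L, paste0(refb, "N"), refb))
  ref_out <- ifelse(code == 6L, paste0(refb, "N"), refb)
  # worst other sample: lowest reference allele frequency
  refaf_self <- refaf
  refaf_self[cbind(k, s)] <- Inf
  worst <- integer(nrow(idx))
  for (r in seq_along(k)) {
    worst[r] <- which.min(refaf_self[k[r], ])
  }
  alt_other <- arr[cbind(k, worst, code)]
  score <- fisher_score(topcount[cbind(k, s)], cov[cbind(k, s)],
                        alt_other, cov[cbind(k, worst)])
  rec <- mutation_records(usam[s], kchrom[k], kpos[k], ref_out, alt,
                          vaf = vaf[cbind(k, s)],
                          score = as.numeric(score))
  rec[order(rec$chrom, rec$pos, rec$sample_id), , drop = FALSE]
}

#' Filter scored calls at per-class score thresholds
#'
#' @param records mutation-record data frame with scores.
#' @param thresholds named numeric vector with elements `SBS`, `INS`, `DEL`
#'   (or a [caller_config()], whose per-class thresholds are used).
#' @return the surviving records.
#' @export
apply_score_thresholds <- function(records, thresholds = caller_config()) {
  if (inherits(thresholds, "caller_config")) {
    thresholds <- c(SBS = thresholds$score_threshold_sbs,
                    INS = thresholds$score_threshold_ins,
                    DEL = thresholds$score_threshold_del)
  }
  keep <- records$score >= thresholds[records$mut_class]
  records[keep, , drop = FALSE]
}

#' Calibrate a score threshold against ancestral clones
#'
#' Scans the sorted set of observed scores (plus 0) for the minimal threshold
#' at which, for SBS, every ancestor's surviving call count is at most
#' `ancestral_fp_fraction` times each of its descendants' surviving counts;
#' for INS/DEL, every ancestor's surviving count is at most
#' `ancestral_indel_cap`. Surviving means `score >= threshold`.
#'
#' @param records scored mutation-record data frame (all classes; the class
#'   of interest is selected internally).
#' @param ancestry data frame with columns `ancestor`, `descendant`.
#' @param mut_class `"SBS"`, `"INS"` or `"DEL"`.
#' @param cfg a [caller_config()] providing the calibration bounds.
#' @return the calibrated threshold (`+Inf` with a warning when no threshold
#'   satisfies the constraint).
#' @export
calibrate_threshold <- function(records, ancestry, mut_class,
                                cfg = caller_config()) {
  stopifnot(nrow(ancestry) > 0,
            all(c("ancestor", "descendant") %in% names(ancestry)))
  mut_class <- match.arg(mut_class, c("SBS", "INS", "DEL"))
  sel <- records$mut_class == mut_class
  sc <- records$score[sel]
  sample_of <- records$sample_id[sel]
  cand <- sort(unique(c(0, sc)))
  samples <- unique(c(ancestry$ancestor, ancestry$descendant,
                      sample_of))
  for (t in cand) {
    cnt <- stats::setNames(numeric(length(samples)), samples)
    surv <- table(sample_of[sc >= t])
    cnt[names(surv)] <- as.numeric(surv)
    ok <- if (mut_class == "SBS") {
      all(cnt[ancestry$ancestor] <=
            cfg$ancestral_fp_fraction * cnt[ancestry$descendant])
    } else {
      all(cnt[unique(ancestry$ancestor)] <= cfg$ancestral_indel_cap)
    }
    if (ok) return(t)
  }
  warning("no threshold bounds the ancestral calls; returning +Inf")
  Inf
}

#' Call unique mutations end to end
#'
#' Generates candidates, then filters them at fixed per-class score
#' thresholds, or at thresholds calibrated against ancestral clones when an
#' ancestry map is supplied.
#'
#' @param counts counts data frame.
#' @param cfg a [caller_config()].
#' @param ancestry optional data frame with columns `ancestor`, `descendant`;
#'   when given, thresholds are calibrated per class instead of fixed.
#' @return list with elements `records` (filtered calls) and `thresholds`
#'   (named per-class vector used).
#' @export
call_mutations <- function(counts, cfg = caller_config(), ancestry = NULL) {
  cand <- call_candidates(counts, cfg)
  if (is.null(ancestry)) {
    thr <- c(SBS = cfg$score_threshold_sbs,
             INS = cfg$score_threshold_ins,
             DEL = cfg$score_threshold_del)
  } else {
    thr <- c(SBS = calibrate_threshold(cand, ancestry, "SBS", cfg),
             INS = calibrate_threshold(cand, ancestry, "INS", cfg),
             DEL = calibrate_threshold(cand, ancestry, "DEL", cfg))
  }
  list(records = apply_score_thresholds(cand, thr), thresholds = thr)
}
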