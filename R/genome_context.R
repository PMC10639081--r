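# Replication timing, replication fork directionality (RFD), transcription
# and genic context of mutations, with strand-bias statistics.
#
# Conventions: the timing-score orientation of the source tracks (higher =
# earlier) is preserved and decile 1 is the earliest-replicating; positive RFD
# means a rightward-moving fork, in which case the plus (sense) strand is the
# lagging-strand template's complement, i.e. the nascent lagging strand copies
# the plus strand. Strand calls are made with the mutation expressed on the
# pyrimidine strand.

#' Replication-timing score at loci
#'
#' Linear interpolation between the nearest track points, clamped to the
#' first/last point beyond the track ends.
#'
#' @param track a timing [genomic_track()].
#' @param chrom chromosome name.
#' @param pos positions (vectorised).
#' @return numeric scores; `NA` when the chromosome is absent from the track.
#' @export
timing_at <- function(track, chrom, pos) {
  tr <- track$data[[chrom]]
  if (is.null(tr)) return(rep(NA_real_, length(pos)))
  if (nrow(tr) == 1L) return(rep(tr$value, length(pos)))
  stats::approx(tr$pos, tr$value, xout = pos, rule = 2)$y
}

#' Decile cut points of a reference score set
#'
#' @param scores numeric vector of at least 10 values with at least 10
#'   distinct values.
#' @return the 9 empirical quantiles at probabilities 0.1..0.9.
#' @export
decile_bins <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(unique(scores)) < 10L) {
    stop("need at least 10 distinct scores to form deciles")
  }
  stats::quantile(scores, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
}

#' Assign scores to deciles
#'
#' Bins are left-closed at the cut points; with the source-track orientation
#' (higher score = earlier replication) decile 10 holds the highest scores.
#'
#' @param score numeric scores.
#' @param cuts the 9 cut points from [decile_bins()].
#' @return integer deciles 1..10 (`NA` for `NA` scores).
#' @export
assign_decile <- function(score, cuts) {
  out <- findInterval(score, cuts) + 1L
  out[!is.finite(score)] <- NA_integer_
  out
}

#' Compute replication fork directionality from OK-seq window counts
#'
#' `RFD = (R - L) / (R + L)` per window; windows without reads give a missing
#' value and are dropped from the track (their number is reported in the
#' `n_missing` attribute).
#'
#' @param ok_counts data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open windows) and `rightward`, `leftward` read counts.
#' @return an RFD [genomic_track()] with points at window midpoints.
#' @export
compute_rfd <- function(ok_counts) {
  stopifnot(all(c("chrom", "start", "end", "rightward", "leftward") %in%
                  names(ok_counts)))
  if (any(ok_counts$rightward < 0 | ok_counts$leftward < 0)) {
    stop("negative read counts")
  }
  tot <- ok_counts$rightward + ok_counts$leftward
  rfd <- ifelse(tot > 0, (ok_counts$rightward - ok_counts$leftward) / tot,
                NA_real_)
  keep <- !is.na(rfd)
  ws <- unique(ok_counts$end - ok_counts$start)
  tr <- genomic_track(
    data.frame(chrom = ok_counts$chrom[keep],
               pos = (ok_counts$start[keep] + ok_counts$end[keep]) / 2,
               value = rfd[keep]),
    kind = "rfd",
    window_size = if (length(ws) == 1L) ws else NULL)
  attr(tr, "n_missing") <- sum(!keep)
  tr
}

#' RFD value at loci (window lookup)
#'
#' Returns the value of the window whose midpoint is nearest, provided the
#' locus falls inside that window; `NA` otherwise.
#'
#' @param track an RFD [genomic_track()].
#' @param chrom chromosome name.
#' @param pos positions (vectorised).
#' @return numeric RFD values with `NA` for uncovered loci.
#' @export
rfd_at <- function(track, chrom, pos) {
  tr <- track$data[[chrom]]
  if (is.null(tr)) return(rep(NA_real_, length(pos)))
  half <- attr(track, "window_size")
  half <- if (is.null(half)) Inf else half / 2
  i <- findInterval(pos, tr$pos)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, nrow(tr))
  pick <- ifelse(abs(pos - tr$pos[lo]) <= abs(pos - tr$pos[hi]), lo, hi)
  val <- tr$value[pick]
  val[abs(pos - tr$pos[pick]) > half] <- NA_real_
  val
}

#' Replication-strand assignment of mutations
#'
#' With the mutation expressed on the pyrimidine strand: a pyrimidine on the
#' plus strand under a rightward fork (RFD > 0) lies on the lagging strand; a
#' leftward fork flips the call, as does a pyrimidine on the minus strand.
#' RFD of exactly 0 or missing gives `"unassigned"`.
#'
#' @param ref reference base of each SBS (determines the pyrimidine strand).
#' @param rfd RFD value at each mutation.
#' @return character vector: `"leading"`, `"lagging"` or `"unassigned"`.
#' @export
replication_strand <- function(ref, rfd) {
  pyr_plus <- toupper(ref) %in% c("C", "T")
  out <- ifelse(is.na(rfd) | rfd == 0, "unassigned",
                ifelse(xor(pyr_plus, rfd < 0), "lagging", "leading"))
  out
}

#' Transcription-strand assignment of mutations
#'
#' With the mutation on the pyrimidine strand: inside a gene footprint on a
#' single strand, the pyrimidine lying on the template (transcribed) strand
#' gives `"transcribed"`, otherwise `"untranscribed"`; positions covered by
#' genes on both strands are `"ambiguous"`, positions outside all genes
#' `"intergenic"`.
#'
#' @param chrom,pos,ref mutation coordinates and reference base (vectorised).
#' @param genes gene intervals (see [read_genes_bed()]).
#' @return character vector of strand labels.
#' @export
transcription_strand <- function(chrom, pos, ref, genes) {
  out <- rep("intergenic", length(pos))
  pyr_plus <- toupper(ref) %in% c("C", "T")
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- genes[genes$chrom == ch, , drop = FALSE]
    up <- interval_union(g$start[g$strand == "+"], g$end[g$strand == "+"])
    um <- interval_union(g$start[g$strand == "-"], g$end[g$strand == "-"])
    inp <- point_in_union(pos[sel], up)
    inm <- point_in_union(pos[sel], um)
    lab <- rep("intergenic", sum(sel))
    lab[inp & inm] <- "ambiguous"
    # gene on plus strand: template is the minus strand
    one_p <- inp & !inm
    one_m <- inm & !inp
    lab[one_p] <- ifelse(pyr_plus[sel][one_p], "untranscribed", "transcribed")
    lab[one_m] <- ifelse(pyr_plus[sel][one_m], "transcribed", "untranscribed")
    out[sel] <- lab
  }
  out
}

#' Chi-square test for strand bias
#'
#' One-degree-of-freedom goodness-of-fit test of the two strand counts
#' against an expected 50:50 split.
#'
#' @param n_strand1,n_strand2 mutation counts on the two strands.
#' @return list with elements `chi2` and `p` (two-sided).
#' @export
strand_bias_test <- function(n_strand1, n_strand2) {
  if (n_strand1 + n_strand2 <= 0) stop("no mutations to test")
  ht <- suppressWarnings(stats::chisq.test(c(n_strand1, n_strand2),
                                           p = c(0.5, 0.5)))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Annotate SBS mutations with replication/transcription context
#'
#' @param records SBS mutation-record data frame.
#' @param timing_track timing [genomic_track()] (optional).
#' @param rfd_track RFD [genomic_track()] (optional).
#' @param genes gene intervals (optional).
#' @param decile_cuts optional decile cut points for the timing scores; when
#'   omitted they are computed from the timing track's own points.
#' @return the records with added columns `timing_score`, `timing_decile`,
#'   `rfd`, `replication_strand`, `transcription_strand`, `sbs_class`.
#' @export
annotate_context <- function(records, timing_track = NULL, rfd_track = NULL,
                             genes = NULL, decile_cuts = NULL) {
  out <- records
  out$sbs_class <- ifelse(out$mut_class == "SBS",
                          sbs_class(out$ref, out$alt), NA_character_)
  if (!is.null(timing_track)) {
    sc <- rep(NA_real_, nrow(out))
    for (ch in unique(out$chrom)) {
      sel <- out$chrom == ch
      sc[sel] <- timing_at(timing_track, ch, out$pos[sel])
    }
    out$timing_score <- sc
    if (is.null(decile_cuts)) {
      decile_cuts <- decile_bins(unlist(lapply(timing_track$data,
                                               function(d) d$value)))
    }
    out$timing_decile <- assign_decile(sc, decile_cuts)
  }
  if (!is.null(rfd_track)) {
    rv <- rep(NA_real_, nrow(out))
    for (ch in unique(out$chrom)) {
      sel <- out$chrom == ch
      rv[sel] <- rfd_at(rfd_track, ch, out$pos[sel])
    }
    out$rfd <- rv
    out$replication_strand <- replication_strand(out$ref, rv)
  }
  if (!is.null(genes)) {
    out$transcription_strand <- transcription_strand(out$chrom, out$pos,
                                                     out$ref, genes)
  }
  out
}

#' Transcription-strand bias stratified by RFD
#'
#' Partitions SBS mutations into RFD strata (boundary values fall in the
#' flanking strata; the middle stratum is the open interval), then counts
#' transcribed/untranscribed mutations per substitution class within each
#' stratum and tests each against 50:50. Ambiguous and intergenic mutations
#' are excluded from the tests.
#'
#' @param records SBS mutation records.
#' @param rfd_track RFD [genomic_track()].
#' @param genes gene intervals.
#' @param lower,upper RFD stratum boundaries (default -0.5 / 0.5).
#' @return data frame: stratum, sbs_class, transcribed, untranscribed,
#'   chi2, p (tests `NA` where a cell is empty).
#' @export
rfd_stratified_bias <- function(records, rfd_track, genes,
                                lower = -0.5, upper = 0.5) {
  ann <- annotate_context(records, rfd_track = rfd_track, genes = genes)
  ann <- ann[ann$mut_class == "SBS" & !is.na(ann$rfd), , drop = FALSE]
  ann$stratum <- ifelse(ann$rfd <= lower, sprintf("RFD<=%g", lower),
                        ifelse(ann$rfd >= upper, sprintf("RFD>=%g", upper),
                               sprintf("%g<RFD<%g", lower, upper)))
  strata <- c(sprintf("RFD<=%g", lower),
              sprintf("%g<RFD<%g", lower, upper),
              sprintf("RFD>=%g", upper))
  res <- expand.grid(stratum = strata, sbs_class = SBS_CLASSES,
                     stringsAsFactors = FALSE)
  res$transcribed <- 0L
  res$untranscribed <- 0L
  res$chi2 <- NA_real_
  res$p <- NA_real_
  use <- ann$transcription_strand %in% c("transcribed", "untranscribed")
  for (r in seq_len(nrow(res))) {
    sel <- use & ann$stratum == res$stratum[r] &
      ann$sbs_class == res$sbs_class[r]
    nt <- sum(ann$transcription_strand[sel] == "transcribed")
    nu <- sum(ann$transcription_strand[sel] == "untranscribed")
    res$transcribed[r] <- nt
    res$untranscribed[r] <- nu
    if (nt + nu > 0) {
      tst <- strand_bias_test(nt, nu)
      res$chi2[r] <- tst$chi2
      res$p[r] <- tst$p
    }
  }
  res
}

#' Mutation density in genic versus intergenic territory
#'
#' Gene footprints are merged into a strandless union; densities are per
#' megabase of territory. Overlapping transcripts double-count neither
#' territory nor mutations.
#'
#' @param records mutation records.
#' @param genes gene intervals.
#' @param genome_length named vector of chromosome lengths (or a single total
#'   when all intervals/mutations share one chromosome).
#' @return data frame with rows `genic` and `intergenic`: territory length
#'   (bp), mutation count and density per Mb.
#' @export
genic_density <- function(records, genes, genome_length) {
  if (is.null(names(genome_length))) {
    chroms <- unique(c(records$chrom, genes$chrom))
    if (length(chroms) > 1 || length(genome_length) != 1) {
      stop("genome_length must be named per chromosome")
    }
    names(genome_length) <- chroms
  }
  genic_len <- 0
  n_genic <- 0L
  total_len <- sum(genome_length)
  for (ch in names(genome_length)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    un <- interval_union(g$start, g$end)
    genic_len <- genic_len + sum(un$end - un$start + 1)
    n_genic <- n_genic +
      sum(point_in_union(records$pos[records$chrom == ch], un))
  }
  inter_len <- total_len - genic_len
  if (genic_len <= 0 || inter_len <= 0) {
    stop("zero genic or intergenic territory")
  }
  n_inter <- nrow(records) - n_genic
  data.frame(
    territory = c("genic", "intergenic"),
    length_bp = c(genic_len, inter_len),
    mutations = c(n_genic, n_inter),
    density_per_mb = c(n_genic / (genic_len / 1e6),
                       n_inter / (inter_len / 1e6))
  )
}
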