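# Synthetic-data generators with planted ground truth for every pipeline
# stage: toy genomes, isogenic allele-count tables, signature-mixture
# mutation catalogs, replication fork/timing fields, VAF mixtures, and a
# two-condition cohort emulating the 60-day low/high oxygen culture design.
# Every generator is a pure function of its arguments (seed included).

#' Generate a random toy genome
#'
#' @param length genome length in bp (>= 1000).
#' @param gc_fraction target GC content in \[0, 1\].
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return named character vector with one chromosome sequence.
#' @export
gen_genome <- function(length, gc_fraction = 0.4, seed = 1L,
                       chrom = "chr1") {
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0,1]")
  if (length < 1000) stop("genome length must be >= 1000")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  stats::setNames(paste(sample(BASES, length, replace = TRUE, prob = p),
                        collapse = ""), chrom)
}

#' Generate an isogenic counts table with planted unique mutations
#'
#' Emulates pileup summaries of one ancestral clone and several descendant
#' clones at ~`depth` mean coverage (Poisson), with per-base sequencing error
#' `error_rate`, shared heterozygous ancestral variants present in every
#' sample, and per-descendant planted heterozygous unique mutations (binomial
#' alt counts at VAF 0.5). SBS, insertion and deletion events can be planted.
#'
#' @param genome named character vector with one chromosome.
#' @param n_descendants number of descendant samples (the ancestor is extra).
#' @param n_sbs,n_ins,n_del planted unique events per descendant.
#' @param n_shared shared heterozygous variants present in all samples.
#' @param depth mean sequencing depth (Poisson).
#' @param error_rate per-base sequencing error rate.
#' @param seed RNG seed.
#' @return list: `counts` (counts data frame), `truth` (planted unique
#'   mutations: sample_id, chrom, pos, ref, alt, mut_class), `ancestry`
#'   (ancestor/descendant map), `samples`.
#' @export
gen_isogenic_counts <- function(genome, n_descendants = 3L, n_sbs = 100L,
                                n_ins = 0L, n_del = 0L, n_shared = 50L,
                                depth = 30, error_rate = 0.001, seed = 1L) {
  set.seed(seed)
  chrom <- names(genome)[1]
  seq <- genome[[1]]
  L <- nchar(seq)
  refbase <- strsplit(seq, "", fixed = TRUE)[[1]]
  samples <- c("ancestor", paste0("desc", seq_len(n_descendants)))
  S <- length(samples)
  n_planted <- n_descendants * (n_sbs + n_ins + n_del)
  if (n_planted + n_shared > L) stop("planted mutations exceed genome length")
  cov <- matrix(stats::rpois(L * S, depth), L, S)
  nb <- array(0L, dim = c(L, S, 4L))
  refidx <- match(refbase, BASES)
  # sequencing errors: spread each cell's error reads over the 3 non-ref bases
  nerr <- matrix(stats::rbinom(L * S, cov, error_rate), L, S)
  nonzero <- which(nerr > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nonzero))) {
    p <- nonzero[r, 1]; s <- nonzero[r, 2]
    alts <- setdiff(1:4, refidx[p])
    draw <- stats::rmultinom(1, nerr[p, s], rep(1 / 3, 3))[, 1]
    for (a in 1:3) nb[p, s, alts[a]] <- nb[p, s, alts[a]] + draw[a]
  }
  nins <- matrix(0L, L, S)
  ndel <- matrix(0L, L, S)
  # positions: disjoint pools for shared and planted unique events
  pool <- sample.int(L, n_planted + n_shared)
  shared_pos <- pool[seq_len(n_shared)]
  upool <- pool[-seq_len(n_shared)]
  # shared heterozygous variants in every sample
  for (p in shared_pos) {
    alt <- sample(setdiff(1:4, refidx[p]), 1)
    for (s in seq_len(S)) {
      a <- stats::rbinom(1, cov[p, s], 0.5)
      nb[p, s, alt] <- nb[p, s, alt] + a
    }
  }
  truth <- list()
  k <- 0L
  for (d in seq_len(n_descendants)) {
    s <- d + 1L
    take <- function(n) {
      out <- upool[seq_len(n)]
      upool <<- upool[-seq_len(n)]
      out
    }
    for (p in take(n_sbs)) {
      alt <- sample(setdiff(1:4, refidx[p]), 1)
      a <- stats::rbinom(1, cov[p, s], 0.5)
      nb[p, s, alt] <- nb[p, s, alt] + a
      k <- k + 1L
      truth[[k]] <- data.frame(sample_id = samples[s], chrom = chrom,
                               pos = p, ref = BASES[refidx[p]],
                               alt = BASES[alt], mut_class = "SBS")
    }
    if (n_ins > 0) for (p in take(n_ins)) {
      ib <- sample(BASES, 1)
      nins[p, s] <- stats::rbinom(1, cov[p, s], 0.5)
      k <- k + 1L
      truth[[k]] <- data.frame(sample_id = samples[s], chrom = chrom,
                               pos = p, ref = refbase[p],
                               alt = paste0(refbase[p], ib),
                               mut_class = "INS")
    }
    if (n_del > 0) for (p in take(n_del)) {
      if (p >= L) next
      ndel[p, s] <- stats::rbinom(1, cov[p, s], 0.5)
      k <- k + 1L
      truth[[k]] <- data.frame(sample_id = samples[s], chrom = chrom,
                               pos = p,
                               ref = paste0(refbase[p], refbase[p + 1]),
                               alt = refbase[p], mut_class = "DEL")
    }
  }
  # alt reads replace reference reads; base counts must not exceed coverage
  nonref <- nb[, , 1] + nb[, , 2] + nb[, , 3] + nb[, , 4]
  over <- nonref > cov
  if (any(over)) {
    idx <- which(over, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, 1]; s <- idx[r, 2]
      scl <- cov[p, s] / nonref[p, s]
      nb[p, s, ] <- floor(nb[p, s, ] * scl)
    }
    nonref <- nb[, , 1] + nb[, , 2] + nb[, , 3] + nb[, , 4]
  }
  nref <- cov - nonref
  for (b in 1:4) {
    rows <- refidx == b
    nb[rows, , b] <- nb[rows, , b] + nref[rows, ]
  }
  counts <- data.frame(
    sample = rep(samples, each = L),
    chrom = chrom,
    pos = rep(seq_len(L), S),
    ref = rep(refbase, S),
    cov = as.vector(cov),
    nA = as.vector(nb[, , 1]),
    nC = as.vector(nb[, , 2]),
    nG = as.vector(nb[, , 3]),
    nT = as.vector(nb[, , 4]),
    n_ins = as.vector(nins),
    n_del = as.vector(ndel),
    stringsAsFactors = FALSE
  )
  truth <- if (k > 0) do.call(rbind, truth) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               mut_class = character(0))
  list(counts = counts,
       truth = truth,
       ancestry = data.frame(ancestor = "ancestor",
                             descendant = samples[-1]),
       samples = samples)
}

# index of genome positions by pyrimidine-strand triplet context
triplet_index <- function(genome) {
  idx <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < 3) next
    centers <- 2:(L - 1)
    trips <- substring(s, centers - 1, centers + 1)
    centerb <- substr(trips, 2, 2)
    pur <- centerb %in% c("A", "G")
    rc <- paste0(comp_base(substr(trips, 3, 3)),
                 comp_base(centerb),
                 comp_base(substr(trips, 1, 1)))
    ptrip <- ifelse(pur, rc, trips)
    ok <- !grepl("[^ACGT]", trips)
    sp <- split(centers[ok], ptrip[ok])
    idx[[ch]] <- sp
  }
  idx
}

#' Generate a mutation catalog from a signature mixture
#'
#' Draws `n` SBS96 channels multinomially from the exposure-weighted mixture
#' of the given signatures and realises each at a genome position whose
#' pyrimidine-strand triplet context matches the channel; positions are
#' unique. Errors if the toy genome lacks enough positions for a required
#' context.
#'
#' @param signatures channels x signatures matrix (SBS96).
#' @param exposures non-negative exposure vector over the signatures.
#' @param n number of mutations to draw.
#' @param genome named character vector of chromosome sequences.
#' @param seed RNG seed.
#' @param sample_id sample name recorded on the records.
#' @param vaf VAF recorded on the records.
#' @return mutation-record data frame with a `channel` column.
#' @export
gen_catalog <- function(signatures, exposures, n, genome, seed = 1L,
                        sample_id = "s1", vaf = 0.5) {
  if (sum(exposures) <= 0) stop("exposures must have positive sum")
  set.seed(seed)
  labels <- sbs96_labels()
  stopifnot(identical(rownames(signatures), labels))
  mix <- as.numeric(signatures %*% (exposures / sum(exposures)))
  if (n == 0) {
    out <- mutation_records(character(0), character(0), integer(0),
                            character(0), character(0))
    out$channel <- character(0)
    return(out)
  }
  chan <- sample.int(96L, n, replace = TRUE, prob = mix)
  idx <- triplet_index(genome)
  p5 <- substr(labels, 1, 1)
  refp <- substr(labels, 3, 3)
  altp <- substr(labels, 5, 5)
  p3 <- substr(labels, 7, 7)
  trip_of_chan <- paste0(p5, refp, p3)
  need <- table(trip_of_chan[chan])
  mchrom <- character(n)
  mpos <- integer(n)
  for (trip in names(need)) {
    pools <- lapply(names(idx), function(ch) idx[[ch]][[trip]])
    names(pools) <- names(idx)
    total <- sum(lengths(pools))
    if (total < need[[trip]]) {
      stop("toy genome lacks enough ", trip, " contexts (need ",
           need[[trip]], ", have ", total, ")")
    }
    flat_ch <- rep(names(pools), lengths(pools))
    flat_pos <- unlist(pools, use.names = FALSE)
    pick <- sample.int(total, need[[trip]])
    sel <- which(trip_of_chan[chan] == trip)
    mchrom[sel] <- flat_ch[pick]
    mpos[sel] <- flat_pos[pick]
  }
  gb <- character(n)
  for (ch in unique(mchrom)) {
    s <- mchrom == ch
    gb[s] <- substring(genome[[ch]], mpos[s], mpos[s])
  }
  pyr <- gb %in% c("C", "T")
  ref <- ifelse(pyr, refp[chan], comp_base(refp[chan]))
  alt <- ifelse(pyr, altp[chan], comp_base(altp[chan]))
  out <- mutation_records(rep(sample_id, n), mchrom, mpos, ref, alt,
                          vaf = vaf)
  out$channel <- labels[chan]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Generate a replication fork field with OK-seq style counts
#'
#' Lays a smooth alternating fork field `rfd_true(x) = tanh(sharpness *
#' sin(2*pi*x / wavelength))` over the genome and draws rightward/leftward
#' read counts per window binomially around it. The planted orientation is
#' known everywhere.
#'
#' @param genome_length genome length in bp.
#' @param wavelength fork-field wavelength in bp (origin spacing).
#' @param window window width in bp (default 1000).
#' @param reads_per_window OK-seq reads per window.
#' @param sharpness steepness of the alternation (larger = closer to square
#'   wave).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return list: `ok_counts` (chrom/start/end/rightward/leftward),
#'   `true_rfd` (per window), `rfd_true_fun` (function of position).
#' @export
gen_fork_field <- function(genome_length, wavelength, window = 1000L,
                           reads_per_window = 200L, sharpness = 5,
                           seed = 1L, chrom = "chr1") {
  if (wavelength > genome_length) stop("wavelength exceeds genome length")
  set.seed(seed)
  starts <- seq(0L, genome_length - window, by = window)
  mids <- starts + window / 2
  f <- function(x) tanh(sharpness * sin(2 * pi * x / wavelength))
  s_true <- f(mids)
  r <- stats::rbinom(length(mids), reads_per_window, (1 + s_true) / 2)
  list(ok_counts = data.frame(chrom = chrom, start = starts,
                              end = starts + window,
                              rightward = r,
                              leftward = reads_per_window - r),
       true_rfd = s_true,
       rfd_true_fun = f)
}

#' Generate a smooth replication-timing track
#'
#' A cosine wave (higher = earlier replication, matching the source-track
#' convention) sampled every `step` bp, with optional Gaussian noise.
#'
#' @param genome_length genome length in bp.
#' @param period wavelength of the timing wave (default: genome length).
#' @param step sampling step in bp.
#' @param amplitude wave amplitude.
#' @param noise_sd Gaussian noise added to the sampled points.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return list: `track` (a timing [genomic_track()]) and `timing_fun`
#'   (noise-free closed form).
#' @export
gen_timing <- function(genome_length, period = NULL, step = 1000L,
                       amplitude = 1, noise_sd = 0, seed = 1L,
                       chrom = "chr1") {
  if (is.null(period)) period <- genome_length
  set.seed(seed)
  pos <- seq(step / 2, genome_length, by = step)
  f <- function(x) amplitude * cos(2 * pi * x / period)
  val <- f(pos) + stats::rnorm(length(pos), 0, noise_sd)
  list(track = genomic_track(data.frame(chrom = chrom, pos = pos,
                                        value = val), kind = "timing"),
       timing_fun = f)
}

#' Generate a bimodal VAF mixture with truth labels
#'
#' VAFs are binomial read-sampled around the subclonal and clonal centres at
#' the given depth.
#'
#' @param n number of mutations.
#' @param clonal_fraction fraction drawn from the clonal (upper) centre.
#' @param centers numeric length-2 vector: subclonal then clonal centre, both
#'   in (0, 1) and distinct.
#' @param depth read depth for binomial sampling.
#' @param seed RNG seed.
#' @return list: `vafs`, `labels` (`"clonal"`/`"subclonal"`).
#' @export
gen_vaf_mixture <- function(n, clonal_fraction = 0.5,
                            centers = c(0.25, 0.5), depth = 60L, seed = 1L) {
  if (length(centers) != 2 || centers[1] == centers[2]) {
    stop("centers must be two distinct values")
  }
  if (any(centers <= 0 | centers >= 1)) stop("centers must lie in (0, 1)")
  set.seed(seed)
  clonal <- stats::runif(n) < clonal_fraction
  p <- ifelse(clonal, max(centers), min(centers))
  list(vafs = stats::rbinom(n, depth, p) / depth,
       labels = ifelse(clonal, "clonal", "subclonal"))
}

#' Study design of the two-condition culture experiment
#'
#' The defaults encode the emulated study conditions: clones cultured for 60
#' days at a 20 h mean doubling time (72 population doublings), five clones
#' per oxygen condition, and per-doubling signature exposures of 76.8 SBS
#' from the baseline MMRd process in both conditions plus 87.0 SBS from the
#' oxygen component in the high-oxygen condition only (totals 76.8 and 163.8
#' per doubling).
#'
#' @param days days in culture.
#' @param doubling_time_hours mean population doubling time.
#' @param n_low,n_high clones per condition.
#' @param rate_baseline,rate_oxygen per-doubling exposures of the baseline
#'   and oxygen components.
#' @return list describing the design.
#' @export
study_design <- function(days = 60, doubling_time_hours = 20,
                         n_low = 5L, n_high = 5L,
                         rate_baseline = 76.8, rate_oxygen = 87.0) {
  doublings <- days * 24 / doubling_time_hours
  list(days = days, doubling_time_hours = doubling_time_hours,
       population_doublings = doublings, n_low = n_low, n_high = n_high,
       rate_baseline = rate_baseline, rate_oxygen = rate_oxygen)
}

#' Generate a two-condition cohort of mutation catalogs
#'
#' Per clone, the mutation total is Poisson around the summed planted
#' exposure and channels are drawn from the exposure-weighted signature
#' mixture (see [gen_catalog()]). Exposures are given in mutation counts per
#' clone (typically per-doubling rates times doublings).
#'
#' @param signatures channels x signatures matrix.
#' @param exposure_matrix signatures x clones matrix of planted exposure
#'   counts; column names are the clone ids.
#' @param genome toy genome for realising positions.
#' @param seed RNG seed.
#' @return list: `catalogs` (list of record data frames per clone),
#'   `catalog_matrix` (channels x clones realised counts), `n` (realised
#'   totals).
#' @export
gen_cohort <- function(signatures, exposure_matrix, genome, seed = 1L) {
  set.seed(seed)
  clones <- colnames(exposure_matrix)
  if (is.null(clones)) clones <- paste0("clone", seq_len(ncol(exposure_matrix)))
  totals <- stats::rpois(length(clones), colSums(exposure_matrix))
  catalogs <- vector("list", length(clones))
  names(catalogs) <- clones
  M <- matrix(0, nrow(signatures), length(clones),
              dimnames = list(rownames(signatures), clones))
  for (j in seq_along(clones)) {
    catalogs[[j]] <- gen_catalog(signatures, exposure_matrix[, j],
                                 totals[j], genome,
                                 seed = seed * 100L + j,
                                 sample_id = clones[j])
    sp <- table(factor(catalogs[[j]]$channel, levels = rownames(signatures)))
    M[, j] <- as.numeric(sp)
  }
  list(catalogs = catalogs, catalog_matrix = M, n = totals)
}

#' Load the synthetic SBS96 signature fixture
#'
#' Three synthetic signatures shipped with the package: `sim_bg` (broad
#' background), `sim_hd` (baseline MMRd-like, T>C and C>T dominated) and
#' `sim_ox` (oxygen-like, T>C dominated and concentrated at the ATA, GTA,
#' GTT and TTA triplets).
#'
#' @return channels x 3 signature matrix with unit column sums.
#' @export
synthetic_signatures <- function() {
  path <- system.file("extdata", "synthetic_sbs96_signatures.tsv",
                      package = "isomutsig", mustWork = TRUE)
  read_signature_matrix(path)
}
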