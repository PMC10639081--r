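# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately re-derive results by brute force, not via the package
# code paths they check.

# literal re-implementation of the caller's three filter inequalities,
# evaluated position by position with plain loops
oracle_filter <- function(counts, cfg = caller_config()) {
  out <- list()
  keys <- unique(counts[c("chrom", "pos")])
  samples <- sort(unique(counts$sample))
  for (r in seq_len(nrow(keys))) {
    rows <- counts[counts$chrom == keys$chrom[r] & counts$pos == keys$pos[r],
                   , drop = FALSE]
    ref <- rows$ref[1]
    per <- list()
    for (s in samples) {
      x <- rows[rows$sample == s, , drop = FALSE]
      if (nrow(x) == 0) {
        per[[s]] <- list(cov = 0, refaf = 0, altn = 0, vaf = 0, allele = NA)
        next
      }
      cnt <- c(A = x$nA, C = x$nC, G = x$nG, T = x$nT,
               INS = x$n_ins, DEL = x$n_del)
      nonref <- sum(cnt[c("A", "C", "G", "T")]) - cnt[[ref]]
      refsup <- max(x$cov - nonref - cnt[["INS"]] - cnt[["DEL"]], 0)
      cand <- cnt
      cand[[ref]] <- -1
      allele <- names(cand)[which.max(cand)]   # ties: A<C<G<T<INS<DEL order
      per[[s]] <- list(cov = x$cov,
                       refaf = if (x$cov > 0) refsup / x$cov else 0,
                       altn = max(cand),
                       vaf = if (x$cov > 0) max(cand, 0) / x$cov else 0,
                       allele = allele)
    }
    for (s in samples) {
      p <- per[[s]]
      if (p$altn <= 0) next
      ok1 <- p$vaf >= cfg$min_alt_vaf
      ok2 <- p$cov >= cfg$min_cov
      ok3 <- all(vapply(setdiff(samples, s), function(o) {
        per[[o]]$refaf >= cfg$min_other_ref_af
      }, logical(1)))
      if (ok1 && ok2 && ok3) {
        out[[length(out) + 1]] <- data.frame(
          sample_id = s, chrom = keys$chrom[r], pos = keys$pos[r],
          allele = p$allele, vaf = p$vaf, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), allele = character(0), vaf = numeric(0))
}

# exact one-tailed Fisher probability by direct summation of the
# hypergeometric mass function (choose() arithmetic, no phyper)
oracle_fisher_p <- function(alt_mut, cov_mut, alt_other, cov_other) {
  K <- alt_mut + alt_other
  N <- cov_mut + cov_other
  amax <- min(K, cov_mut)
  a <- alt_mut:amax
  sum(choose(K, a) * choose(N - K, cov_mut - a) / choose(N, cov_mut))
}

# projected-gradient non-negative least squares (independent of lsqnonneg)
oracle_nnls <- function(A, y, iters = 20000, tol = 1e-12) {
  x <- rep(0, ncol(A))
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  step <- 1 / L
  for (i in seq_len(iters)) {
    g <- crossprod(A, A %*% x - y)
    xn <- pmax(x - step * g, 0)
    if (sqrt(sum((xn - x)^2)) < tol * (1 + sqrt(sum(x^2)))) {
      x <- xn
      break
    }
    x <- xn
  }
  as.numeric(x)
}

# brute-force ID83 classification of an anchored indel in a linear sequence:
# re-derives left alignment, tandem copies and microhomology by direct
# string scanning
oracle_id83 <- function(seq, pos, ref, alt) {
  is_del <- nchar(ref) > nchar(alt)
  unit <- if (is_del) substr(ref, 2, nchar(ref)) else substr(alt, 2, nchar(alt))
  L <- nchar(unit)
  repeat {
    if (pos < 1) break
    if (substr(seq, pos, pos) != substr(unit, L, L)) break
    unit <- paste0(substr(seq, pos, pos), substr(unit, 1, L - 1))
    pos <- pos - 1
  }
  copies <- 0
  at <- pos + 1
  while (at + L - 1 <= nchar(seq) && substr(seq, at, at + L - 1) == unit) {
    copies <- copies + 1
    at <- at + L
  }
  if (L == 1) {
    b <- if (unit %in% c("A", "G")) chartr("AG", "TC", unit) else unit
    if (is_del) return(paste0("1:Del:", b, ":", min(copies, 6) - 1))
    return(paste0("1:Ins:", b, ":", min(copies, 5)))
  }
  lencat <- min(L, 5)
  if (!is_del) return(paste0(lencat, ":Ins:R:", min(copies, 5)))
  if (copies >= 2) return(paste0(lencat, ":Del:R:", min(copies, 6) - 1))
  mh <- 0
  for (j in seq_len(L - 1)) {   # forward prefix match after the deletion
    if (pos + L + j <= nchar(seq) &&
        substr(seq, pos + L + 1, pos + L + j) == substr(unit, 1, j)) {
      mh <- max(mh, j)
    }
  }
  for (j in seq_len(L - 1)) {   # backward suffix match before the deletion
    if (pos - j >= 1 &&
        substr(seq, pos - j + 1, pos) == substr(unit, L - j + 1, L)) {
      mh <- max(mh, j)
    }
  }
  if (mh >= 1) return(paste0(lencat, ":Del:M:", min(mh, 5)))
  paste0(lencat, ":Del:R:0")
}

# exhaustive optimal 1-D 2-means over all sorted split points
oracle_two_means <- function(x) {
  x <- sort(x)
  n <- length(x)
  best <- NULL
  for (k in 1:(n - 1)) {
    a <- x[1:k]
    b <- x[(k + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(ss = ss, centers = c(mean(a), mean(b)))
    }
  }
  best
}

# O(n*m) brute-force interval overlap for points
oracle_point_overlap <- function(pos, start, end) {
  vapply(pos, function(p) any(start <= p & p <= end), logical(1))
}

# random reference signature columns for decoy sets
random_signatures <- function(n, k, seed, prefix = "decoy") {
  set.seed(seed)
  m <- matrix(stats::rgamma(n * k, 0.5, 1), n, k)
  m <- sweep(m, 2, colSums(m), "/")
  colnames(m) <- paste0(prefix, seq_len(k))
  m
}

# plain-string reverse complement (independent of package internals)
revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# pyrimidine-strand substitution class of an SBS
sbs_class_of <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  paste0(ifelse(pur, chartr("AG", "TC", ref), ref), ">",
         ifelse(pur, chartr("ACGT", "TGCA", alt), alt))
}
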