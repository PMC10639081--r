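# SBS96 / ID83 channel classification and spectrum construction.
#
# SBS channels follow the COSMIC convention: substitutions are expressed on
# the pyrimidine strand (purine refs are reverse-complemented, flanks swapped
# and complemented), blocks ordered C>A, C>G, C>T, T>A, T>C, T>G, and within a
# block the 5' then the 3' base run alphabetically. Indel channels follow the
# COSMIC v3 ID83 convention (type, length, homopolymer run / tandem-repeat
# copies / microhomology length) so published ID signature matrices can be
# refit directly.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' SBS96 channel labels in canonical order
#' @return character vector of 96 labels like `"A[C>A]A"`.
#' @export
sbs96_labels <- function() {
  out <- character(0)
  for (sub in SBS_CLASSES) {
    for (p5 in BASES) {
      for (p3 in BASES) {
        out <- c(out, paste0(p5, "[", sub, "]", p3))
      }
    }
  }
  out
}

#' ID83 channel labels in canonical order
#'
#' 1 bp deletions and insertions at C/T homopolymers, 2-5+ bp deletions and
#' insertions at tandem repeats, and deletions with microhomology, in the
#' COSMIC v3 order (83 channels).
#' @return character vector of 83 labels like `"1:Del:C:0"`.
#' @export
id83_labels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Del:R:", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  out
}

#' Channel labels for a spectrum kind
#' @param kind `"SBS96"` or `"ID83"`.
#' @return character vector of channel labels.
#' @export
channel_labels <- function(kind = c("SBS96", "ID83")) {
  kind <- match.arg(kind)
  if (kind == "SBS96") sbs96_labels() else id83_labels()
}

#' Classify a single base substitution into its SBS96 channel
#'
#' @param ref,alt single reference and alternate bases (vectorised).
#' @param fivep,threep the 5' and 3' flanking reference bases.
#' @return integer channel indices (1..96); `NA` for non-ACGT input.
#' @export
sbs96_channel <- function(ref, alt, fivep, threep) {
  ref <- toupper(ref); alt <- toupper(alt)
  fivep <- toupper(fivep); threep <- toupper(threep)
  ok <- ref %in% BASES & alt %in% BASES & fivep %in% BASES &
    threep %in% BASES & ref != alt
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp_base(ref), ref)
  a <- ifelse(pur, comp_base(alt), alt)
  p5 <- ifelse(pur, comp_base(threep), fivep)
  p3 <- ifelse(pur, comp_base(fivep), threep)
  lab <- paste0(p5, "[", r, ">", a, "]", p3)
  idx <- match(lab, sbs96_labels())
  idx[!ok] <- NA_integer_
  idx
}

# pyrimidine-strand substitution class ("C>A", ..., "T>G") of an SBS
sbs_class <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  paste0(ifelse(pur, comp_base(ref), ref), ">",
         ifelse(pur, comp_base(alt), alt))
}

# ---- indel classification -------------------------------------------------

# left-align an anchored indel: while the reference base at the anchor equals
# the last base of the indel unit, shift the event one base left
left_align_indel <- function(seq, pos, unit) {
  L <- nchar(unit)
  while (pos >= 1L) {
    anchor <- substr(seq, pos, pos)
    if (anchor != substr(unit, L, L)) break
    unit <- paste0(anchor, substr(unit, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, unit = unit)
}

# number of consecutive copies of `unit` in `seq` starting at `from`
count_tandem_copies <- function(seq, from, unit) {
  L <- nchar(unit)
  n <- 0L
  while (from + L - 1L <= nchar(seq) &&
         substr(seq, from, from + L - 1L) == unit) {
    n <- n + 1L
    from <- from + L
  }
  n
}

# longest prefix of `unit` matching seq starting at `from` (rightward), or
# longest suffix of `unit` matching seq ending at `to` (leftward)
microhomology_len <- function(seq, unit, from, to) {
  L <- nchar(unit)
  fwd <- 0L
  while (fwd < L - 1L && from + fwd <= nchar(seq) &&
         substr(seq, from + fwd, from + fwd) ==
         substr(unit, fwd + 1L, fwd + 1L)) {
    fwd <- fwd + 1L
  }
  bwd <- 0L
  while (bwd < L - 1L && to - bwd >= 1L &&
         substr(seq, to - bwd, to - bwd) ==
         substr(unit, L - bwd, L - bwd)) {
    bwd <- bwd + 1L
  }
  max(fwd, bwd)
}

#' Classify a short indel into its ID83 channel
#'
#' The record must use VCF anchoring (ref and alt share their first base) and
#' be at most 50 bp. The indel is left-aligned against the reference, then
#' classified by type and length; 1 bp events by the homopolymer run of the
#' affected base (A/G mapped to T/C), longer events by the number of tandem
#' copies of the indel unit scanning rightward from the anchored position, and
#' deletions without a second tandem copy by microhomology length.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,pos,ref,alt the anchored indel (vectorised).
#' @return character vector of ID83 labels; `NA` where the context is
#'   unavailable or the event is not a classifiable short indel.
#' @export
classify_indel <- function(genome, chrom, pos, ref, alt) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    out[i] <- classify_indel_one(genome, chrom[i], as.integer(pos[i]),
                                 toupper(ref[i]), toupper(alt[i]))
  }
  out
}

classify_indel_one <- function(genome, chrom, pos, ref, alt) {
  if (!chrom %in% names(genome)) return(NA_character_)
  seq <- genome[[chrom]]
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) return(NA_character_)
  is_del <- nchar(ref) > nchar(alt)
  unit <- if (is_del) substr(ref, 2L, nchar(ref)) else substr(alt, 2L, nchar(alt))
  L <- nchar(unit)
  if (L < 1L || L > 50L) return(NA_character_)
  if (!all(strsplit(unit, "", fixed = TRUE)[[1]] %in% BASES)) {
    return(NA_character_)
  }
  if (pos < 1L || pos + (if (is_del) L else 0L) > nchar(seq)) {
    return(NA_character_)
  }
  # verify the record against the reference, then left-align
  if (substr(seq, pos, pos) != substr(ref, 1L, 1L)) return(NA_character_)
  if (is_del && substr(seq, pos + 1L, pos + L) != unit) return(NA_character_)
  la <- left_align_indel(seq, pos, unit)
  pos <- la$pos
  unit <- la$unit
  lencat <- min(L, 5L)
  if (L == 1L) {
    run <- count_tandem_copies(seq, pos + 1L, unit)  # includes deleted base
    b <- if (unit %in% c("A", "G")) comp_base(unit) else unit
    if (is_del) {
      return(paste0("1:Del:", b, ":", min(run, 6L) - 1L))
    }
    return(paste0("1:Ins:", b, ":", min(run, 5L)))
  }
  copies <- count_tandem_copies(seq, pos + 1L, unit)
  if (is_del) {
    if (copies >= 2L) {
      return(paste0(lencat, ":Del:R:", min(copies, 6L) - 1L))
    }
    mh <- microhomology_len(seq, unit, from = pos + 1L + L, to = pos)
    if (mh >= 1L) {
      return(paste0(lencat, ":Del:M:", min(mh, 5L)))
    }
    return(paste0(lencat, ":Del:R:0"))
  }
  paste0(lencat, ":Ins:R:", min(copies, 5L))
}

# ---- spectra --------------------------------------------------------------

#' Construct a mutation spectrum object
#'
#' @param values non-negative numeric vector of length 96 (SBS96) or 83
#'   (ID83), named by channel.
#' @param kind `"SBS96"` or `"ID83"`.
#' @param normalized whether `values` are frequencies summing to one.
#' @return numeric vector of class `mut_spectrum`.
#' @export
mut_spectrum <- function(values, kind = c("SBS96", "ID83"),
                         normalized = FALSE) {
  kind <- match.arg(kind)
  labels <- channel_labels(kind)
  if (length(values) != length(labels)) {
    stop("expected ", length(labels), " channels for ", kind)
  }
  if (!is.null(names(values))) {
    if (!setequal(names(values), labels)) stop("channel labels do not match ",
                                               kind)
    values <- values[labels]
  } else {
    names(values) <- labels
  }
  if (any(values < 0)) stop("spectrum values must be non-negative")
  if (normalized && abs(sum(values) - 1) > 1e-9) {
    stop("normalized spectrum must sum to 1")
  }
  structure(as.numeric(stats::setNames(values, labels)),
            names = labels, kind = kind, normalized = normalized,
            class = "mut_spectrum")
}

#' @export
print.mut_spectrum <- function(x, ...) {
  cat(sprintf("<mut_spectrum %s, total %.4g%s>\n", attr(x, "kind"), sum(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("  top channels:",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Normalise a spectrum to frequencies
#' @param spec a [mut_spectrum()].
#' @return the spectrum scaled to sum to one.
#' @export
normalize_spectrum <- function(spec) {
  s <- sum(spec)
  if (s <= 0) stop("cannot normalise an all-zero spectrum")
  mut_spectrum(unclass(spec) / s, attr(spec, "kind"), normalized = TRUE)
}

#' Build an SBS96 or ID83 spectrum from mutation records
#'
#' Records of the matching class are classified against the genome; channel
#' counts sum to the number of classifiable inputs. Unclassifiable records
#' (missing context, non-ACGT bases) are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param records mutation-record data frame.
#' @param genome named character vector of chromosome sequences.
#' @param kind `"SBS96"` or `"ID83"`.
#' @return a [mut_spectrum()] of counts.
#' @export
build_spectrum <- function(records, genome, kind = c("SBS96", "ID83")) {
  kind <- match.arg(kind)
  labels <- channel_labels(kind)
  counts <- stats::setNames(numeric(length(labels)), labels)
  cls <- if ("mut_class" %in% names(records)) records$mut_class
         else mut_class_of(records$ref, records$alt)
  if (kind == "SBS96") {
    rec <- records[cls == "SBS", , drop = FALSE]
    idx <- rep(NA_integer_, nrow(rec))
    for (ch in unique(rec$chrom)) {
      sel <- rec$chrom == ch
      ctx <- fetch_context(genome, ch, rec$pos[sel], flank = 1L)
      ok <- !is.na(ctx)
      idx[sel][ok] <- sbs96_channel(rec$ref[sel][ok], rec$alt[sel][ok],
                                    substr(ctx[ok], 1, 1),
                                    substr(ctx[ok], 3, 3))
    }
    tab <- table(factor(labels[idx], levels = labels))
    counts[] <- as.numeric(tab)
    n_excl <- sum(is.na(idx))
  } else {
    rec <- records[cls %in% c("INS", "DEL"), , drop = FALSE]
    lab <- classify_indel(genome, rec$chrom, rec$pos, rec$ref, rec$alt)
    tab <- table(factor(lab, levels = labels))
    counts[] <- as.numeric(tab)
    n_excl <- sum(is.na(lab))
  }
  out <- mut_spectrum(counts, kind)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Cosine similarity between two spectra
#'
#' @param a,b numeric vectors or [mut_spectrum()] objects over the same
#'   channel set.
#' @return similarity in \[0, 1\] for non-negative inputs; scale-invariant.
#' @export
cosine <- function(a, b) {
  if (inherits(a, "mut_spectrum") && inherits(b, "mut_spectrum") &&
      !identical(attr(a, "kind"), attr(b, "kind"))) {
    stop("spectra have different channel sets")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# ---- extended-context enrichment logos ------------------------------------

#' Enrichment/depletion logo of the extended context of one mutation class
#'
#' Observed contexts are taken on the pyrimidine strand of each mutation.
#' The background is built from 10 random positions per mutation (uniform in
#' +/- `bg_window` bp of the mutation, windows leaving the chromosome
#' excluded), oriented like their focal mutation. Per position and base the
#' score is `log2((f_obs + eps) / (f_bg + eps))` on pseudo-counted
#' frequencies, then median-centred over the four bases of the position.
#'
#' @param records SBS mutation records of a single class (e.g. all T>C).
#' @param genome named character vector of chromosome sequences.
#' @param flank positions considered on each side of the mutated base.
#' @param bg_per_mut background positions sampled per mutation.
#' @param bg_window half-width in bp of the background sampling window.
#' @param pseudo pseudo-count added per base before computing frequencies.
#' @param seed RNG seed for background sampling.
#' @return matrix of class `context_logo` (4 bases x 2*flank+1 positions).
#' @export
context_logo <- function(records, genome, flank = 5L, bg_per_mut = 10L,
                         bg_window = 1000L, pseudo = 0.5, seed = 1L) {
  set.seed(seed)
  w <- 2L * flank + 1L
  obs <- matrix(0, 4, w, dimnames = list(BASES, as.character(-flank:flank)))
  bg <- obs
  n_used <- 0L
  for (ch in unique(records$chrom)) {
    sel <- which(records$chrom == ch)
    L <- nchar(genome[[ch]])
    ctx <- fetch_context(genome, ch, records$pos[sel], flank)
    flip <- records$ref[sel] %in% c("A", "G")
    for (k in seq_along(sel)) {
      if (is.na(ctx[k])) next
      cc <- if (flip[k]) revcomp(ctx[k]) else ctx[k]
      bb <- strsplit(cc, "", fixed = TRUE)[[1]]
      for (p in seq_len(w)) obs[bb[p], p] <- obs[bb[p], p] + 1
      n_used <- n_used + 1L
      # background: positions near this mutation whose window stays in-bounds
      lo <- max(records$pos[sel][k] - bg_window, flank + 1L)
      hi <- min(records$pos[sel][k] + bg_window, L - flank)
      if (hi < lo) next
      bpos <- sample(seq(lo, hi), bg_per_mut, replace = TRUE)
      bctx <- fetch_context(genome, ch, bpos, flank)
      for (bc in bctx) {
        if (is.na(bc)) next
        if (flip[k]) bc <- revcomp(bc)
        bb <- strsplit(bc, "", fixed = TRUE)[[1]]
        for (p in seq_len(w)) bg[bb[p], p] <- bg[bb[p], p] + 1
      }
    }
  }
  if (n_used == 0L) stop("no mutation with available context")
  fo <- sweep(obs + pseudo, 2, colSums(obs + pseudo), "/")
  fb <- sweep(bg + pseudo, 2, colSums(bg + pseudo), "/")
  score <- log2(fo / fb)
  score <- sweep(score, 2, apply(score, 2, stats::median), "-")
  structure(score, n_mutations = n_used, class = c("context_logo", "matrix"))
}

#' @export
print.context_logo <- function(x, ...) {
  cat(sprintf("<context_logo: %d mutations, positions %s..%s>\n",
              attr(x, "n_mutations"), colnames(x)[1],
              colnames(x)[ncol(x)]))
  print(round(unclass(x), 3))
  invisible(x)
}
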