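#' Read a reference genome from FASTA
#'
#' Sequences are held internally as a named character vector of uppercase
#' chromosome sequences; names are the first whitespace-delimited token of each
#' FASTA header. All coordinates in the package are 1-based inclusive.
#'
#' @param path path to a FASTA file (a `.fai` index is not required).
#' @return named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(x))
  names(g) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Fetch the reference context around a locus
#'
#' Returns the `2 * flank + 1` uppercase reference bases centred on `pos`, or
#' `NA` when the window leaves the chromosome (the context-unavailable signal;
#' callers exclude such records from context analyses and count them).
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 1-based position (vectorised).
#' @param flank number of bases on each side.
#' @return character vector of contexts, `NA` where unavailable.
#' @export
fetch_context <- function(genome, chrom, pos, flank = 1L) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  s <- genome[[chrom]]
  L <- nchar(s)
  lo <- pos - flank
  hi <- pos + flank
  out <- rep(NA_character_, length(pos))
  ok <- lo >= 1L & hi <= L
  if (any(ok)) out[ok] <- substring(s, lo[ok], hi[ok])
  out
}

#' Read a per-sample allele-count table
#'
#' Expects a TSV with header columns `sample, chrom, pos, ref, cov, nA, nC,
#' nG, nT, n_ins, n_del`: one row per sample and genomic position, standing in
#' for an aligned pileup. Rows failing validation abort with the offending
#' line named; nothing is silently dropped. `cov >= nA + nC + nG + nT` is
#' enforced, as is uniqueness of `(sample, chrom, pos)`.
#'
#' @param path path to the TSV.
#' @return data frame of counts rows, ordered by chrom, pos, sample.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "pos", "ref", "cov",
           "nA", "nC", "nG", "nT", "n_ins", "n_del")
  if (!all(req %in% names(df))) {
    stop("counts table is missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  df <- df[req]
  if (nrow(df) == 0L) return(df)
  num <- c("pos", "cov", "nA", "nC", "nG", "nT", "n_ins", "n_del")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed value in column '", cn, "' at line ", bad[1] + 1L,
           " of ", path)
    }
    df[[cn]] <- v
  }
  validate_counts(df, path)
  df[order(df$chrom, df$pos, df$sample), , drop = FALSE]
}

# shared validation for count tables (file line = row index + header)
validate_counts <- function(df, origin = "counts table") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!toupper(df$ref) %in% BASES)
  if (length(bad)) {
    stop("non-ACGT reference base at line ", bad[1] + 1L, " of ", origin)
  }
  neg <- which(df$cov < 0 | df$nA < 0 | df$nC < 0 | df$nG < 0 | df$nT < 0 |
                 df$n_ins < 0 | df$n_del < 0 | df$pos < 1)
  if (length(neg)) {
    stop("negative count or position at line ", neg[1] + 1L, " of ", origin)
  }
  over <- which(df$cov < df$nA + df$nC + df$nG + df$nT)
  if (length(over)) {
    stop("coverage smaller than summed base counts at line ", over[1] + 1L,
         " of ", origin)
  }
  key <- paste(df$sample, df$chrom, df$pos)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (sample, chrom, pos) at line ", dup[1] + 1L,
         " of ", origin)
  }
  invisible(df)
}

#' Write a counts table
#' @param counts data frame as produced by [read_counts_table()].
#' @param path output path.
#' @export
write_counts_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- genomic tracks -------------------------------------------------------

#' Construct a genomic track
#'
#' A position-indexed scalar field: replication-timing scores (unitless,
#' higher = earlier under the source-track convention) or replication fork
#' directionality (RFD, dimensionless in \[-1, 1\]). Positions must be
#' strictly increasing within each chromosome.
#'
#' @param df data frame with columns `chrom`, `pos`, `value`.
#' @param kind `"timing"` or `"rfd"`.
#' @param window_size optional window width in bp for windowed tracks.
#' @return an object of class `genomic_track`.
#' @export
genomic_track <- function(df, kind = c("timing", "rfd"), window_size = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("chrom", "pos", "value") %in% names(df)))
  if (any(!is.finite(df$value))) stop("non-finite track value")
  if (kind == "rfd" && any(df$value < -1 | df$value > 1)) {
    stop("RFD values must lie in [-1, 1]")
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  byc <- split(df[c("pos", "value")], df$chrom)
  for (ch in names(byc)) {
    if (anyDuplicated(byc[[ch]]$pos)) {
      stop("duplicated track position on ", ch)
    }
  }
  structure(list(data = byc),
            kind = kind, window_size = window_size,
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  n <- sum(vapply(x$data, nrow, integer(1)))
  cat(sprintf("<genomic_track kind=%s, %d points on %d chromosome(s)>\n",
              attr(x, "kind"), n, length(x$data)))
  invisible(x)
}

# read one bedGraph-like 4-column file (chrom, start, end, value; 0-based
# half-open), tolerating a single header line
read_bedgraph_file <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  f1 <- strsplit(first, "\t|\\s+")[[1]]
  if (length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2])))) skip <- 1L
  df <- utils::read.table(path, header = FALSE, skip = skip,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("expected 4 columns (chrom, start, end, value) in ",
                         path)
  df <- df[1:4]
  names(df) <- c("chrom", "start", "end", "value")
  for (cn in c("start", "end", "value")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric '", cn, "' at line ", bad[1] + skip, " of ", path)
    }
    df[[cn]] <- v
  }
  o <- order(df$chrom, df$start)
  if (is.unsorted(o) && any(o != seq_len(nrow(df)))) {
    warning("track file not sorted; sorting internally: ", path)
  }
  df[o, , drop = FALSE]
}

#' Read replication-timing or RFD tracks
#'
#' Input is bedGraph-like (chrom, start, end, value; 0-based half-open
#' intervals, converted at this boundary). Points are stored at interval
#' midpoints. For `kind = "timing"` several files may be given; their values
#' are averaged per position after an inner join on identical intervals (rows
#' present in only some files are dropped with a warning).
#'
#' @param path character vector of one or more file paths.
#' @param kind `"timing"` or `"rfd"`.
#' @return a [genomic_track()].
#' @export
read_track <- function(path, kind = c("timing", "rfd")) {
  kind <- match.arg(kind)
  if (kind == "rfd" && length(path) > 1) {
    stop("multiple files are only supported for timing tracks")
  }
  tabs <- lapply(path, read_bedgraph_file)
  base <- tabs[[1]]
  if (length(tabs) > 1) {
    for (k in 2:length(tabs)) {
      m <- merge(base, tabs[[k]], by = c("chrom", "start", "end"))
      dropped <- nrow(base) + nrow(tabs[[k]]) - 2L * nrow(m)
      if (dropped > 0) {
        warning(dropped, " interval(s) not shared between timing files; ",
                "inner join keeps the common grid")
      }
      vcols <- grep("^value", names(m))
      base <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                         value = rowMeans(m[vcols]))
    }
  }
  ws <- unique(base$end - base$start)
  genomic_track(
    data.frame(chrom = base$chrom,
               pos = (base$start + base$end) / 2,
               value = base$value),
    kind = kind,
    window_size = if (length(ws) == 1L) ws else NULL
  )
}

#' Read gene intervals from BED6
#'
#' BED half-open 0-based coordinates are converted to the package's 1-based
#' inclusive convention at this boundary.
#'
#' @param path path to a BED6 file (chrom, start, end, name, score, strand).
#' @return data frame with columns `chrom`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("expected BED6 (6 columns) in ", path)
  out <- data.frame(chrom = df[[1]],
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    gene_id = as.character(df[[4]]),
                    strand = as.character(df[[6]]),
                    stringsAsFactors = FALSE)
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", bad[1], " of ", path)
  bad <- which(out$start > out$end)
  if (length(bad)) stop("start > end at line ", bad[1], " of ", path)
  out
}

# ---- VCF ------------------------------------------------------------------

#' Write mutation records as minimal VCF 4.2
#'
#' One data line per record with the sample id, VAF, mutation class and
#' quality score carried in INFO. Records are sorted by (chrom, pos) before
#' writing; the writer/reader pair is an identity on valid inputs.
#'
#' @param records mutation-record data frame (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `vaf`, `score`).
#' @param path output path.
#' @export
write_vcf <- function(records, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=isomutsig",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample carrying the unique mutation\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Mutation class (SBS/INS/DEL)\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Fisher quality score (-log10 p)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(records)) {
    records <- records[order(records$chrom, records$pos), , drop = FALSE]
    cls <- if ("mut_class" %in% names(records)) records$mut_class
           else mut_class_of(records$ref, records$alt)
    info <- sprintf("SAMPLE=%s;VAF=%s;CLASS=%s;SCORE=%s",
                    records$sample_id,
                    sprintf("%.17g", records$vaf),
                    cls,
                    sprintf("%.17g", records$score))
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                              records$chrom, records$pos, records$ref,
                              records$alt, info))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read mutation records from a VCF written by [write_vcf()]
#'
#' @param path path to the VCF.
#' @return mutation-record data frame.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(mutation_records(character(0), character(0), integer(0),
                            character(0), character(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad)) stop("malformed VCF data line ", bad[1], " in ", path)
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(parts, `[`, character(1), 8L)
  mutation_records(
    sample_id = get_info(info, "SAMPLE"),
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref = vapply(parts, `[`, character(1), 4L),
    alt = vapply(parts, `[`, character(1), 5L),
    vaf = as.numeric(get_info(info, "VAF")),
    score = as.numeric(get_info(info, "SCORE"))
  )
}

# ---- spectra and signature matrices ---------------------------------------

#' Write a spectrum as two-column TSV
#' @param spec a [mut_spectrum()].
#' @param path output path.
#' @export
write_spectrum <- function(spec, path) {
  utils::write.table(
    data.frame(channel = names(spec), value = as.numeric(spec)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from two-column TSV
#' @param path path to a TSV with columns `channel`, `value`.
#' @return a [mut_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "value") %in% names(df))) {
    stop("expected columns 'channel' and 'value' in ", path)
  }
  v <- as.numeric(df$value)
  names(v) <- df$channel
  kind <- infer_channel_kind(df$channel)
  v <- v[channel_labels(kind)]
  mut_spectrum(v, kind)
}

infer_channel_kind <- function(labels) {
  if (setequal(labels, sbs96_labels())) return("SBS96")
  if (setequal(labels, id83_labels())) return("ID83")
  stop("channel labels match neither the SBS96 nor the ID83 set")
}

#' Read a reference signature matrix (COSMIC layout)
#'
#' First column holds channel labels (e.g. `A[C>A]A`), remaining columns one
#' signature each. Rows are reordered to the canonical channel order and
#' columns are normalised to sum to one.
#'
#' @param path path to the TSV.
#' @return numeric matrix (channels x signatures) with unit column sums.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(df[[1]])
  kind <- infer_channel_kind(labels)
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric signature values in ", path)
  rownames(m) <- labels
  m <- m[channel_labels(kind), , drop = FALSE]
  signature_matrix(m)
}

#' Validate and column-normalise a signature matrix
#' @param m non-negative channels x signatures matrix with channel rownames.
#' @return the matrix with columns scaled to sum to one.
#' @export
signature_matrix <- function(m) {
  if (is.null(rownames(m))) stop("signature matrix needs channel rownames")
  kind <- infer_channel_kind(rownames(m))
  m <- m[channel_labels(kind), , drop = FALSE]
  if (any(m < 0)) stop("signature matrix entries must be non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) stop("signature column with zero mass")
  sweep(m, 2, cs, "/")
}

#' Write a signature matrix as COSMIC-layout TSV
#' @param m channels x signatures matrix.
#' @param path output path.
#' @export
write_signature_matrix <- function(m, path) {
  df <- data.frame(Type = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
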