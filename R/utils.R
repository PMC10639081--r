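# internal helpers shared across modules

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# vectorised reverse complement for short uppercase sequences
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_pyrimidine <- function(base) base %in% c("C", "T")

#' Infer the mutation class of ref/alt allele pairs
#'
#' SBS when both alleles are single bases, INS when the alternate allele is
#' longer than the reference allele (VCF anchoring), DEL when it is shorter.
#'
#' @param ref,alt character vectors of reference and alternate alleles.
#' @return character vector with values `"SBS"`, `"INS"` or `"DEL"`.
#' @export
mut_class_of <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- ifelse(nr == 1L & na == 1L, "SBS", ifelse(na > nr, "INS", "DEL"))
  bad <- nr == na & nr > 1L
  if (any(bad)) {
    stop("ambiguous allele pair (equal lengths > 1) at entry ",
         which(bad)[1])
  }
  out
}

# assemble a mutation-record data frame with invariant checks
mutation_records <- function(sample_id, chrom, pos, ref, alt,
                             vaf = NA_real_, score = NA_real_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    stringsAsFactors = FALSE
  )
  df$mut_class <- if (nrow(df)) mut_class_of(df$ref, df$alt) else character(0)
  df$vaf <- rep_len(as.numeric(vaf), nrow(df))
  df$score <- rep_len(as.numeric(score), nrow(df))
  if (any(df$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad_vaf <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
  if (any(bad_vaf)) stop("vaf outside [0, 1] at record ", which(bad_vaf)[1])
  df
}

# merge 1-based inclusive intervals into a disjoint sorted union
interval_union <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  us <- start[1]
  ue <- end[1]
  ks <- numeric(0)
  ke <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ue + 1) {
      ue <- max(ue, end[i])
    } else {
      ks <- c(ks, us)
      ke <- c(ke, ue)
      us <- start[i]
      ue <- end[i]
    }
  }
  data.frame(start = c(ks, us), end = c(ke, ue))
}

# membership of positions in a sorted disjoint interval union
point_in_union <- function(pos, un) {
  if (nrow(un) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, un$start)
  idx > 0L & pos <= un$end[pmax(idx, 1L)]
}
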