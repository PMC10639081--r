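# Signature refitting (non-negative least squares), strict greedy signature
# removal, de novo extraction by NMF, oxygen difference spectra and the
# two-component decomposition used for stratified mutation sets.

#' Fit a spectrum to a reference signature set (non-negative least squares)
#'
#' Exposures minimise `||spectrum - sigs %*% e||_2` subject to `e >= 0`
#' (Lawson-Hanson NNLS). Exposures carry mutation-count units when the
#' spectrum holds counts.
#'
#' @param spectrum a [mut_spectrum()] or named numeric vector of channel
#'   values.
#' @param sigs channels x signatures matrix with unit column sums.
#' @return an object of class `signature_fit` with elements `exposures`,
#'   `cosine` (reconstruction cosine, `NA` for an all-zero spectrum),
#'   `fitted`, and `removed` (empty here).
#' @export
refit <- function(spectrum, sigs) {
  y <- as.numeric(spectrum)
  if (!is.null(names(spectrum)) && !is.null(rownames(sigs))) {
    if (!identical(names(spectrum), rownames(sigs))) {
      if (!setequal(names(spectrum), rownames(sigs))) {
        stop("spectrum and signature channels do not match")
      }
      sigs <- sigs[names(spectrum), , drop = FALSE]
    }
  } else if (length(y) != nrow(sigs)) {
    stop("spectrum length does not match signature channels")
  }
  if (ncol(sigs) < 1) stop("need at least one signature")
  if (all(y == 0)) {
    e <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
    return(structure(list(exposures = e, cosine = NA_real_,
                          fitted = y * 0, removed = character(0)),
                     class = "signature_fit"))
  }
  fit <- pracma::lsqnonneg(sigs, y)
  e <- stats::setNames(fit$x, colnames(sigs))
  fitted <- as.numeric(sigs %*% e)
  cs <- if (all(fitted == 0)) 0 else cosine(y, fitted)
  structure(list(exposures = e, cosine = cs, fitted = fitted,
                 removed = character(0)),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat(sprintf("<signature_fit: %d signatures, reconstruction cosine %.4f>\n",
              length(x$exposures), x$cosine))
  e <- sort(x$exposures[x$exposures > 0], decreasing = TRUE)
  if (length(e)) {
    cat("  exposures:",
        paste(sprintf("%s=%.3g", names(e), e), collapse = ", "), "\n")
  }
  if (length(x$removed)) {
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' Strict signature refitting with greedy removal
#'
#' Iteratively refits, then removes the signature whose removal decreases the
#' reconstruction cosine the least (ties broken by signature order); a removal
#' is accepted while that decrease is smaller than `max_delta`, and the last
#' remaining signature is never removed. `max_delta = 0` reduces to [refit()].
#'
#' @param spectrum spectrum vector.
#' @param sigs channels x signatures matrix.
#' @param max_delta strictness: largest acceptable cosine decrease per
#'   removal (default 0.004).
#' @return a `signature_fit`; `removed` lists the dropped signatures in
#'   removal order.
#' @export
refit_strict <- function(spectrum, sigs, max_delta = 0.004) {
  keep <- colnames(sigs)
  if (is.null(keep)) {
    keep <- paste0("S", seq_len(ncol(sigs)))
    colnames(sigs) <- keep
  }
  removed <- character(0)
  current <- refit(spectrum, sigs[, keep, drop = FALSE])
  while (length(keep) > 1L) {
    cos_without <- vapply(seq_along(keep), function(j) {
      refit(spectrum, sigs[, keep[-j], drop = FALSE])$cosine
    }, numeric(1))
    drop_j <- which.max(cos_without)     # smallest cosine decrease; first wins
    delta <- max(0, current$cosine - cos_without[drop_j])
    if (is.na(delta) || delta >= max_delta) break
    removed <- c(removed, keep[drop_j])
    keep <- keep[-drop_j]
    current <- refit(spectrum, sigs[, keep, drop = FALSE])
  }
  full <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
  full[names(current$exposures)] <- current$exposures
  structure(list(exposures = full, cosine = current$cosine,
                 fitted = current$fitted, removed = removed),
            class = "signature_fit")
}

#' De novo signature extraction by NMF
#'
#' Multiplicative-update non-negative matrix factorisation minimising the
#' Frobenius error, best of `n_starts` seeded random restarts; bitwise
#' reproducible for a fixed seed. Signature columns are normalised to unit
#' sum with exposures rescaled accordingly.
#'
#' @param catalog non-negative channels x samples matrix (counts).
#' @param k factorisation rank (number of signatures), `k < n_samples`.
#' @param n_starts number of random restarts.
#' @param seed RNG seed.
#' @param max_iter maximum update iterations per restart.
#' @param tol relative-change stopping tolerance on the Frobenius error.
#' @return object of class `mut_nmf` with elements `signatures` (channels x
#'   k, unit column sums), `exposures` (k x samples), `error` (Frobenius
#'   norm of the residual) and `k`.
#' @export
nmf_extract <- function(catalog, k, n_starts = 200L, seed = 1L,
                        max_iter = 2000L, tol = 1e-6) {
  V <- as.matrix(catalog)
  if (any(V < 0)) stop("catalog must be non-negative")
  if (k >= ncol(V)) stop("rank k must be smaller than the number of samples")
  if (k > nrow(V)) stop("rank k exceeds the number of channels")
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_starts)) {
    set.seed(seed * 1000L + r)
    W <- matrix(stats::runif(nrow(V) * k), nrow(V), k)
    H <- matrix(stats::runif(k * ncol(V)), k, ncol(V))
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
    if (is.null(best) || err < best$error) {
      best <- list(W = W, H = H, error = err)
    }
  }
  cs <- colSums(best$W)
  cs[cs == 0] <- 1
  W <- sweep(best$W, 2, cs, "/")
  H <- sweep(best$H, 1, cs, "*")
  colnames(W) <- paste0("N", seq_len(k))
  rownames(H) <- colnames(W)
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  structure(list(signatures = W, exposures = H, error = best$error, k = k),
            class = "mut_nmf")
}

#' @export
print.mut_nmf <- function(x, ...) {
  cat(sprintf("<mut_nmf: rank %d, %d channels x %d samples, Frobenius error %.4g>\n",
              x$k, nrow(x$signatures), ncol(x$exposures), x$error))
  invisible(x)
}

#' Reconstruction-error scree over candidate NMF ranks
#'
#' Supports the choice of rank; no automatic selection is made.
#'
#' @param catalog channels x samples matrix.
#' @param ks candidate ranks.
#' @inheritParams nmf_extract
#' @return data frame with columns `k` and `error`.
#' @export
nmf_scree <- function(catalog, ks, n_starts = 20L, seed = 1L) {
  data.frame(k = ks, error = vapply(ks, function(k) {
    nmf_extract(catalog, k, n_starts = n_starts, seed = seed)$error
  }, numeric(1)))
}

#' Oxygen difference spectrum
#'
#' Normalises both spectra by their population doublings, floors the
#' channel-wise difference `high/norm_high - low/norm_low` at zero, and
#' renormalises to unit sum. The number of floored channels is reported in
#' the `floored` attribute so the choice is auditable.
#'
#' @param high,low count spectra over the same channels.
#' @param norm_high,norm_low positive normalisation constants (population
#'   doublings).
#' @return a normalised [mut_spectrum()].
#' @export
difference_spectrum <- function(high, low, norm_high = 1, norm_low = 1) {
  if (norm_high <= 0 || norm_low <= 0) stop("norms must be positive")
  kind <- attr(high, "kind")
  if (!is.null(kind) && !identical(kind, attr(low, "kind"))) {
    stop("spectra have different channel sets")
  }
  d <- as.numeric(high) / norm_high - as.numeric(low) / norm_low
  floored <- sum(d < 0)
  d <- pmax(d, 0)
  if (sum(d) == 0) stop("difference spectrum is undefined (all channels zero)")
  names(d) <- names(high)
  out <- if (is.null(kind)) d / sum(d) else
    mut_spectrum(d / sum(d), kind, normalized = TRUE)
  attr(out, "floored") <- floored
  out
}

#' Two-component decomposition of stratified spectra
#'
#' Refits each stratum spectrum (e.g. replication-timing deciles) against a
#' two-column signature matrix made of a baseline component and a difference
#' component; warns when the components are effectively collinear.
#'
#' @param stratum_spectra list of spectra (counts), one per stratum.
#' @param comp_low baseline component (normalised spectrum).
#' @param comp_diff difference component (normalised spectrum).
#' @return data frame with one row per stratum: exposures of both components
#'   and the reconstruction cosine.
#' @export
two_component_fit <- function(stratum_spectra, comp_low, comp_diff) {
  if (cosine(comp_low, comp_diff) > 1 - 1e-8) {
    warning("components are collinear; the decomposition is ill-conditioned")
  }
  S <- cbind(low = as.numeric(comp_low) / sum(comp_low),
             diff = as.numeric(comp_diff) / sum(comp_diff))
  rownames(S) <- names(comp_low)
  res <- lapply(stratum_spectra, function(sp) {
    f <- refit(sp, S)
    c(low = unname(f$exposures["low"]), diff = unname(f$exposures["diff"]),
      cosine = f$cosine)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$stratum <- if (!is.null(names(stratum_spectra))) {
    names(stratum_spectra)
  } else {
    seq_along(stratum_spectra)
  }
  out[c("stratum", "low", "diff", "cosine")]
}

#' Assemble a substituted reference signature set
#'
#' Retains the base signatures (minus those dropped) in their original order
#' and appends the additions.
#'
#' @param base channels x signatures matrix.
#' @param drop character vector of signature names to remove from `base`.
#' @param add optional channels x signatures matrix to append.
#' @return the combined matrix.
#' @export
assemble_reference_set <- function(base, drop = character(0), add = NULL) {
  unknown <- setdiff(drop, colnames(base))
  if (length(unknown)) {
    stop("unknown signature name(s) in drop: ",
         paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(base), drop)
  out <- base[, keep, drop = FALSE]
  if (!is.null(add)) {
    if (!identical(rownames(base), rownames(add))) {
      if (is.null(rownames(add)) || !setequal(rownames(add), rownames(base))) {
        stop("channel sets of base and add differ")
      }
      add <- add[rownames(base), , drop = FALSE]
    }
    out <- cbind(out, add)
  }
  if (anyDuplicated(colnames(out))) {
    stop("duplicate signature name after merge: ",
         colnames(out)[duplicated(colnames(out))][1])
  }
  out
}

#' Classify a sample as MMR deficient from its signature fit
#'
#' @param fit a `signature_fit` containing exposures for all of `mmrd_names`.
#' @param mmrd_names names of the MMRd signatures to sum.
#' @param min_mutations strict threshold on the summed exposure.
#' @return `TRUE` iff the summed exposure is strictly greater than
#'   `min_mutations`.
#' @export
select_mmrd <- function(fit, mmrd_names = c("MMRd-A", "MMRd-B"),
                        min_mutations = 1000) {
  e <- fit$exposures
  missing <- setdiff(mmrd_names, names(e))
  if (length(missing)) {
    stop("fit lacks signature(s): ", paste(missing, collapse = ", "))
  }
  sum(e[mmrd_names]) > min_mutations
}
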