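#' Cosine similarity between two 96-channel vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return `u . v / (|u| |v|)`, in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop_data("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_data("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# Golden-section minimisation of f on [lo, hi] to tolerance tol on x.
golden_section <- function(f, lo = 0, hi = 1, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  x <- (a + b) / 2
  list(x = x, fx = f(x))
}

# Weight update used by both selection and refinement: set signature k's
# weight to `a`, rescaling the whole vector onto the simplex if it overflows.
adjust_weights <- function(w, k, a) {
  w[k] <- a
  s <- sum(w)
  if (s > 1) w <- w / s
  w
}

#' Deconstruct a spectrum into non-negative reference-signature exposures
#'
#' Fits a mutation spectrum as a convex combination of reference signatures
#' by iterative forward selection: the spectrum is normalised to
#' proportions, the single best-fitting signature starts the model, and at
#' each step every candidate signature's weight is optimised by
#' golden-section search on `[0, 1]` (existing weights rescaled to keep the
#' total at or below 1); the best candidate is accepted while the relative
#' reduction in the sum of squared channel errors (SSE) exceeds `rel_tol`.
#' After convergence, signatures whose weight falls below `prune_threshold`
#' are dropped and the fit is re-refined over the survivors by coordinate
#' descent.
#'
#' @param spectrum a `spectrum` object (see [build_spectrum()]) or a named
#'   96-vector of channel counts.
#' @param signatures a `signature_catalog`.
#' @param prune_threshold drop signatures with final weight below this
#'   (default 0.06).
#' @param max_signatures cap on the number of signatures in the model
#'   (default 10); a message is emitted when the cap binds.
#' @param rel_tol stop when the relative SSE improvement of the best
#'   candidate falls below this (default 1e-3).
#' @param gs_tol golden-section tolerance on a weight (default 1e-4).
#' @param context_scaling optional positive 96-vector multiplied into the
#'   signature columns before fitting (e.g. exome/genome trinucleotide
#'   abundance correction); columns are renormalised after scaling.
#' @return an object of class `exposure_fit`: `weights` (named, all at or
#'   above `prune_threshold`), `unexplained` (`1 - sum(weights)`),
#'   `reconstruction` (96-vector), `sse`, `cosine`, `prune_threshold`.
#' @export
fit_exposures <- function(spectrum, signatures, prune_threshold = 0.06,
                          max_signatures = 10L, rel_tol = 1e-3,
                          gs_tol = 1e-4, context_scaling = NULL) {
  counts <- if (inherits(spectrum, "spectrum")) spectrum$counts else spectrum
  if (length(counts) != 96L) stop_data("spectrum must have 96 channels")
  if (!is.null(names(counts)) && !identical(names(counts), signatures$channels)) {
    if (!setequal(names(counts), signatures$channels)) {
      stop_data("spectrum channels do not match the signature catalog")
    }
    counts <- counts[signatures$channels]
  }
  total <- sum(counts)
  if (total <= 0) stop_data("empty spectrum: no SNVs to fit")
  t_vec <- as.numeric(counts) / total
  P <- signatures$matrix
  if (!is.null(context_scaling)) {
    if (length(context_scaling) != 96L || any(context_scaling <= 0)) {
      stop_data("context_scaling must be a positive 96-vector")
    }
    P <- P * context_scaling
    P <- sweep(P, 2, colSums(P), "/")
  }
  K <- ncol(P)
  sse_of <- function(w) { r <- t_vec - as.numeric(P %*% w); sum(r * r) }

  best_weight_for <- function(w, k) {
    gs <- golden_section(function(a) sse_of(adjust_weights(w, k, a)),
                         0, 1, tol = gs_tol)
    gs
  }

  # forward selection
  w <- numeric(K)
  sse0 <- sse_of(w)
  first <- lapply(seq_len(K), function(k) best_weight_for(w, k))
  k0 <- which.min(vapply(first, `[[`, numeric(1), "fx"))
  w <- adjust_weights(w, k0, first[[k0]]$x)
  sse <- sse_of(w)
  capped <- FALSE
  repeat {
    cand <- lapply(seq_len(K), function(k) best_weight_for(w, k))
    fx <- vapply(cand, `[[`, numeric(1), "fx")
    active <- which(w > 0)
    new_sig <- !(seq_len(K) %in% active)
    if (length(active) >= max_signatures) {
      if (any(new_sig) && min(fx[new_sig]) < min(fx[!new_sig])) capped <- TRUE
      fx[new_sig] <- Inf
    }
    k <- which.min(fx)
    if (!is.finite(fx[k])) break
    if ((sse - fx[k]) / sse <= rel_tol) break
    w <- adjust_weights(w, k, cand[[k]]$x)
    sse <- fx[k]
  }
  if (capped) message("fit_exposures: max_signatures cap of ", max_signatures, " reached")

  refine <- function(w, keep) {
    # coordinate-descent passes over the retained signatures
    repeat {
      delta <- 0
      for (k in keep) {
        gs <- best_weight_for(w, k)
        if (gs$fx < sse_of(w) - 1e-12) {
          delta <- delta + abs(gs$x - w[k])
          w <- adjust_weights(w, k, gs$x)
        }
      }
      if (delta < gs_tol) break
    }
    w
  }

  # prune-and-refit until every retained weight clears the threshold
  repeat {
    keep <- which(w >= prune_threshold)
    if (length(keep) == 0L) {
      keep <- which.max(w)
    }
    w2 <- numeric(K)
    w2[keep] <- w[keep]
    w2 <- refine(w2, keep)
    w <- w2
    if (all(w[w > 0] >= prune_threshold)) break
    w[w < prune_threshold] <- 0
    if (sum(w) == 0) break
  }

  recon <- as.numeric(P %*% w)
  names(recon) <- signatures$channels
  weights <- stats::setNames(w, signatures$names)
  weights <- weights[weights > 0]
  structure(list(weights = weights,
                 unexplained = max(0, 1 - sum(w)),
                 reconstruction = recon,
                 sse = sse_of(w),
                 cosine = if (sum(recon) > 0) cosine_similarity(t_vec, recon) else NA_real_,
                 prune_threshold = prune_threshold,
                 total_snvs = total),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("exposure_fit on", x$total_snvs, "SNVs\n")
  w <- sort(x$weights, decreasing = TRUE)
  for (nm in names(w)) cat(sprintf("  %-8s %.4f\n", nm, w[nm]))
  cat(sprintf("  unexplained %.4f | SSE %.3e | cosine %.4f\n",
              x$unexplained, x$sse, x$cosine))
  invisible(x)
}

#' Bundled signature aetiology lookup
#'
#' Proposed aetiologies of commonly encountered COSMIC SBS signatures, with
#' a flag for signatures regarded as possible sequencing artefacts.
#'
#' @return `data.table` with columns `signature`, `aetiology`, `artefact`.
#' @export
signature_aetiologies <- function() {
  art <- c("SBS27", "SBS43", paste0("SBS", 45:60), "SBS95")
  tab <- data.table::data.table(
    signature = c("SBS1", "SBS2", "SBS3", "SBS4", "SBS5", "SBS6", "SBS7a",
                  "SBS9", "SBS10a", "SBS10b", "SBS13", "SBS14", "SBS15",
                  "SBS18", "SBS20", "SBS21", "SBS26", "SBS39", "SBS40",
                  "SBS44", "SBS54", "SBS87", "SBS88"),
    aetiology = c(
      "spontaneous or enzymatic deamination of 5-methylcytosine (clock-like)",
      "APOBEC cytidine deaminase activity",
      "defective homologous recombination repair",
      "tobacco smoking",
      "clock-like, aetiology unknown",
      "defective DNA mismatch repair (dMMR)",
      "ultraviolet light",
      "polymerase eta somatic hypermutation",
      "POLE exonuclease domain mutation",
      "POLE exonuclease domain mutation",
      "APOBEC cytidine deaminase activity",
      "concurrent POLE mutation and dMMR",
      "defective DNA mismatch repair (dMMR)",
      "reactive oxygen species damage",
      "concurrent POLD1 mutation and dMMR",
      "defective DNA mismatch repair (dMMR)",
      "defective DNA mismatch repair (dMMR)",
      "aetiology unknown",
      "aetiology unknown",
      "defective DNA mismatch repair (dMMR)",
      "possible contamination by germline variants",
      "thiopurine chemotherapy",
      "colibactin exposure"))
  extra <- data.table::data.table(signature = setdiff(art, tab$signature),
                                  aetiology = "possible sequencing artefact")
  out <- rbind(tab, extra)
  out$artefact <- out$signature %in% art
  out
}

#' Annotate a fit with signature aetiologies
#'
#' Joins the retained signatures of an [fit_exposures()] result with an
#' aetiology lookup and flags artefact-associated signatures. Signatures
#' absent from the lookup are labelled `"unknown"`.
#'
#' @param fit an `exposure_fit`.
#' @param aetiology_map lookup with columns `signature`, `aetiology`,
#'   `artefact`; defaults to [signature_aetiologies()].
#' @return `data.table` with `signature`, `weight`, `aetiology`, `artefact`.
#' @export
compare_to_reference <- function(fit, aetiology_map = signature_aetiologies()) {
  sig <- names(fit$weights)
  idx <- match(sig, aetiology_map$signature)
  data.table::data.table(
    signature = sig,
    weight = as.numeric(fit$weights),
    aetiology = ifelse(is.na(idx), "unknown", aetiology_map$aetiology[idx]),
    artefact = ifelse(is.na(idx), FALSE, aetiology_map$artefact[idx]))
}
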