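#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe
#' a small but realistic desk-scale cohort: a handful of megabase contigs,
#' tens of samples, a background mutation load drawn from a known signature
#' mixture, injected kataegis showers of at least 6 mutations with short
#' geometric intermutational gaps, and expression/survival tables with a
#' known group hazard ratio.
#'
#' @param seed integer master seed.
#' @param n_contigs number of reference contigs.
#' @param ref_length_per_contig contig length in bp.
#' @param gc GC fraction of the reference (default 0.41, genome-like).
#' @param n_samples cohort size.
#' @param background_snvs_per_sample background SNVs drawn per sample.
#' @param true_exposures named non-negative weights over the signature
#'   names, summing to 1.
#' @param kataegis_spec list of cluster specs, each a list with
#'   `n_clusters`, `cluster_size` (>= 6), `imd_mean` (bp),
#'   `tpc_fraction`, `c_to_t_fraction` (both in `[0, 1]`).
#' @param expression_model list: `high_group_fraction`,
#'   `kataegis_rate_effect` (multiplier on injected clusters in the
#'   high-expression group), `low_mean`, `high_mean`, `sdlog`.
#' @param survival_model list: `baseline_hazard` (events/day in the low
#'   group), `true_hr` (high vs low), `censoring_rate` (expected censored
#'   fraction).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 2L,
                       ref_length_per_contig = 5e5,
                       gc = 0.41,
                       n_samples = 20L,
                       background_snvs_per_sample = 200L,
                       true_exposures = c(SBS_APOBEC = 0.7, SBS_AGE = 0.3),
                       kataegis_spec = list(list(n_clusters = 3L, cluster_size = 8L,
                                                 imd_mean = 100, tpc_fraction = 0.9,
                                                 c_to_t_fraction = 0.8)),
                       expression_model = list(high_group_fraction = 0.5,
                                               kataegis_rate_effect = 2,
                                               low_mean = 100, high_mean = 1000,
                                               sdlog = 0.3),
                       survival_model = list(baseline_hazard = 1 / 600,
                                             true_hr = 3, censoring_rate = 0.2)) {
  if (abs(sum(true_exposures) - 1) > 1e-9) stop_data("true_exposures must sum to 1")
  if (any(true_exposures < 0)) stop_data("true_exposures must be non-negative")
  for (ks in kataegis_spec) {
    if (ks$cluster_size < 6L) stop_data("kataegis cluster_size must be >= 6")
    if (ks$imd_mean <= 0) stop_data("imd_mean must be > 0")
    if (ks$tpc_fraction < 0 || ks$tpc_fraction > 1) stop_data("tpc_fraction in [0,1]")
    if (ks$c_to_t_fraction < 0 || ks$c_to_t_fraction > 1) stop_data("c_to_t_fraction in [0,1]")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 ref_length_per_contig = ref_length_per_contig, gc = gc,
                 n_samples = as.integer(n_samples),
                 background_snvs_per_sample = as.integer(background_snvs_per_sample),
                 true_exposures = true_exposures,
                 kataegis_spec = kataegis_spec,
                 expression_model = expression_model,
                 survival_model = survival_model),
            class = "sim_config")
}

#' Generate a random reference sequence
#'
#' i.i.d. bases at a configurable GC fraction; deterministic for a given
#' seed.
#'
#' @param n_contigs number of contigs (named `"1"`, `"2"`, ...).
#' @param length_per_contig contig length in bp (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a [ref_seq].
#' @export
generate_reference <- function(n_contigs = 1L, length_per_contig = 1e5,
                               gc = 0.41, seed = 1L) {
  if (length_per_contig <= 0) stop_data("length_per_contig must be > 0")
  if (gc < 0 || gc > 1) stop_data("gc must be in [0, 1]")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    contigs <- lapply(seq_len(n_contigs), function(i) {
      paste(sample(names(p), length_per_contig, replace = TRUE, prob = p),
            collapse = "")
    })
    names(contigs) <- as.character(seq_len(n_contigs))
    ref_seq(contigs)
  })
}

#' Built-in synthetic reference signatures
#'
#' Small signature catalog constructed in code for simulation and testing
#' (these are synthetic profiles shaped like well-known processes, not
#' COSMIC data): `SBS_APOBEC` concentrates on T[C>T]W and T[C>G]W (the tCw
#' APOBEC target), `SBS_AGE` on N[C>T]G (CpG deamination), `SBS_FLAT` is
#' uniform over the 96 channels, and `SBS_TCT` is a point mass on
#' `T[C>T]A`/`T[C>T]T`.
#'
#' @param which signature names to include.
#' @return a `signature_catalog`.
#' @export
synthetic_signatures <- function(which = c("SBS_APOBEC", "SBS_AGE", "SBS_FLAT")) {
  ch <- sbs_channels()
  mk <- function(weights) {
    v <- stats::setNames(numeric(96), ch)
    v[names(weights)] <- weights
    v / sum(v)
  }
  defs <- list(
    SBS_APOBEC = mk(c("T[C>T]A" = 0.33, "T[C>T]T" = 0.27,
                      "T[C>G]A" = 0.22, "T[C>G]T" = 0.18)),
    SBS_AGE = mk(stats::setNames(rep(0.25, 4),
                                 paste0(c("A", "C", "G", "T"), "[C>T]G"))),
    SBS_FLAT = rep(1 / 96, 96),
    SBS_TCT = mk(c("T[C>T]A" = 0.5, "T[C>T]T" = 0.5)))
  bad <- setdiff(which, names(defs))
  if (length(bad)) stop_data("unknown synthetic signature(s): ", paste(bad, collapse = ", "))
  mat <- vapply(which, function(nm) defs[[nm]], numeric(96))
  rownames(mat) <- ch
  signature_catalog(mat)
}

# channel index (1..96) -> collapsed context id (0..31) and alt base int
channel_ctx <- function(i) {
  cls <- (i - 1L) %/% 16L
  within <- (i - 1L) %% 16L
  16L * (cls >= 3L) + within
}

channel_alt_int <- function(i) {
  cls <- (i - 1L) %/% 16L
  alts <- rbind(c(0L, 2L, 3L), c(0L, 1L, 2L))  # C-centre / T-centre
  alts[cbind(1L + (cls >= 3L), (cls %% 3L) + 1L)]
}

#' Simulate a background mutation catalog from a signature mixture
#'
#' Each SNV is drawn by sampling a 96-channel from the mixture
#' `sum_k w_k P[, k]`, choosing uniformly (without replacement per sample)
#' among reference positions whose pyrimidine-collapsed trinucleotide
#' matches the channel's context, and writing ref/alt on the + strand
#' (reverse-complemented at purine-centred sites). Empirical channel
#' frequencies therefore converge to the mixture.
#'
#' @param ref a [ref_seq].
#' @param signatures a `signature_catalog`.
#' @param exposures named weights over `signatures$names`, summing to 1.
#' @param n_samples number of samples (`sample_prefix` + index ids).
#' @param snvs_per_sample background SNVs per sample.
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample ids.
#' @return a mutation catalog (`data.table`, sorted).
#' @export
simulate_background <- function(ref, signatures, exposures, n_samples = 1L,
                                snvs_per_sample = 100L, seed = 1L,
                                sample_prefix = "S") {
  w <- stats::setNames(numeric(length(signatures$names)), signatures$names)
  w[names(exposures)] <- exposures
  if (abs(sum(w) - 1) > 1e-9) stop_data("exposures must sum to 1")
  p96 <- as.numeric(signatures$matrix %*% w)
  sites <- context_site_index(ref)
  by_ctx <- split(sites, sites$ctx)
  ctx_of_channel <- channel_ctx(1:96)
  # every channel with positive mixture probability needs an eligible site
  need <- which(p96 > 0)
  missing_ctx <- !(as.character(ctx_of_channel[need]) %in% names(by_ctx))
  if (any(missing_ctx)) {
    stop_data("no eligible reference site for channel ",
              sbs_channels()[need[which(missing_ctx)[1]]])
  }
  alt_of_channel <- channel_alt_int(1:96)
  contigs <- unclass(ref)
  with_seed(seed, {
    out <- lapply(seq_len(n_samples), function(si) {
      sid <- sprintf("%s%02d", sample_prefix, si)
      draws <- as.integer(stats::rmultinom(1, snvs_per_sample, p96))
      recs <- lapply(unique(ctx_of_channel[draws > 0]), function(ctx) {
        chans <- which(ctx_of_channel == ctx & draws > 0)
        n_ctx <- sum(draws[chans])
        tab <- by_ctx[[as.character(ctx)]]
        if (nrow(tab) < n_ctx) {
          stop_data("not enough eligible sites for context ",
                    context_labels()[ctx + 1L], " (need ", n_ctx,
                    ", have ", nrow(tab), ")")
        }
        pick <- tab[sample.int(nrow(tab), n_ctx), ]
        chan_vec <- rep(chans, draws[chans])
        alt_int <- alt_of_channel[chan_vec]
        # write on + strand: purine-centred sites take the complemented alt
        alt_plus <- ifelse(pick$pur, 3L - alt_int, alt_int)
        ref_base <- vapply(seq_len(n_ctx), function(k)
          contig_bases(contigs[[pick$chrom[k]]], pick$pos[k]), character(1))
        data.table::data.table(sample_id = sid, chrom = pick$chrom,
                               pos = pick$pos, ref = ref_base,
                               alt = INT_BASE[alt_plus + 1L],
                               variant_type = "SNP",
                               variant_classification = NA_character_,
                               gene = NA_character_)
      })
      data.table::rbindlist(recs)
    })
    sort_catalog(data.table::rbindlist(out))
  })
}

# Positions of TpC sites on either strand (C preceded by T on +, or G
# followed by A on +, i.e. TpC on the - strand), per contig.
tpc_sites <- function(contig_seq) {
  x <- encode_bases(contig_seq)
  L <- length(x)
  pos <- 2:(L - 1L)
  isC <- x[pos] == 1L & x[pos - 1L] == 3L
  isG <- x[pos] == 2L & x[pos + 1L] == 0L
  pos[isC | isG]
}

#' Inject kataegis showers into a catalog
#'
#' Places mutation clusters at uniformly chosen anchors: successive
#' positions are separated by geometric gaps with the requested mean,
#' snapped to the nearest unused TpC site with probability `tpc_fraction`
#' (TpC mutations become C>T with probability `c_to_t_fraction`, otherwise
#' C>A/C>G; unsnapped positions mutate whatever base they land on). Every
#' injected record and cluster span is recorded in a truth table; the
#' returned catalog is re-sorted.
#'
#' Clusters are assigned round-robin over `samples`.
#'
#' @param catalog base catalog to extend (may be empty).
#' @param ref a [ref_seq].
#' @param kataegis_spec list of cluster specs (see [sim_config()]).
#' @param seed integer seed.
#' @param samples sample ids receiving clusters (default: all catalog
#'   samples).
#' @return list with `catalog` (extended, sorted), `truth` (one row per
#'   cluster: `sample_id`, `chrom`, `start`, `end`, `size`, `class`) and
#'   `records` (the injected records themselves).
#' @export
inject_kataegis <- function(catalog, ref, kataegis_spec, seed = 1L,
                            samples = NULL) {
  validate_catalog(catalog)
  if (is.null(samples)) samples <- unique(catalog$sample_id)
  if (!length(samples)) stop_data("no samples to inject into")
  contigs <- unclass(ref)
  lens <- ref_lengths(ref)
  tpc <- lapply(contigs, tpc_sites)
  with_seed(seed, {
    truth <- list(); added <- list()
    used <- new.env(parent = emptyenv())
    used_key <- function(sid, chrom) paste0(sid, "\r", chrom)
    get_used <- function(sid, chrom) {
      k <- used_key(sid, chrom)
      if (!is.null(used[[k]])) used[[k]]
      else {
        u <- catalog$pos[catalog$sample_id == sid & catalog$chrom == chrom]
        used[[k]] <- u
        u
      }
    }
    si <- 0L
    for (ks in kataegis_spec) {
      for (cl in seq_len(ks$n_clusters)) {
        si <- si + 1L
        sid <- samples[((si - 1L) %% length(samples)) + 1L]
        placed <- FALSE
        for (try in 1:100) {
          chrom <- sample(names(contigs), 1, prob = lens)
          L <- lens[[chrom]]
          gaps <- stats::rgeom(ks$cluster_size - 1L, 1 / ks$imd_mean) + 1L
          extent <- sum(gaps)
          if (extent > L - 4L) next
          anchor <- sample.int(L - 2L - extent, 1) + 1L
          prop <- anchor + c(0L, cumsum(gaps))
          u <- get_used(sid, chrom)
          snap <- stats::runif(length(prop)) < ks$tpc_fraction
          final <- integer(length(prop))
          for (k in seq_along(prop)) {
            if (snap[k]) {
              cand <- setdiff(tpc[[chrom]], c(u, final[seq_len(k - 1L)]))
            } else {
              cand <- setdiff(2:(L - 1L), c(u, final[seq_len(k - 1L)]))
            }
            if (!length(cand)) stop_data("no free site left on contig ", chrom)
            final[k] <- cand[which.min(abs(cand - prop[k]))]
          }
          final <- sort(final)
          recs <- data.table::rbindlist(lapply(final, function(p) {
            b <- contig_bases(contigs[[chrom]], p)
            is_snapped <- p %in% tpc[[chrom]] && b %in% c("C", "G")
            if (is_snapped) {
              # collapsed C>T with prob c_to_t_fraction, else C>A or C>G
              alt_c <- if (stats::runif(1) < ks$c_to_t_fraction) "T"
                       else sample(c("A", "G"), 1)
              alt <- if (b == "C") alt_c else chartr("ACGT", "TGCA", alt_c)
            } else {
              alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
            }
            data.table::data.table(sample_id = sid, chrom = chrom, pos = p,
                                   ref = b, alt = alt, variant_type = "SNP",
                                   variant_classification = NA_character_,
                                   gene = NA_character_)
          }))
          used[[used_key(sid, chrom)]] <- c(u, final)
          truth[[length(truth) + 1L]] <- data.table::data.table(
            sample_id = sid, chrom = chrom, start = min(final), end = max(final),
            size = ks$cluster_size,
            class = if (ks$tpc_fraction >= 1 && ks$c_to_t_fraction >= 1) {
              "tpc_to_tpt"
            } else if (ks$tpc_fraction >= 1) "tpc_to_tpx" else "mixed")
          added[[length(added) + 1L]] <- recs
          placed <- TRUE
          break
        }
        if (!placed) {
          stop_data("cluster of size ", ks$cluster_size,
                    " cannot fit inside any contig")
        }
      }
    }
    records <- sort_catalog(data.table::rbindlist(added))
    list(catalog = sort_catalog(rbind(catalog, records)),
         truth = data.table::rbindlist(truth),
         records = records)
  })
}

#' Simulate paired control / overexpressing catalogs
#'
#' The treated catalog is the control catalog plus newly acquired
#' mutations: fresh background drawn from an APOBEC-skewed mixture and,
#' optionally, newly injected kataegis clusters. The truth table lists
#' exactly the added records, so `subtract_catalog(treated, control)` has a
#' set-difference oracle.
#'
#' @param ref a [ref_seq].
#' @param signatures a `signature_catalog`.
#' @param baseline_exposures mixture for the shared baseline background.
#' @param n_baseline baseline SNV count.
#' @param added_exposures mixture for the newly acquired SNVs.
#' @param n_added newly acquired SNV count (0 gives `treated == control`).
#' @param kataegis_spec optional cluster specs for new showers.
#' @param seed integer seed.
#' @return list: `control`, `treated` (catalogs; samples `"control"` /
#'   `"treated"`), `truth` (catalog of the added records, labelled
#'   `"treated"`), `clusters` (truth spans of new showers, may be empty).
#' @export
simulate_paired_lines <- function(ref, signatures,
                                  baseline_exposures = c(SBS_FLAT = 1),
                                  n_baseline = 300L,
                                  added_exposures = c(SBS_APOBEC = 1),
                                  n_added = 200L,
                                  kataegis_spec = NULL,
                                  seed = 1L) {
  control <- simulate_background(ref, signatures, baseline_exposures,
                                 n_samples = 1L, snvs_per_sample = n_baseline,
                                 seed = seed, sample_prefix = "control_")
  control$sample_id <- "control"
  treated <- data.table::copy(control)
  treated$sample_id <- "treated"
  added <- NULL
  clusters <- data.table::data.table()
  if (n_added > 0L) {
    new_bg <- simulate_background(ref, signatures, added_exposures,
                                  n_samples = 1L, snvs_per_sample = n_added,
                                  seed = seed + 1L, sample_prefix = "new_")
    new_bg$sample_id <- "treated"
    # drop collisions with the baseline so truth is an exact set difference
    key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
    new_bg <- new_bg[!key(new_bg) %in% key(control), ]
    treated <- rbind(treated, new_bg)
    added <- new_bg
  }
  if (!is.null(kataegis_spec)) {
    inj <- inject_kataegis(treated, ref, kataegis_spec, seed = seed + 2L,
                           samples = "treated")
    treated <- inj$catalog
    clusters <- inj$truth
    added <- if (is.null(added)) inj$records else rbind(added, inj$records)
  }
  truth <- if (is.null(added)) {
    treated[0L, ]
  } else sort_catalog(added)
  list(control = sort_catalog(control), treated = sort_catalog(treated),
       truth = truth, clusters = clusters)
}

#' Simulate expression and survival tables with a known hazard ratio
#'
#' Expression is bimodal on a TPM-like scale (log-normal per group around a
#' known cutoff); survival times are exponential with hazard
#' `baseline_hazard` in the low group and `baseline_hazard * true_hr` in
#' the high group, under independent exponential censoring tuned to the
#' requested expected censoring fraction. `censoring_rate = 1` censors
#' every subject (events all 0), a degenerate input that downstream
#' log-rank tests reject.
#'
#' @param n_samples cohort size.
#' @param high_fraction expected fraction of high-expression samples.
#' @param low_mean,high_mean group medians of the log-normal expression.
#' @param sdlog log-scale standard deviation of expression.
#' @param baseline_hazard events per day in the low group.
#' @param true_hr hazard ratio of the high group versus the low group.
#' @param censoring_rate expected censored fraction in the low group.
#' @param seed integer seed.
#' @return list: `expression`, `survival` (tables as read by the IO
#'   module), `truth` (per-sample group, `true_cutoff` =
#'   geometric midpoint of the group medians, `true_hr`).
#' @export
simulate_cohort_tables <- function(n_samples = 100L, high_fraction = 0.5,
                                   low_mean = 100, high_mean = 1000,
                                   sdlog = 0.3, baseline_hazard = 1 / 600,
                                   true_hr = 3, censoring_rate = 0.2,
                                   seed = 1L) {
  with_seed(seed, {
    sid <- sprintf("P%03d", seq_len(n_samples))
    high <- stats::runif(n_samples) < high_fraction
    expr <- stats::rlnorm(n_samples,
                          meanlog = ifelse(high, log(high_mean), log(low_mean)),
                          sdlog = sdlog)
    haz <- baseline_hazard * ifelse(high, true_hr, 1)
    t_event <- stats::rexp(n_samples, rate = haz)
    if (censoring_rate >= 1) {
      time <- stats::rexp(n_samples, rate = baseline_hazard)
      event <- rep(0L, n_samples)
    } else if (censoring_rate <= 0) {
      time <- t_event
      event <- rep(1L, n_samples)
    } else {
      c_rate <- baseline_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n_samples, rate = c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    list(expression = data.table::data.table(sample_id = sid, expression = expr),
         survival = data.table::data.table(sample_id = sid, time = time,
                                           event = event),
         truth = list(group = data.table::data.table(sample_id = sid,
                                                     high = high),
                      true_cutoff = sqrt(low_mean * high_mean),
                      true_hr = true_hr))
  })
}

#' Simulate a simple tiling gene model
#'
#' Non-overlapping gene intervals laid across the reference at regular
#' spacing, for exercising gene annotation on synthetic cohorts.
#'
#' @param ref a [ref_seq].
#' @param gene_length,gap interval length and inter-gene gap in bp.
#' @return gene interval `data.table` (1-based inclusive, like
#'   [read_bed_genes()]).
#' @export
simulate_gene_model <- function(ref, gene_length = 10000L, gap = 5000L) {
  out <- lapply(names(ref), function(chrom) {
    L <- ref_lengths(ref)[[chrom]]
    starts <- seq(1L, max(1L, L - gene_length), by = gene_length + gap)
    data.table::data.table(chrom = chrom, start = starts,
                           end = pmin(starts + gene_length - 1L, L),
                           gene = sprintf("GENE_%s_%03d", chrom,
                                          seq_along(starts)),
                           strand = "*")
  })
  data.table::rbindlist(out)
}

#' Generate and write a full synthetic cohort to disk
#'
#' Runs the generator end-to-end under one configuration and writes the
#' artefacts the analysis pipeline consumes: `reference.fasta`,
#' `mutations.maf`, `genes.bed`, `signatures.tsv`, `expression.tsv`,
#' `survival.tsv` and the truth tables (`truth_clusters.tsv`,
#' `truth_groups.tsv`).
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects.
#' @export
write_simulated_cohort <- function(config, outdir) {
  obj <- simulate_cohort(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(obj$ref, file.path(outdir, "reference.fasta"))
  write_maf(obj$catalog, file.path(outdir, "mutations.maf"))
  write_bed_genes(obj$genes, file.path(outdir, "genes.bed"))
  write_signature_matrix(obj$signatures, file.path(outdir, "signatures.tsv"))
  data.table::fwrite(obj$expression, file.path(outdir, "expression.tsv"), sep = "\t")
  data.table::fwrite(obj$survival, file.path(outdir, "survival.tsv"), sep = "\t")
  data.table::fwrite(obj$cluster_truth, file.path(outdir, "truth_clusters.tsv"),
                     sep = "\t")
  data.table::fwrite(obj$group_truth, file.path(outdir, "truth_groups.tsv"),
                     sep = "\t")
  invisible(obj)
}

#' Generate a full synthetic cohort in memory
#'
#' @param config a [sim_config()].
#' @return list: `ref`, `signatures`, `catalog` (background + injected
#'   clusters), `genes`, `expression`, `survival`, `cluster_truth`,
#'   `group_truth`, `true_cutoff`, `true_hr`, `exposures`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- generate_reference(config$n_contigs, config$ref_length_per_contig,
                            config$gc, seed = config$seed)
  signatures <- synthetic_signatures()
  catalog <- simulate_background(ref, signatures, config$true_exposures,
                                 n_samples = config$n_samples,
                                 snvs_per_sample = config$background_snvs_per_sample,
                                 seed = config$seed + 1L)
  tables <- simulate_cohort_tables(
    n_samples = config$n_samples,
    high_fraction = config$expression_model$high_group_fraction,
    low_mean = config$expression_model$low_mean,
    high_mean = config$expression_model$high_mean,
    sdlog = config$expression_model$sdlog,
    baseline_hazard = config$survival_model$baseline_hazard,
    true_hr = config$survival_model$true_hr,
    censoring_rate = config$survival_model$censoring_rate,
    seed = config$seed + 2L)
  # align table sample ids with catalog sample ids
  samples <- sort(unique(catalog$sample_id))
  tables$expression$sample_id <- samples
  tables$survival$sample_id <- samples
  tables$truth$group$sample_id <- samples
  high <- tables$truth$group$sample_id[tables$truth$group$high]
  low <- setdiff(samples, high)
  # the high-expression group receives `kataegis_rate_effect` times the
  # injected clusters of the low group
  eff <- config$expression_model$kataegis_rate_effect
  inj_low <- if (length(low)) {
    inject_kataegis(catalog, ref, config$kataegis_spec,
                    seed = config$seed + 3L, samples = low)
  } else list(catalog = catalog, truth = data.table::data.table())
  spec_high <- lapply(config$kataegis_spec, function(ks) {
    ks$n_clusters <- as.integer(round(ks$n_clusters * eff)); ks
  })
  inj_high <- if (length(high)) {
    inject_kataegis(inj_low$catalog, ref, spec_high,
                    seed = config$seed + 4L, samples = high)
  } else list(catalog = inj_low$catalog, truth = data.table::data.table())
  genes <- simulate_gene_model(ref)
  list(ref = ref, signatures = signatures, catalog = inj_high$catalog,
       genes = genes, expression = tables$expression,
       survival = tables$survival,
       cluster_truth = data.table::rbindlist(list(inj_low$truth, inj_high$truth)),
       group_truth = tables$truth$group,
       true_cutoff = tables$truth$true_cutoff,
       true_hr = tables$truth$true_hr,
       exposures = config$true_exposures)
}
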