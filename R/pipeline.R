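#' Pipeline configuration
#'
#' Collects the input paths and tunable parameters of the end-to-end
#' analysis. Paths may be `NULL`; stages whose inputs are missing are
#' skipped with a warning. Referenced paths must exist at run start.
#'
#' @param maf,fasta,signatures,bed,expression,survival input file paths.
#' @param outdir output directory.
#' @param kataegis a [kataegis_config()].
#' @param motif,flank,enrichment_threshold enrichment-scoring parameters.
#' @param prune_threshold signature-fit pruning threshold.
#' @param top_n,bottom_n expression-extreme subgroup sizes.
#' @param minprop,n_perm survival cutpoint parameters.
#' @param seed integer seed for every stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(maf, fasta, signatures = NULL, bed = NULL,
                            expression = NULL, survival = NULL,
                            outdir = "apobecscope_out",
                            kataegis = kataegis_config(),
                            motif = "TCW", flank = 20L,
                            enrichment_threshold = 2,
                            prune_threshold = 0.06,
                            top_n = 25L, bottom_n = 25L,
                            minprop = 0.1, n_perm = 1000L, seed = 1L) {
  for (p in c(maf, fasta, signatures, bed, expression, survival)) {
    if (!is.null(p) && !file.exists(p)) stop_format("input path does not exist: ", p)
  }
  structure(list(maf = maf, fasta = fasta, signatures = signatures, bed = bed,
                 expression = expression, survival = survival, outdir = outdir,
                 kataegis = kataegis, motif = motif, flank = as.integer(flank),
                 enrichment_threshold = enrichment_threshold,
                 prune_threshold = prune_threshold,
                 top_n = as.integer(top_n), bottom_n = as.integer(bottom_n),
                 minprop = minprop, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes spectrum construction, signature deconstruction, APOBEC motif
#' enrichment and classification, kataegis detection/classification/
#' annotation, expression-subgroup comparison and survival stratification
#' on a directory of inputs, writing TSV/JSON outputs and a run manifest
#' (package version, parameters, seed, input checksums). Stages whose
#' inputs are absent from the configuration are skipped with a warning.
#' Reruns with identical configuration and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  catalog <- stage("read_maf", read_maf(config$maf))
  ref <- stage("read_fasta", read_fasta(config$fasta))
  snv <- catalog[catalog$variant_type == "SNP", ]

  # spectrum + signature fit
  spec <- stage("spectrum", build_spectrum(snv, ref))
  spec_mat <- stage("spectrum", per_sample_spectra(snv, ref))
  data.table::fwrite(data.table::data.table(channel = sbs_channels(),
                                            pooled = as.integer(spec$counts),
                                            spec_mat),
                     file.path(config$outdir, "spectrum.tsv"), sep = "\t")
  out$spectrum <- spec
  if (!is.null(config$signatures)) {
    sigs <- stage("read_signatures", read_signature_matrix(config$signatures))
    fit <- stage("fit_signatures",
                 fit_exposures(spec, sigs, prune_threshold = config$prune_threshold))
    report <- compare_to_reference(fit)
    data.table::fwrite(report, file.path(config$outdir, "signature_weights.tsv"),
                       sep = "\t")
    out$fit <- fit
  } else {
    warning("no signature matrix configured; signature fit skipped", call. = FALSE)
  }

  # enrichment
  enr <- stage("enrichment",
               motif_enrichment(snv, ref, motif = config$motif,
                                flank = config$flank))
  part <- classify_enriched(enr, threshold = config$enrichment_threshold)
  data.table::fwrite(part$results, file.path(config$outdir, "enrichment.tsv"),
                     sep = "\t")
  out$enrichment <- part
  genes <- if (!is.null(config$bed)) stage("read_bed", read_bed_genes(config$bed)) else NULL
  if (length(part$enriched) > 0 && length(part$non_enriched) > 0) {
    gd <- stage("group_diff",
                compare_groups(catalog, part, ref = ref, genes = genes,
                               motif = config$motif, flank = config$flank))
    if (!is.null(gd$genes)) {
      data.table::fwrite(gd$genes, file.path(config$outdir, "group_diff_genes.tsv"),
                         sep = "\t")
    }
    out$group_diff <- gd
  }

  # kataegis
  regions <- stage("kataegis", detect_kataegis(snv, config = config$kataegis))
  regions <- stage("kataegis",
                   classify_regions(regions, snv, ref, config = config$kataegis))
  if (!is.null(genes)) regions <- annotate_genes(regions, genes)
  counts <- per_sample_counts(regions, samples = sort(unique(snv$sample_id)))
  data.table::fwrite(regions, file.path(config$outdir, "kataegis_regions.tsv"),
                     sep = "\t")
  data.table::fwrite(counts, file.path(config$outdir, "kataegis_counts.tsv"),
                     sep = "\t")
  rf <- data.table::rbindlist(lapply(sort(unique(snv$sample_id)),
                                     function(s) rainfall(snv, s)))
  data.table::fwrite(rf, file.path(config$outdir, "rainfall.tsv"), sep = "\t")
  out$kataegis <- list(regions = regions, counts = counts)

  # expression-linked analyses
  expr <- NULL
  if (!is.null(config$expression)) {
    expr <- stage("read_expression", read_expression_table(config$expression))
    cor_res <- stage("correlation",
                     correlate_counts_with_expression(counts, expr))
    out$correlation <- cor_res
    if (config$top_n + config$bottom_n <= nrow(expr)) {
      out$subgroups <- stage("subgroups",
                             compare_subgroups(regions, expr,
                                               top_n = config$top_n,
                                               bottom_n = config$bottom_n))
      if (!is.null(out$subgroups$genes)) {
        data.table::fwrite(out$subgroups$genes,
                           file.path(config$outdir, "subgroup_genes.tsv"),
                           sep = "\t")
      }
    } else {
      warning("cohort smaller than top_n + bottom_n; subgroup comparison skipped",
              call. = FALSE)
    }
  } else {
    warning("no expression table configured; correlation and subgroup stages skipped",
            call. = FALSE)
  }

  if (!is.null(config$expression) && !is.null(config$survival)) {
    surv <- stage("read_survival", read_survival_table(config$survival))
    cut_res <- stage("survival",
                     optimal_cutpoint(expr, surv, minprop = config$minprop,
                                      n_perm = config$n_perm, seed = config$seed))
    jsonlite::write_json(
      cut_res[c("cutoff", "n_high", "n_low", "logrank_chi2", "p",
                "p_adjusted", "hr", "ci_low", "ci_high", "minprop")],
      file.path(config$outdir, "cutpoint.json"),
      auto_unbox = TRUE, digits = NA)
    d <- cut_res$data
    for (grp in c("high", "low")) {
      sel <- if (grp == "high") d$expression > cut_res$cutoff else d$expression <= cut_res$cutoff
      km <- km_estimate(d[sel, ])
      data.table::fwrite(data.table::data.table(time = km$time,
                                                n_risk = km$n_risk,
                                                n_event = km$n_event,
                                                surv = km$surv),
                         file.path(config$outdir, paste0("km_", grp, ".tsv")),
                         sep = "\t")
    }
    out$cutpoint <- cut_res
  } else if (is.null(config$survival)) {
    warning("no survival table configured; survival stage skipped", call. = FALSE)
  }

  manifest <- list(
    package = "apobecscope",
    version = as.character(utils::packageVersion("apobecscope")),
    parameters = lapply(config[setdiff(names(config),
                                       c("maf", "fasta", "signatures", "bed",
                                         "expression", "survival", "outdir"))],
                        function(x) if (is.list(x)) unclass(x) else x),
    inputs = lapply(config[c("maf", "fasta", "signatures", "bed",
                             "expression", "survival")],
                    function(p) if (is.null(p)) NULL else
                      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
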