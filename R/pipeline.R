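#' Run the full analysis pipeline over a sample manifest
#'
#' For every manifest row, events are simulated from the named template (or
#' read from file), debris-gated and deconvolved with [ploidy_fit()].
#' Within each calibration group the reference replicates' 2Cx means are
#' averaged into one reference intensity, each sample replicate's 2Cx mean
#' is calibrated into pg with [estimate_c_value()], and replicates are
#' aggregated per species/tissue.  Adjacent-cluster ratios are tested
#' against 2.0 across replicates, ploidy-class composition is tabulated,
#' and when several sample groups have replicates a one-way ANOVA with
#' LSD letters is run over the per-replicate C-values.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `composition.tsv`,
#'   `ratios.tsv`, `cvalues.tsv` and a machine-readable `pipeline.json`.
#'   Reports regenerate byte-identically from the same config and seed.
#' @return Object of class `"pipeline_run"`: `fits` (named list of
#'   [ploidy_fit()] objects), `cvalues` (per-group aggregation),
#'   `cvalue_table`, `ratio_table`, `composition`, `anova`, `logs`,
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  man <- config$manifest
  prm <- config$params
  logs <- character()
  note <- function(fmt, ...) logs[[length(logs) + 1L]] <<- sprintf(fmt, ...)
  lib <- template_library()

  fits <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    ev <- if (!is.na(row$template)) {
      if (!row$template %in% names(lib))
        stop_fmt("sample '%s': unknown template '%s'", row$sample_id,
                 row$template)
      generate_sample(lib[[row$template]],
                      if (is.na(row$n_events)) prm$n_events else row$n_events,
                      seed = derive_seed(config$seed, i))
    } else {
      tab <- read_events(row$path)
      note("sample %s: dropped %d invalid row(s) on read", row$sample_id,
           attr(tab, "dropped") %||% 0L)
      tab
    }
    fit <- tryCatch(
      ploidy_fit(ev, expect_haploid = isTRUE(row$expect_haploid),
                 gate_k = prm$gate_k,
                 max_gate_fraction = prm$max_gate_fraction,
                 bw_factor = prm$bw_factor,
                 min_prominence_fraction = prm$min_prominence_fraction,
                 min_separation_ratio = prm$min_separation_ratio,
                 ladder_window = prm$ladder_window,
                 window_sd = prm$window_sd,
                 valley_fraction = prm$valley_fraction,
                 keep_events = FALSE),
      error = function(e)
        stop_fmt("sample '%s', stage deconvolution: %s", row$sample_id,
                 conditionMessage(e)))
    note("sample %s: gated %.2f%%, anchor %dCx, %d cluster(s), %d peak(s) unassigned",
         row$sample_id, 100 * fit$gated_fraction, fit$anchor_level,
         nrow(fit$clusters), nrow(fit$ladder$unassigned))
    fits[[row$sample_id]] <- fit
  }

  # calibration: one reference intensity per group
  pg <- rep(NA_real_, nrow(man))
  for (g in unique(man$group)) {
    in_g <- man$group == g
    ref_ids <- man$sample_id[in_g & man$role == "reference"]
    if (!length(ref_ids))
      stop_fmt("calibration group '%s' has no reference sample", g)
    ref_fi <- mean(vapply(fits[ref_ids], fit_2cx_mean, numeric(1)))
    for (id in man$sample_id[in_g]) {
      pg[man$sample_id == id] <- estimate_c_value(
        fit_2cx_mean(fits[[id]]), ref_fi, config$reference_c_value_pg)
    }
  }
  man$c_value_pg <- pg

  cv2 <- vapply(fits, function(f) {
    f$clusters$cv[match(2, f$clusters$level)]
  }, numeric(1))
  man$cv_2cx <- cv2[man$sample_id]

  # per species/tissue aggregation (samples only)
  smp <- man[man$role == "sample", , drop = FALSE]
  grp_key <- paste(smp$species, smp$tissue, sep = " / ")
  cvalues <- lapply(split(seq_len(nrow(smp)), grp_key), function(idx) {
    if (length(idx) >= 2L) {
      aggregate_replicates(smp$c_value_pg[idx], smp$cv_2cx[idx],
                           pg_per_mb = config$pg_per_mb,
                           species = smp$species[idx[1L]],
                           tissue = smp$tissue[idx[1L]])
    } else {
      structure(list(per_replicate_pg = smp$c_value_pg[idx],
                     mean_pg = smp$c_value_pg[idx], se_pg = NA_real_,
                     mean_mb = smp$c_value_pg[idx] * config$pg_per_mb,
                     se_mb = NA_real_,
                     cv_range_pct = rep(smp$cv_2cx[idx], 2L),
                     n = 1L, species = smp$species[idx[1L]],
                     tissue = smp$tissue[idx[1L]]),
                class = "cvalue_estimate")
    }
  })
  cvalue_table <- do.call(rbind, lapply(cvalues, function(e) {
    data.frame(species = e$species, tissue = e$tissue, n = e$n,
               c_value_pg = e$mean_pg, genome_mb = round(e$mean_mb),
               se_mb = e$se_mb, cv_lo = e$cv_range_pct[1L],
               cv_hi = e$cv_range_pct[2L])
  }))
  rownames(cvalue_table) <- NULL

  # adjacent-cluster ratio series per species/tissue (all roles)
  all_key <- paste(man$species, man$tissue, sep = " / ")
  ratio_table <- do.call(rbind, lapply(split(seq_len(nrow(man)), all_key),
                                       function(idx) {
    per_rep <- lapply(man$sample_id[idx], function(id) {
      clu <- fits[[id]]$clusters
      if (nrow(clu) < 2L) return(NULL)
      data.frame(step = paste0(clu$level[-1L], "Cx/", clu$level[-nrow(clu)], "Cx"),
                 ratio = clu$mean_fi[-1L] / clu$mean_fi[-nrow(clu)])
    })
    per_rep <- do.call(rbind, per_rep)
    if (is.null(per_rep)) return(NULL)
    spl <- split(per_rep$ratio, per_rep$step)
    do.call(rbind, lapply(names(spl), function(step) {
      r <- spl[[step]]
      out <- data.frame(species = man$species[idx[1L]],
                        tissue = man$tissue[idx[1L]],
                        step = step, n = length(r), ratio = mean(r),
                        se = NA_real_, t = NA_real_, p = NA_real_)
      if (length(r) >= 2L && sd(r) > 0) {
        out$se <- sd(r) / sqrt(length(r))
        tt <- ratio_t_test(mean(r), out$se, length(r))
        out$t <- tt$t
        out$p <- tt$p
      }
      out
    }))
  }))
  rownames(ratio_table) <- NULL

  # composition table (fractions of classified events per sample)
  composition <- do.call(rbind, lapply(man$sample_id, function(id) {
    clu <- fits[[id]]$clusters
    row <- man[man$sample_id == id, ]
    data.frame(sample_id = id, species = row$species, tissue = row$tissue,
               level = clu$level, fraction = clu$fraction)
  }))
  rownames(composition) <- NULL

  # ANOVA over per-replicate C-values when >= 2 replicated sample groups
  anova <- NULL
  reps <- split(smp$c_value_pg, grp_key)
  reps <- reps[lengths(reps) >= 2L]
  if (length(reps) >= 2L) anova <- anova_lsd(reps)

  run <- structure(list(config = config, fits = fits,
                        cvalues = cvalues, cvalue_table = cvalue_table,
                        ratio_table = ratio_table, composition = composition,
                        anova = anova, logs = logs,
                        seed = config$seed),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_reports(run, out_dir)
  run
}

write_tsv_report <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 8, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_report(run$composition, file.path(out_dir, "composition.tsv"))
  write_tsv_report(run$ratio_table, file.path(out_dir, "ratios.tsv"))
  write_tsv_report(run$cvalue_table, file.path(out_dir, "cvalues.tsv"))
  payload <- list(
    seed = run$seed,
    composition = run$composition,
    ratios = run$ratio_table,
    cvalues = run$cvalue_table,
    anova = if (!is.null(run$anova))
      list(F = run$anova$F, df = c(run$anova$df_between, run$anova$df_within),
           p = run$anova$p, letters = as.list(run$anova$letters)),
    logs = run$logs)
  jsonlite::write_json(payload, file.path(out_dir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d sample(s), seed %d\n",
              length(x$fits), x$seed))
  cat("\nC-values:\n")
  tab <- x$cvalue_table
  tab$c_value_pg <- round(tab$c_value_pg, 4)
  tab$se_mb <- round(tab$se_mb, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$anova))
    cat(sprintf("\nTissue ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
                x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}

#' Build the default synthetic study configuration
#'
#' One manifest covering all eight built-in templates with `replicates`
#' replicates each; the *D. melanogaster* adult-head template is the
#' calibration reference, the male gonad is flagged `expect_haploid`.
#'
#' @param replicates Replicates per tissue (default 3).
#' @param n_events Events per replicate.
#' @param seed Master seed.
#' @return A [run_config()].
#' @export
demo_config <- function(replicates = 3L, n_events = 10000L, seed = 1L) {
  lib <- names(template_library())
  rows <- do.call(rbind, lapply(lib, function(tpl) {
    species <- if (startsWith(tpl, "dmel")) "D_melanogaster"
    else if (startsWith(tpl, "hass")) "H_assulta" else "H_armigera"
    data.frame(sample_id = paste0(tpl, "_r", seq_len(replicates)),
               species = species,
               tissue = sub("^(dmel|harm|hass)_", "", tpl),
               replicate = seq_len(replicates),
               role = if (startsWith(tpl, "dmel")) "reference" else "sample",
               template = tpl,
               expect_haploid = grepl("gonad", tpl))
  }))
  run_config(rows, params = list(n_events = as.integer(n_events)), seed = seed)
}

#' One-command synthetic reproduction of the study design
#'
#' Simulates all eight tissue templates with three replicates, runs the
#' full pipeline, and appends the summary-statistic reconstructions
#' computed from the bundled printed tables (not from the synthetic data):
#' the tissue C-value ANOVA with LSD letters, the species genome-size
#' pooled t-test, and every adjacent-ratio t-test.
#'
#' @param seed Master seed.
#' @param n_events Events per synthetic replicate.
#' @param out_dir Optional report directory, see [run_pipeline()].
#' @return Object of class `"paper_demo"`: `run` (a `"pipeline_run"`) and
#'   `reconstructions` (`anova`, `genome_t`, `ratio_tests`).
#' @export
demo_paper <- function(seed = 1L, n_events = 10000L, out_dir = NULL) {
  run <- run_pipeline(demo_config(3L, n_events, seed), out_dir = out_dir)
  t2 <- helicoverpa_tissue_summary()
  rec_anova <- anova_from_summary(t2$c_value_pg, t2$se_pg, t2$n,
                                  labels = t2$tissue)
  t3 <- helicoverpa_genome_summary()
  rec_t <- two_sample_t(t3$genome_mb[1L], t3$se_mb[1L], t3$n[1L],
                        t3$genome_mb[2L], t3$se_mb[2L], t3$n[2L])
  t1 <- helicoverpa_ratio_summary()
  rt <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
    res <- ratio_t_test(t1$ratio[i], t1$se[i], t1$n[i])
    data.frame(sample = t1$sample[i], step = t1$step[i],
               ratio = t1$ratio[i], se = t1$se[i], t = res$t, p = res$p,
               p_published = t1$p_published[i])
  }))
  structure(list(run = run,
                 reconstructions = list(anova = rec_anova, genome_t = rec_t,
                                        ratio_tests = rt)),
            class = "paper_demo")
}

#' @export
print.paper_demo <- function(x, ...) {
  print(x$run)
  rec <- x$reconstructions
  cat(sprintf("\nReconstructed tissue ANOVA: F(%d, %d) = %.2f, p = %.4f\n",
              rec$anova$df_between, rec$anova$df_within, rec$anova$F,
              rec$anova$p))
  cat("LSD letters:",
      paste(names(rec$anova$letters), rec$anova$letters, sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("Reconstructed genome-size t-test: t(%d) = %.2f, p = %.2g\n",
              rec$genome_t$df, rec$genome_t$t, rec$genome_t$p))
  cat("\nAdjacent-ratio tests vs 2.0 (reconstructed):\n")
  rt <- rec$ratio_tests
  rt$t <- round(rt$t, 2)
  rt$p <- round(rt$p, 3)
  print(rt, row.names = FALSE)
  invisible(x)
}
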