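#' Format an Akaike weight for report tables
#'
#' Weights below 1e-3 are rendered in scientific notation with two
#' significant digits (\code{"1.2 x 10^-56"}), larger weights with three
#' decimals.
#'
#' @param w numeric vector of weights.
#' @return character vector.
#' @export
format_weight <- function(w) {
  vapply(w, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x >= 1e-3) return(sprintf("%.3f", x))
    e <- floor(log10(x))
    sprintf("%.1f x 10^%d", x / 10^e, e)
  }, "")
}

#' Pipeline run configuration
#'
#' @param out_dir directory for all outputs (created if absent).
#' @param seed root seed, recorded in the manifest and forwarded to the
#'   simulators.
#' @param stages character subset of
#'   \code{c("simulate", "call", "table", "fit")}; later stages consume
#'   the outputs of earlier ones within the same run.
#' @param align_config an [alignment_sim_config()] (its \code{seed} is
#'   overridden by \code{seed}).
#' @param filter_cfg a [filter_config()].
#' @param long_min_length length cut for the long-contig companion table.
#' @param responses responses to model.
#' @param predict_grid data frame of \code{length, depth, cnc} points for
#'   the prediction grid (defaults to a 1 kb contig at depths 10 and 100,
#'   both classes).
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(out_dir = tempfile("snpdepth_run_"),
                       seed = 1L,
                       stages = c("simulate", "call", "table", "fit"),
                       align_config = alignment_sim_config(),
                       filter_cfg = filter_config(),
                       long_min_length = 501,
                       responses = c("snp", "ti", "tv"),
                       predict_grid = expand.grid(length = 1000,
                                                  depth = c(10, 100),
                                                  cnc = c(1, 0))) {
  stages <- if (length(stages)) match.arg(stages, several.ok = TRUE)
            else character(0)
  align_config$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, align_config = align_config,
                 filter_cfg = filter_cfg,
                 long_min_length = long_min_length,
                 responses = responses, predict_grid = predict_grid),
            class = "run_config")
}

#' Run the simulate / call / table / fit pipeline
#'
#' Executes the enabled stages in order, writing every intermediate and
#' report file under \code{config$out_dir}: simulated consensus FASTA,
#' quality file, SAM and truth tables; the VCF and TSV of accepted SNP
#' calls; the contig regression table (all contigs and the long subset);
#' summary, correlation, model-selection and coefficient report tables;
#' and a prediction grid from the best SNP model. A manifest records the
#' seed, a hash of the configuration, and the files produced, so a rerun
#' with the same configuration is byte-identical.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of each stage and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  results <- list()
  produced <- character(0)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if ("simulate" %in% config$stages) {
    results$sim <- stage("simulate", simulate_alignments(config$align_config))
    stage("simulate", {
      write_alignments(results$sim$alignments, fasta = path("consensus.fasta"),
                       qual = path("consensus.qual"), sam = path("reads.sam"))
      write_contig_table(results$sim$truth$snps, path("truth_snps.tsv"))
      write_contig_table(results$sim$truth$decoys, path("truth_decoys.tsv"))
      write_contig_table(results$sim$labels, path("labels.tsv"))
    })
    produced <- c(produced, "consensus.fasta", "consensus.qual", "reads.sam",
                  "truth_snps.tsv", "truth_decoys.tsv", "labels.tsv")
  }
  need <- function(name, x, from)
    if (is.null(x))
      stop(sprintf("stage '%s' failed: requires output of stage '%s'",
                   name, from), call. = FALSE)
  if ("call" %in% config$stages) {
    need("call", results$sim, "simulate")
    results$calls <- stage("call",
      call_snps_all(results$sim$alignments, config$filter_cfg))
    lens <- vapply(results$sim$alignments,
                   function(a) nchar(a$consensus), 0L)
    stage("call", {
      write_vcf(results$calls, path("calls.vcf"), contig_lengths = lens)
      write_contig_table(results$calls, path("calls.tsv"))
    })
    produced <- c(produced, "calls.vcf", "calls.tsv")
  }
  if ("table" %in% config$stages) {
    need("table", results$sim, "simulate")
    results$table <- stage("table", build_table(
      results$calls, alignment_metadata(results$sim$alignments),
      results$sim$labels, config$filter_cfg))
    results$table_long <- subset_long(results$table, config$long_min_length)
    stage("table", {
      write_contig_table(results$table, path("contig_table.tsv"))
      write_contig_table(results$table_long, path("contig_table_long.tsv"))
    })
    produced <- c(produced, "contig_table.tsv", "contig_table_long.tsv")
  }
  if ("fit" %in% config$stages) {
    need("fit", results$table, "table")
    tab <- results$table_long
    if (is.null(tab) || nrow(tab) < 10) tab <- results$table
    results$fit <- stage("fit", run_full_selection(tab, config$responses))
    best <- results$fit[[config$responses[1]]]$best
    results$pred <- if (!is.null(best)) stage("fit", predict_count(
      best, length = config$predict_grid$length,
      depth = config$predict_grid$depth, cnc = config$predict_grid$cnc))
    report <- render_tables(list(table = results$table,
                                 table_long = results$table_long,
                                 fit = results$fit, pred = results$pred))
    stage("fit", {
      writeLines(report$text, path("report.txt"))
      write_contig_table(report$selection, path("model_selection.tsv"))
      write_contig_table(report$coefficients, path("coefficients.tsv"))
      if (!is.null(results$pred))
        write_contig_table(results$pred, path("prediction_grid.tsv"))
    })
    produced <- c(produced, "report.txt", "model_selection.tsv",
                  "coefficients.tsv",
                  if (!is.null(results$pred)) "prediction_grid.tsv")
  }

  cfg_file <- path("config.txt")
  writeLines(utils::capture.output(utils::str(config)), cfg_file)
  manifest <- c(sprintf("seed\t%d", config$seed),
                sprintf("config_md5\t%s", unname(tools::md5sum(cfg_file))),
                sprintf("stages\t%s", paste(config$stages, collapse = ",")),
                sprintf("file\t%s", produced))
  writeLines(manifest, path("manifest.tsv"))
  results$manifest <- manifest
  invisible(results)
}

#' Render report tables from pipeline results
#'
#' Produces a plain-text report (summary statistics per dataset,
#' Ti/Tv ratios, correlations, model-selection and coefficient tables with
#' report rounding: integer means, 1-decimal ratios, 3-decimal or
#' scientific weights) plus tidy data frames of the selection and
#' coefficient tables.
#'
#' @param results list with elements \code{table}, \code{table_long},
#'   \code{fit} (from [run_full_selection()]) and optionally \code{pred}.
#' @return list with \code{text} (character lines), \code{selection} and
#'   \code{coefficients} (data frames).
#' @export
render_tables <- function(results) {
  txt <- character(0)
  add <- function(...) txt <<- c(txt, sprintf(...))

  sum_block <- function(tab, label) {
    s <- summarize_contigs(tab)
    add("== Summary: %s ==", label)
    add("%-10s %9s %12s %11s %9s %6s %6s", "group", "contigs",
        "mean_len", "mean_depth", "snps", "ti", "tv")
    z <- function(v) ifelse(is.finite(v), v, 0)  # empty partition -> 0
    for (i in seq_len(nrow(s)))
      add("%-10s %9d %12.0f %11.0f %9d %6d %6d", s$group[i], s$n_contigs[i],
          round(z(s$mean_length[i])), round(z(s$mean_depth[i])),
          s$total_snp[i], s$total_ti[i], s$total_tv[i])
    if (s$total_tv[1] > 0)
      add("Ti/Tv = %.1f", titv_ratio(s$total_ti[1], s$total_tv[1]))
    for (xy in list(c("length", "n_snp"), c("depth", "n_snp"))) {
      ok <- tryCatch({
        ct <- snp_cor(tab, xy[1], xy[2])
        add("r(%s, %s) = %.2f (P %s)", xy[1], xy[2], ct$r,
            if (ct$p < 0.001) "< 0.001" else sprintf("= %.3f", ct$p))
        TRUE
      }, error = function(e) FALSE)
    }
  }
  if (!is.null(results$table)) sum_block(results$table, "all contigs")
  if (!is.null(results$table_long) && nrow(results$table_long))
    sum_block(results$table_long, "long contigs")

  sel_rows <- list(); coef_rows <- list()
  if (!is.null(results$fit)) {
    for (resp in names(results$fit)) {
      r <- results$fit[[resp]]
      if (!is.null(r$selection)) {
        add("== Model selection: %s ==", resp)
        s <- as.data.frame(r$selection)
        for (i in seq_len(nrow(s)))
          add("%-3s %-18s AIC %9.1f  dAIC %7.1f  w %s", s$model[i],
              s$covariates[i], s$aic[i], s$delta_aic[i],
              format_weight(s$weight[i]))
        s$response <- resp
        sel_rows[[resp]] <- s
      }
      if (!is.null(r$best)) {
        b <- r$best
        cf <- data.frame(response = resp, model = b$spec$name,
                         term = names(b$beta), estimate = unname(b$beta),
                         lower = unname(b$ci95[, "lower"]),
                         upper = unname(b$ci95[, "upper"]),
                         p = unname(b$wald_p))
        coef_rows[[resp]] <- cf
        add("== Best model coefficients: %s (%s) ==", resp, b$spec$name)
        for (i in seq_len(nrow(cf)))
          add("%-12s %9.4f  [%9.4f, %9.4f]  P = %.4f", cf$term[i],
              cf$estimate[i], cf$lower[i], cf$upper[i], cf$p[i])
      }
      if (length(r$errors))
        add("fit errors (%s): %s", resp,
            paste(names(r$errors), unlist(r$errors), collapse = "; "))
    }
  }
  if (!is.null(results$pred)) {
    add("== Standardized SNP count predictions ==")
    p <- results$pred
    for (i in seq_len(nrow(p)))
      add("length %5d  depth %4d  %s: %.2f [%.2f, %.2f]", p$length[i],
          p$depth[i], ifelse(p$cnc[i] == 1, "coding   ", "noncoding"),
          p$estimate[i], p$lower[i], p$upper[i])
  }
  list(text = txt,
       selection = if (length(sel_rows)) do.call(rbind, sel_rows)
                   else data.frame(),
       coefficients = if (length(coef_rows)) do.call(rbind, coef_rows)
                      else data.frame())
}
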