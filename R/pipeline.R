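# Orchestration: run the full per-wave analysis (harmonize -> describe ->
# regress -> index -> decompose -> diagnose) from a single JSON-able config
# and write paper-style tables.

pipeline_log <- function(level, stage, msg) {
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

#' Run the full analysis pipeline
#'
#' Executes every analysis stage on one survey table: weighted prevalence
#' overall, by SES quintile and by province; the survey-weighted logistic
#' regression with adjusted odds ratios; concentration indices (Erreygers
#' by default, plus standard and Wagstaff); the regression-based
#' decomposition; and the diagnostic suite. The input table either comes
#' from a `simulate` block (a wave name or full generator config, plus a
#' seed) or from a `csv` block (path + optional schema, with a raw-hunger
#' harmonization convention). Deterministic given the seed.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{simulate}{list(`wave`, optional `n`) — generate synthetic data.}
#'     \item{csv}{list(`path`, optional `schema`, optional
#'       `hunger_convention`) — load a CSV instead.}
#'     \item{seed}{integer seed (default 1).}
#'     \item{model}{`"lpm"` or `"logit_ame"` decomposition first stage.}
#'     \item{index}{`"erreygers"`, `"standard"` or `"wagstaff"`.}
#'     \item{bootstrap}{optional bootstrap replicate count for the index SE
#'       cross-check (omitted = convenient-regression SE only).}
#'   }
#' @return An `analysis_report`: named list of tables
#'   (`prevalence_overall`, `prevalence_by_ses`, `prevalence_by_province`,
#'   `regression`, `index_table`, `decomposition_groups`,
#'   `decomposition_detail`, `diagnostics`) plus a `provenance` block
#'   (seed, config hash, package version, row count).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  model <- if (is.null(config$model)) "lpm" else config$model
  index_type <- if (is.null(config$index)) "erreygers" else config$index

  stage <- "load_survey"
  tab <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim <- config$simulate
      cfg <- if (!is.null(sim$wave)) {
        default_wave_config(sim$wave,
                            n = if (is.null(sim$n)) NULL else as.integer(sim$n))
      } else {
        do.call(generator_config, sim)
      }
      pipeline_log("info", stage, paste0("generating n=", cfg$n,
                                         " (", cfg$wave_id, ", seed ", seed, ")"))
      generate_wave(cfg, seed)
    } else if (!is.null(config$csv)) {
      tab <- load_survey(config$csv$path, config$csv$schema)
      conv <- config$csv$hunger_convention
      if (!is.null(conv)) {
        tab$no_hunger <- harmonize_no_hunger(tab$no_hunger, conv)
        pipeline_log("info", "harmonize", paste("applied convention", conv))
      }
      tab
    } else stop("config needs a 'simulate' or 'csv' block")
  }, error = function(e) {
    stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline aborted in stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
    pipeline_log("info", stage,
                 sprintf("done in %.2fs", as.numeric(Sys.time() - t0,
                                                     units = "secs")))
    out
  }

  prev_all <- run_stage("prevalence", prevalence_table(tab))
  prev_ses <- run_stage("prevalence_by_ses",
                        prevalence_table(tab, by = "ses_quintile"))
  prev_prov <- run_stage("prevalence_by_province",
                         prevalence_table(tab, by = "province"))

  fml <- canonical_formula()
  fit <- run_stage("regression", fit_weighted_logit(tab, fml))
  ortab <- odds_ratio_table(fit)
  if (nrow(fit$dropped_terms) > 0)
    pipeline_log("warn", "regression",
                 paste("dropped:", paste(fit$dropped_terms$term,
                                         collapse = ", ")))

  ranks <- run_stage("ranks", {
    ses <- if (!is.null(tab$ses_score) && !all(is.na(tab$ses_score)))
      tab$ses_score else as.numeric(as.character(tab$ses_quintile))
    weighted_fractional_rank(ses, tab$weight)
  })
  cc <- stats::complete.cases(tab[all.vars(fml)])
  idx <- run_stage("index", {
    lapply(c("erreygers", "standard", "wagstaff"), function(ty)
      index_se(tab$no_hunger[cc], ranks$rank[cc], tab$weight[cc],
               index_type = ty))
  })
  index_table <- do.call(rbind, lapply(idx, function(e)
    data.frame(survey = tab$wave_id[1], index = e$index_type,
               value = e$value, std_err = e$std_err, p_value = e$p_value,
               interpretation = interpret_index(e),
               stringsAsFactors = FALSE)))
  if (!is.null(config$bootstrap)) {
    e <- idx[[match(index_type, c("erreygers", "standard", "wagstaff"))]]
    bs <- index_se(tab$no_hunger[cc], ranks$rank[cc], tab$weight[cc],
                   index_type = index_type, method = "bootstrap",
                   B = as.integer(config$bootstrap), seed = seed)
    pipeline_log("info", "bootstrap",
                 sprintf("SE %s = %.4f (convenient regression %.4f)",
                         index_type, bs$std_err, e$std_err))
    index_table$bootstrap_se <- NA_real_
    index_table$bootstrap_se[index_table$index == index_type] <- bs$std_err
  }

  dec <- run_stage("decompose",
                   decompose_index(tab, fml, ranks, index_type = index_type,
                                   model = model))

  diag_ <- run_stage("diagnostics", {
    hl <- hosmer_lemeshow(fit)
    lt <- link_test(fit)
    vf <- vif(tab, fml)
    data.frame(
      metric = c("hosmer_lemeshow_stat", "hosmer_lemeshow_p", "auc",
                 "mean_vif", "link_test_hat", "link_test_hatsq_p"),
      value = c(hl$statistic, hl$p_value, roc_auc(fit),
                attr(vf, "mean_vif"), lt$coef_hat, lt$p_hatsq),
      stringsAsFactors = FALSE)
  })

  cfg_for_hash <- config[setdiff(names(config), "seed")]
  provenance <- list(
    seed = seed,
    config_hash = config_hash(cfg_for_hash),
    package_version = as.character(utils::packageVersion("foodineq")),
    n_rows = nrow(tab),
    wave_id = tab$wave_id[1])

  structure(list(prevalence_overall = prev_all,
                 prevalence_by_ses = prev_ses,
                 prevalence_by_province = prev_prov,
                 regression = ortab,
                 index_table = index_table,
                 decomposition_groups = dec$groups,
                 decomposition_detail = dec$detail,
                 decomposition_summary = data.frame(
                   total_index = dec$total_index,
                   explained = dec$explained,
                   residual_gc = dec$residual_gc,
                   residual_percent = dec$residual_percent,
                   model = dec$model, index_type = dec$index_type),
                 diagnostics = diag_,
                 provenance = provenance),
            class = "analysis_report")
}

# order-independent hash of the config (no external digest dependency)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

#' Write an analysis report to disk
#'
#' One CSV per table family, a `summary.json` with the decomposition
#' summary, diagnostics and provenance, and a plain-text rendering
#' (`report.txt`) with the three-tier significance marks and the index
#' interpretation strings.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  tables <- c("prevalence_overall", "prevalence_by_ses",
              "prevalence_by_province", "regression", "index_table",
              "decomposition_groups", "decomposition_detail")
  files <- character(0)
  for (tb in tables) {
    f <- file.path(out_dir, paste0(tb, ".csv"))
    utils::write.csv(as.data.frame(report[[tb]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(decomposition = report$decomposition_summary,
                            diagnostics = report$diagnostics,
                            provenance = report$provenance),
                       sj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, sj)

  txt <- file.path(out_dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  p <- report$provenance
  writeLines(c(
    sprintf("Analysis report: %s (n = %d, seed %d, config %s)",
            p$wave_id, p$n_rows, p$seed, p$config_hash),
    "",
    "Weighted no-hunger prevalence (%):",
    sprintf("  overall  %6.2f  [%5.2f, %5.2f]",
            report$prevalence_overall$proportion,
            report$prevalence_overall$ci_low,
            report$prevalence_overall$ci_high),
    "By SES quintile:",
    sprintf("  Q%s  %6.2f  [%5.2f, %5.2f]",
            report$prevalence_by_ses$group,
            report$prevalence_by_ses$proportion,
            report$prevalence_by_ses$ci_low,
            report$prevalence_by_ses$ci_high),
    "",
    "Adjusted odds ratios (no hunger; a p<0.01, b p<0.05, c p<0.1):",
    sprintf("  %-28s %6.2f [%5.2f-%6.2f] %s",
            report$regression$term, report$regression$aOR,
            report$regression$ci_low, report$regression$ci_high,
            report$regression$mark),
    "",
    "Concentration indices:",
    sprintf("  %-10s %7.4f (robust SE %.4f)  %s",
            report$index_table$index, report$index_table$value,
            report$index_table$std_err, report$index_table$interpretation),
    "",
    sprintf("Decomposition (%s, %s): total %.4f, residual %.4f (%.2f%%)",
            report$decomposition_summary$index_type,
            report$decomposition_summary$model,
            report$decomposition_summary$total_index,
            report$decomposition_summary$residual_gc,
            report$decomposition_summary$residual_percent),
    sprintf("  %-16s CI %7.4f  %7.2f%%",
            report$decomposition_groups$variable,
            report$decomposition_groups$factor_ci,
            report$decomposition_groups$percent)
  ), con)
  files <- c(files, txt)
  invisible(files)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate` (write a synthetic wave as CSV),
#' `analyze` (run the full pipeline and write a report), `decompose`
#' (decomposition only) and `report` (alias of analyze). Typical use from a
#' shell: `Rscript -e 'foodineq::foodineq_main()' analyze --config cfg.json
#' --out outdir`.
#'
#' @param argv Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status 0L, invisibly.
#' @export
foodineq_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L)
    stop("usage: foodineq <simulate|analyze|decompose|report> [--config F] ",
         "[--seed N] [--out DIR] [--model lpm|logit_ame] ",
         "[--index erreygers|standard|wagstaff] [--bootstrap B] [--wave W] ",
         "[--n N]")
  cmd <- argv[1]
  opts <- list(seed = 1L, out = ".", model = "lpm", index = "erreygers")
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE) else list()
  if (!is.null(opts$wave)) config$simulate <- list(wave = opts$wave)
  if (!is.null(opts$n)) config$simulate$n <- as.integer(opts$n)
  config$seed <- as.integer(opts$seed)
  config$model <- opts$model
  config$index <- opts$index
  if (!is.null(opts$bootstrap)) config$bootstrap <- as.integer(opts$bootstrap)

  if (cmd == "simulate") {
    cfg <- if (!is.null(config$simulate$wave))
      default_wave_config(config$simulate$wave,
                          n = config$simulate$n) else
      do.call(generator_config, config$simulate)
    tab <- generate_wave(cfg, config$seed)
    f <- file.path(opts$out, paste0(cfg$wave_id, "_synthetic.csv"))
    if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
    utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
    message("wrote ", f)
  } else if (cmd %in% c("analyze", "report", "decompose")) {
    report <- run_pipeline(config)
    write_report(report, opts$out)
    message("report written to ", opts$out)
  } else stop("unknown command: ", cmd)
  invisible(0L)
}
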