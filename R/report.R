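# Report generation: CSV/JSON exports, four bar-chart figures and a
# rendered Markdown (optionally HTML) report for one (design, scenario)
# pair. All numbers shown in the report are taken from the same rounded
# tables that are written to CSV, so report and exports agree exactly.

fmt_pct <- function(x) round_half_away(x, 1)        # percentages: 1 dp
fmt_prob <- function(x) round_half_away(x, 3)       # probabilities: 3 dp
fmt_count <- function(x) round_half_away(x, 2)      # expected counts: 2 dp

#' Read a run configuration from a plain-text file
#'
#' The file holds one `key = value` pair per line (`#` starts a comment).
#' Recognised keys: `A`, `B`, `C`, `D`, `E`, `deescalation` (`true`/
#' `false`), `dose_probs` (comma-separated probabilities) and `conf_level`.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `design` (an [ab_design()]), `scenario`
#'   (a [tox_scenario()]) and `conf_level`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  cfg <- stats::setNames(as.list(vals), keys)
  need <- c("A", "B", "C", "D", "E", "dose_probs")
  missing <- setdiff(need, keys)
  if (length(missing))
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  deesc <- tolower(cfg$deescalation %||% "false") %in%
    c("true", "yes", "1", "t")
  design <- ab_design(as.numeric(cfg$A), as.numeric(cfg$B),
                      as.numeric(cfg$C), as.numeric(cfg$D),
                      as.numeric(cfg$E), deescalate = deesc)
  probs <- as.numeric(strsplit(cfg$dose_probs, ",")[[1]])
  scenario <- tox_scenario(probs)
  conf_level <- as.numeric(cfg$conf_level %||% "0.95")
  list(design = design, scenario = scenario, conf_level = conf_level)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rounded_dose_table <- function(ocs) {
  data.frame(
    dose = ocs$dose_table$dose,
    true_dlt_prob = fmt_prob(ocs$dose_table$true_dlt_prob),
    experimentation_pct = fmt_pct(ocs$dose_table$experimentation_pct),
    recommendation_pct = fmt_pct(ocs$dose_table$recommendation_pct),
    expected_patients = fmt_count(ocs$dose_table$expected_patients),
    expected_dlts = fmt_count(ocs$dose_table$expected_dlts))
}

rounded_ci_table <- function(dcs) {
  data.frame(
    dlts = dcs$ci_table$dlts, n = dcs$ci_table$n,
    method = dcs$ci_table$method,
    lower_pct = round_half_away(100 * dcs$ci_table$lower, 2),
    upper_pct = round_half_away(100 * dcs$ci_table$upper, 2),
    level = dcs$ci_table$level)
}

md_table <- function(df) {
  # element-wise formatting so each cell prints exactly as in the CSVs
  fmt <- function(v) if (is.numeric(v))
    vapply(v, function(x) format(x, trim = TRUE), character(1))
  else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

bar_chart <- function(df, x, y, xlab, ylab, title, discrete_x = TRUE) {
  dd <- data.frame(
    xv = if (discrete_x) factor(df[[x]], levels = unique(df[[x]]))
         else df[[x]],
    yv = df[[y]])
  ggplot2::ggplot(dd, ggplot2::aes(x = xv, y = yv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab, title = title) +
    ggplot2::theme_minimal(base_size = 11)
}

#' Evaluate a design and write a full report bundle
#'
#' Runs the exact engine for one design and dose-toxicity scenario and
#' writes, to `out_dir`: four bar charts (sample-size distribution,
#' experimentation percentages, MTD recommendation percentages, DLT-rate
#' distribution) as PNGs; CSV tables of the per-dose scenario operating
#' characteristics, the distributions, the toxicity-interval summaries, the
#' pathway table and the design characteristics; JSON exports of the
#' scenario and design operating characteristics; and a Markdown report
#' (`report.md`, plus `report.html` when `format = "html"`) whose numbers
#' equal the CSV exports exactly. Optionally a Monte-Carlo cross-check
#' comparison table is included.
#'
#' @param design An [ab_design()] object.
#' @param scenario A [tox_scenario()] object.
#' @param out_dir Output directory; created if absent.
#' @param conf_level Confidence level for MTD confidence intervals.
#' @param format `"md"` (default) or `"html"` (requires the `commonmark`
#'   package; writes both `report.md` and `report.html`).
#' @param mc_check If non-`NULL`, number of Monte-Carlo simulations to run
#'   as a cross-check; the exact-vs-empirical comparison is exported and
#'   reported.
#' @param seed Integer seed for the Monte-Carlo cross-check.
#' @param overwrite Logical; must be `TRUE` to write into a directory that
#'   already contains a previous report.
#' @param verbose Logical; print progress information.
#' @return Invisibly, a list with the computed `scenario_ocs`,
#'   `design_ocs`, optional `mc` comparison, and the paths written.
#' @export
run_report <- function(design, scenario, out_dir, conf_level = 0.95,
                       format = c("md", "html"), mc_check = NULL,
                       seed = NULL, overwrite = FALSE, verbose = FALSE) {
  stopifnot(inherits(design, "ab_design"), inherits(scenario, "tox_scenario"))
  format <- match.arg(format)
  if (length(conf_level) != 1L || !is.numeric(conf_level) ||
      is.na(conf_level) || conf_level <= 0 || conf_level >= 1)
    stop("'conf_level' must lie strictly between 0 and 1", call. = FALSE)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  } else if (file.exists(file.path(out_dir, "report.md")) && !overwrite) {
    stop("'", out_dir, "' already contains a report; use overwrite = TRUE",
         call. = FALSE)
  }
  t0 <- Sys.time()
  ps <- enumerate_pathways(design, scenario)
  ocs <- operating_characteristics(ps)
  dcs <- design_characteristics(design, conf_level)
  if (verbose)
    message(sprintf("enumerated %d pathways in %.2f s", length(ps$pathways),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  paths <- character(0)
  wcsv <- function(df, name) {
    fp <- file.path(out_dir, name)
    utils::write.csv(df, fp, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- fp
    fp
  }

  dose_tab <- rounded_dose_table(ocs)
  ss_tab <- data.frame(n = ocs$sample_size$n,
                       prob = fmt_prob(ocs$sample_size$prob))
  dr_tab <- data.frame(rate = fmt_prob(ocs$dlt_rates$rate),
                       prob = fmt_prob(ocs$dlt_rates$prob))
  int_tab <- data.frame(
    interval = ocs$intervals$interval,
    experimentation_pct = fmt_pct(ocs$intervals$experimentation_pct),
    recommendation_pct = fmt_pct(ocs$intervals$recommendation_pct))
  ci_tab <- rounded_ci_table(dcs)

  wcsv(dose_tab, "scenario_dose_table.csv")
  wcsv(ss_tab, "sample_size_distribution.csv")
  wcsv(dr_tab, "dlt_rate_distribution.csv")
  wcsv(int_tab, "interval_summaries.csv")
  wcsv(ci_tab, "design_ci_table.csv")
  wcsv(pathway_table(ps), "pathways.csv")

  scen_json <- list(
    design = design[c("A", "B", "C", "D", "E", "deescalate")],
    dlt_probs = scenario$dlt_probs,
    n_pathways = ocs$n_pathways,
    dose_table = ocs$dose_table,
    sample_size = ocs$sample_size,
    dlt_rates = ocs$dlt_rates,
    intervals = ocs$intervals,
    prob_no_mtd_safety = ocs$prob_no_mtd_safety,
    prob_all_tolerated = ocs$prob_all_tolerated,
    etl = ocs$etl, eotr = ocs$eotr, mean_dlts = ocs$mean_dlts,
    expected_n = ocs$expected_n)
  jsonlite::write_json(scen_json, file.path(out_dir, "scenario_ocs.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  design_json <- list(
    design = design[c("A", "B", "C", "D", "E", "deescalate")],
    ci_table = dcs$ci_table, tipping_point = dcs$tipping_point,
    conf_level = conf_level)
  jsonlite::write_json(design_json, file.path(out_dir, "design_ocs.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  paths <- c(paths, file.path(out_dir, c("scenario_ocs.json",
                                         "design_ocs.json")))

  # four bar charts
  figs <- list(
    sample_size = bar_chart(ocs$sample_size, "n", "prob",
                            "Total sample size", "Probability",
                            "Sample size distribution"),
    experimentation = bar_chart(ocs$dose_table, "dose",
                                "experimentation_pct", "Dose level",
                                "% of patients",
                                "Experimentation percentages"),
    mtd_recommendation = bar_chart(
      within(mtd_distribution(ps),
             category <- sub("^dose_", "d", category)),
      "category", "pct", "MTD outcome", "% of trials",
      "MTD recommendation percentages"),
    dlt_rates = bar_chart(
      within(ocs$dlt_rates, rate <- sprintf("%.2f", rate)),
      "rate", "prob", "Within-trial DLT rate", "Probability",
      "DLT rate distribution"))
  for (nm in names(figs)) {
    fp <- file.path(out_dir, paste0(nm, ".png"))
    suppressMessages(ggplot2::ggsave(fp, figs[[nm]], width = 5, height = 3.5,
                                     dpi = 120))
    paths <- c(paths, fp)
  }

  mc_cmp <- NULL
  if (!is.null(mc_check)) {
    mc <- estimate_ocs(design, scenario, n_sims = mc_check, seed = seed)
    mc_cmp <- compare_exact_mc(ocs, mc)
    mc_tab <- data.frame(quantity = mc_cmp$quantity,
                         exact = round_half_away(mc_cmp$exact, 3),
                         mc = round_half_away(mc_cmp$mc, 3),
                         z = round_half_away(mc_cmp$z, 2))
    wcsv(mc_tab, "mc_comparison.csv")
  }

  md <- c(
    sprintf("# A+B design evaluation: %d+%d {%d,%d,%d,%d,%d}", design$A,
            design$B, design$A, design$B, design$C, design$D, design$E),
    "",
    "## Design summary",
    "",
    sprintf("- Cohort sizes: first %d, expansion %d", design$A, design$B),
    sprintf("- Expand on %d..%d DLTs out of %d; escalate an expanded dose on at most %d DLTs out of %d",
            design$C, design$D, design$A, design$E, design$A + design$B),
    sprintf("- Dose de-escalation: %s",
            if (design$deescalate) "permitted" else "not permitted"),
    sprintf("- True DLT probabilities: %s",
            paste(fmt_prob(scenario$dlt_probs), collapse = ", ")),
    sprintf("- Distinct trial pathways: %d", ocs$n_pathways),
    "",
    "## Scenario operating characteristics",
    "",
    md_table(dose_tab),
    "",
    sprintf("- P(no MTD, safety): %s%%",
            format(fmt_pct(100 * ocs$prob_no_mtd_safety))),
    sprintf("- P(all doses tolerated): %s%%",
            format(fmt_pct(100 * ocs$prob_all_tolerated))),
    sprintf("- Expected toxicity level (ETL): %s", format(fmt_prob(ocs$etl))),
    sprintf("- Expected overall toxicity rate (EOTR): %s",
            format(fmt_prob(ocs$eotr))),
    sprintf("- Mean number of DLTs: %s", format(fmt_count(ocs$mean_dlts))),
    sprintf("- Expected sample size: %s", format(fmt_count(ocs$expected_n))),
    "",
    "### By interval of true DLT probability",
    "",
    md_table(int_tab),
    "",
    "### Sample size distribution",
    "",
    md_table(ss_tab),
    "",
    "## Design operating characteristics",
    "",
    sprintf("%.0f%% confidence intervals for the DLT probability given the data possible at the selected MTD:",
            100 * conf_level),
    "",
    md_table(ci_tab),
    "",
    if (is.na(dcs$tipping_point))
      "- Tipping point: undefined for this design"
    else sprintf("- Tipping point: %s",
                 format(round_half_away(dcs$tipping_point, 3))),
    "",
    "## Plots",
    "",
    "![Sample size distribution](sample_size.png)",
    "![Experimentation percentages](experimentation.png)",
    "![MTD recommendation percentages](mtd_recommendation.png)",
    "![DLT rate distribution](dlt_rates.png)",
    "")
  if (!is.null(mc_cmp)) {
    md <- c(md,
            sprintf("## Monte-Carlo cross-check (%d simulations)",
                    as.integer(mc_check)),
            "",
            md_table(utils::read.csv(file.path(out_dir,
                                               "mc_comparison.csv"))),
            "")
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  paths <- c(paths, md_path)
  if (format == "html") {
    if (!requireNamespace("commonmark", quietly = TRUE))
      stop("HTML output requires the 'commonmark' package", call. = FALSE)
    html_path <- file.path(out_dir, "report.html")
    writeLines(commonmark::markdown_html(paste(md, collapse = "\n"),
                                         extensions = TRUE), html_path)
    paths <- c(paths, html_path)
  }
  if (verbose) message("wrote ", length(paths), " files to ", out_dir)
  invisible(list(scenario_ocs = ocs, design_ocs = dcs, mc = mc_cmp,
                 paths = paths))
}
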