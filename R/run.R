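#' Plot an index-versus-p4 curve family panel
#'
#' Draws one panel in the style of the simulation figures: the tracked index
#' (|SII|, RII or PAF) against the top-level share p4, one line per curve
#' family.
#'
#' @param families List of [extract_family()] results sharing the same
#'   index.
#' @return A ggplot object.
#' @export
plot_families <- function(families) {
  if (inherits(families, "curve_family")) families <- list(families)
  stopifnot(length(families) > 0L)
  idx <- attr(families[[1]], "index")
  dat <- do.call(rbind, lapply(families, function(f) {
    fx <- attr(f, "fixed")
    data.frame(p4 = f$p4, value = f$value,
               family = paste(names(fx), fx, sep = "=", collapse = ", "))
  }))
  lab <- switch(idx, sii = "|SII| (per 100,000 person-years)",
                rii = "RII", paf = "PAF")
  ggplot2::ggplot(dat, ggplot2::aes(x = p4, y = value, colour = family)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "share of the highest level, p4 (%)", y = lab,
                  colour = "fixed shares") +
    ggplot2::theme_minimal()
}

# Shared bookkeeping for the run_* front ends.
prepare_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

run_log <- function(outdir, command, config, results) {
  lines <- c(
    sprintf("ineqshift %s", as.character(utils::packageVersion("ineqshift"))),
    sprintf("command: %s", command),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "config:",
    paste0("  ", utils::capture.output(utils::str(config, give.attr = FALSE))),
    "results (full precision):",
    paste0("  ", utils::capture.output(print(results)))
  )
  writeLines(lines, file.path(outdir, paste0(command, ".log")))
}

#' Compute indices for one stratified table and write reports
#'
#' Reads a `level_label, share, rate` CSV, computes the full set of
#' inequality indices and writes `indices.json` (full-precision and
#' display-rounded values), `indices.csv` and a run log to the output
#' directory.
#'
#' @param input Path to the stratified-table CSV.
#' @param outdir Output directory (created if absent).
#' @param reference Reference level; defaults to the last level.
#' @return The [inequality_indices()] object, invisibly.
#' @export
run_indices <- function(input, outdir = ".", reference = NULL) {
  tab <- read_rate_table(input)
  ref <- if (is.null(reference)) nrow(tab) else reference
  ix <- inequality_indices(tab$share, tab$rate, ref)
  prepare_outdir(outdir)
  indices_json(ix, file.path(outdir, "indices.json"))
  utils::write.csv(as.data.frame(ix), file.path(outdir, "indices.csv"),
                   row.names = FALSE, quote = FALSE)
  run_log(outdir, "indices", list(input = input, reference = ref),
          as.data.frame(ix))
  invisible(ix)
}

#' Run the distribution-grid simulation and write its outputs
#'
#' Enumerates the share grid, evaluates SII/RII/PAF at the fixed schedule,
#' writes the full grid as CSV and, for each requested family, a
#' curve-family CSV and a figure panel per index.
#'
#' @param rates Rate schedule per 100,000 person-years.
#' @param spec A [grid_spec()].
#' @param families Optional named list of family requests, each a list with
#'   `kind` and `fixed` (see [extract_family()]).
#' @param outdir Output directory.
#' @param plot Write PNG panels for the requested families?
#' @return The evaluated grid data frame, invisibly.
#' @export
run_grid <- function(rates, spec = grid_spec(), families = NULL,
                     outdir = ".", plot = TRUE) {
  grid <- generate_eld_grid(spec)
  res <- evaluate_grid(grid, rates)
  prepare_outdir(outdir)
  utils::write.csv(res, file.path(outdir, "grid.csv"), row.names = FALSE,
                   quote = FALSE)
  for (idx in c("sii", "rii", "paf")) {
    fams <- lapply(families, function(f)
      extract_family(res, f$kind, f$fixed, index = idx))
    fams <- Filter(function(f) nrow(f) > 0L, fams)
    if (length(fams)) {
      for (k in seq_along(fams))
        utils::write.csv(
          fams[[k]],
          file.path(outdir, sprintf("family_%s_%s.csv", idx, names(fams)[k])),
          row.names = FALSE, quote = FALSE)
      if (plot)
        ggplot2::ggsave(file.path(outdir, sprintf("family_%s.png", idx)),
                        plot_families(fams), width = 6, height = 4, dpi = 150)
    }
  }
  run_log(outdir, "grid", list(rates = rates, spec = unclass(spec)),
          utils::head(res))
  invisible(res)
}

#' Evaluate scenarios, decompose changes and write a report
#'
#' Evaluates every scenario of a YAML config (or an in-memory list), writes
#' the wide comparison table as CSV, a formatted text report, and — when a
#' baseline is named — the percent-change decomposition.
#'
#' @param config Path to a YAML scenario config (see
#'   [read_scenarios_yaml()]), or a list of [scenario()] objects.
#' @param baseline Baseline label; overrides the config's when given.
#' @param outdir Output directory.
#' @param reference Reference level; defaults to the last level.
#' @return The [scenario_table()], invisibly.
#' @export
run_scenarios <- function(config, baseline = NULL, outdir = ".",
                          reference = NULL) {
  if (is.character(config)) {
    cfg <- read_scenarios_yaml(config)
    scen <- cfg$scenarios
    if (is.null(baseline)) baseline <- cfg$baseline
  } else scen <- config
  tab <- scenario_table(scen, baseline = baseline, reference = reference)
  prepare_outdir(outdir)
  ev <- evaluate_scenarios(scen, reference)
  utils::write.csv(ev, file.path(outdir, "scenarios.csv"), row.names = FALSE,
                   quote = FALSE)
  report <- utils::capture.output(print(tab))
  writeLines(report, file.path(outdir, "scenario_report.txt"))
  if (!is.null(tab$changes))
    utils::write.csv(tab$changes, file.path(outdir, "scenario_changes.csv"),
                     row.names = FALSE, quote = FALSE)
  run_log(outdir, "scenarios",
          list(n_scenarios = length(scen), baseline = baseline), ev)
  invisible(tab)
}

#' Simulate confidence-interval behaviour on synthetic populations
#'
#' Draws `reps` Poisson populations at the given distribution, schedule and
#' person-years, computes SII/RII confidence intervals for each, and writes
#' a per-replicate CSV plus a coverage summary (how often the interval
#' covers the noise-free index).
#'
#' @param shares,rates Distribution and schedule of the simulated
#'   population.
#' @param person_years Total person-years per replicate.
#' @param reps Number of replicates.
#' @param seed Integer seed governing all draws.
#' @param ci_level Confidence level.
#' @param outdir Output directory.
#' @return Data frame of per-replicate estimates and bounds, invisibly;
#'   the coverage summary is attached as attribute `"coverage"`.
#' @export
run_simulate_ci <- function(shares, rates, person_years, reps = 200L,
                            seed = 1L, ci_level = 0.95, outdir = ".") {
  truth <- inequality_indices(shares, rates)
  rows <- lapply(seq_len(reps), function(r) {
    pop <- sample_population(shares, rates, person_years, seed = seed + r)
    est <- indices_with_ci(pop, ci_level)
    data.frame(rep = r, sii = est$indices$sii, rii = est$indices$rii,
               sii_lo = est$ci["sii", 1], sii_hi = est$ci["sii", 2],
               rii_lo = est$ci["rii", 1], rii_hi = est$ci["rii", 2])
  })
  out <- do.call(rbind, rows)
  coverage <- c(
    sii = mean(out$sii_lo <= truth$sii & truth$sii <= out$sii_hi),
    rii = mean(out$rii_lo <= truth$rii & truth$rii <= out$rii_hi, na.rm = TRUE)
  )
  prepare_outdir(outdir)
  utils::write.csv(out, file.path(outdir, "simulate_ci.csv"),
                   row.names = FALSE, quote = FALSE)
  run_log(outdir, "simulate-ci",
          list(person_years = person_years, reps = reps, seed = seed,
               ci_level = ci_level),
          data.frame(true_sii = truth$sii, true_rii = truth$rii,
                     coverage_sii = coverage["sii"],
                     coverage_rii = coverage["rii"]))
  attr(out, "coverage") <- coverage
  invisible(out)
}
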