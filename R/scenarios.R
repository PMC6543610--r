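#' Named (rates, distribution) scenario
#'
#' A scenario couples a mortality schedule with an educational-level
#' distribution under a label, the unit of the scenario-comparison engine.
#'
#' @param label Short scenario name (e.g. `"A"`).
#' @param shares Population shares per level, lowest level first.
#' @param rates Event rates per 100,000 person-years, aligned with `shares`.
#' @return List of class `"scenario"`.
#' @examples
#' scenario("A", c(0.40, 0.25, 0.25, 0.10), c(750, 550, 450, 300))
#' @export
scenario <- function(label, shares, rates) {
  p <- as.numeric(as_eld(shares))
  y <- rate_schedule(rates, p)
  structure(list(label = as.character(label), shares = p, rates = y),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$label, "-", length(x$shares), "levels\n")
  print(data.frame(level = paste0("EL", seq_along(x$shares)),
                   share = x$shares, rate = x$rates))
  invisible(x)
}

#' The six reference scenarios of the composition-shift study
#'
#' Three rate schedules (baseline; lower rates with smaller differentials;
#' higher rates with larger differentials) crossed with two educational
#' distributions (ELD1, left-skewed with p1 = 40% and p4 = 10%; ELD2, an
#' upward shift with p1 = 20% and p4 = 30%) give scenarios A-F.
#'
#' @return Named list of six [scenario()] objects.
#' @export
reference_scenarios <- function() {
  eld1 <- c(0.40, 0.25, 0.25, 0.10)
  eld2 <- c(0.20, 0.25, 0.25, 0.30)
  r1 <- c(750, 550, 450, 300)
  r2 <- c(630, 500, 400, 290)
  r3 <- c(750, 570, 420, 260)
  list(A = scenario("A", eld1, r1), B = scenario("B", eld2, r1),
       C = scenario("C", eld1, r2), D = scenario("D", eld2, r2),
       E = scenario("E", eld1, r3), F = scenario("F", eld2, r3))
}

#' Evaluate inequality indices for a set of scenarios
#'
#' @param scenarios List of [scenario()] objects (at least one).
#' @param reference Reference level for PAF and pairwise comparisons;
#'   defaults to the last level.
#' @return Data frame with one row per scenario: `label`, `sii`, `rii`,
#'   `paf`, `mean_rate`, plus pairwise `diff_EL<i>` and `ratio_EL<i>`
#'   columns versus the reference level. Full `inequality_indices` objects
#'   are attached as the `"indices"` attribute.
#' @examples
#' evaluate_scenarios(reference_scenarios())
#' @export
evaluate_scenarios <- function(scenarios, reference = NULL) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  if (length(scenarios) < 1L) stop("need at least one scenario", call. = FALSE)
  rows <- lapply(scenarios, function(s) {
    stopifnot(inherits(s, "scenario"))
    ref <- if (is.null(reference)) length(s$rates) else reference
    ix <- inequality_indices(s$shares, s$rates, ref)
    pw <- ix$pairwise
    row <- data.frame(label = s$label, sii = ix$sii, rii = ix$rii,
                      paf = ix$paf, mean_rate = ix$mean_rate,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pw))) {
      row[[paste0("diff_", pw$level[i])]] <- pw$difference[i]
      row[[paste0("ratio_", pw$level[i])]] <- pw$ratio[i]
    }
    list(row = row, ix = ix)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "indices") <- setNames(lapply(rows, `[[`, "ix"), out$label)
  out
}

# Index values used by the decomposition, computed in full precision.
decomposable_values <- function(s, reference = NULL) {
  ref <- if (is.null(reference)) length(s$rates) else reference
  ix <- inequality_indices(s$shares, s$rates, ref)
  pw <- ix$pairwise
  non_ref <- setdiff(seq_len(nrow(pw)), ref)
  vals <- c(sii = ix$sii, rii = ix$rii, paf = ix$paf)
  for (i in non_ref) {
    vals[[paste0("diff_", pw$level[i])]] <- pw$difference[i]
    vals[[paste0("ratio_", pw$level[i])]] <- pw$ratio[i]
  }
  vals
}

#' Decompose an index change into rate and composition components
#'
#' Splits the change of each inequality index from a baseline scenario to a
#' scenario where both the rate schedule and the distribution have changed,
#' into (i) a mortality-differential component — the change produced by the
#' new rates at the baseline distribution — and (ii) a composition-shift
#' component — the further change produced by the new distribution at the
#' new rates. Both are expressed as percent of the baseline index, so they
#' add up exactly to the total percent change.
#'
#' The decomposition is path-dependent by construction (rates move first,
#' then the distribution), matching the definition
#' `differential = (index(rates_changed) - index(baseline)) / index(baseline)`
#' and
#' `shift = (index(rates_and_eld_changed) - index(rates_changed)) / index(baseline)`.
#' All components are computed from full-precision index values; rounding is
#' applied only for display.
#'
#' @param baseline Baseline [scenario()].
#' @param rates_changed Scenario with the new rate schedule and the
#'   baseline's distribution.
#' @param rates_and_eld_changed Scenario with the new rate schedule and the
#'   new distribution.
#' @param reference Reference level; defaults to the last level.
#' @return Data frame of class `"decomposition"`, one row per index (`sii`,
#'   `rii`, `paf` and the pairwise differentials): `baseline`, `comparison`,
#'   `total_pct`, `differential_pct`, `shift_pct`.
#' @examples
#' s <- reference_scenarios()
#' decompose_change(s$A, s$C, s$D)
#' @export
decompose_change <- function(baseline, rates_changed, rates_and_eld_changed,
                             reference = NULL) {
  stopifnot(inherits(baseline, "scenario"),
            inherits(rates_changed, "scenario"),
            inherits(rates_and_eld_changed, "scenario"))
  if (!isTRUE(all.equal(baseline$shares, rates_changed$shares)))
    stop("'rates_changed' must keep the baseline distribution", call. = FALSE)
  if (!isTRUE(all.equal(rates_changed$rates, rates_and_eld_changed$rates)))
    stop("'rates_and_eld_changed' must keep the changed rate schedule",
         call. = FALSE)
  v0 <- decomposable_values(baseline, reference)
  v1 <- decomposable_values(rates_changed, reference)
  v2 <- decomposable_values(rates_and_eld_changed, reference)
  if (any(v0 == 0))
    stop("zero baseline index: percent change undefined for ",
         paste(names(v0)[v0 == 0], collapse = ", "), call. = FALSE)
  out <- data.frame(
    index = names(v0),
    baseline = unname(v0),
    comparison = unname(v2),
    total_pct = unname(100 * (v2 - v0) / v0),
    differential_pct = unname(100 * (v1 - v0) / v0),
    shift_pct = unname(100 * (v2 - v1) / v0),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("decomposition", "data.frame"),
            labels = c(baseline$label, rates_changed$label,
                       rates_and_eld_changed$label))
}

#' @export
print.decomposition <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("Change decomposition: %s -> %s (rates) -> %s (distribution)\n",
              lab[1], lab[2], lab[3]))
  disp <- x
  disp$total_pct <- sprintf("%+.0f%%", x$total_pct)
  disp$differential_pct <- sprintf("%+.0f%%", x$differential_pct)
  disp$shift_pct <- sprintf("%+.0f%%", x$shift_pct)
  disp$baseline <- signif(x$baseline, 4)
  disp$comparison <- signif(x$comparison, 4)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Build a scenario comparison table
#'
#' Renders a set of scenarios as a wide report table: per-scenario rates and
#' shares, the pairwise block (differences and ratios versus the reference
#' level) and the composite block (SII, RII, PAF), with percent-change
#' annotations against a baseline when one is named. Composite values are
#' display-rounded (SII to integers, RII/PAF to 2 decimals); percent changes
#' come from full-precision values.
#'
#' @param scenarios List of [scenario()] objects; may be empty.
#' @param baseline Label of the baseline scenario for change annotations, or
#'   `NULL` for a table without change columns.
#' @param reference Reference level; defaults to the last level.
#' @return List of class `"scenario_table"` with data frames `inputs`
#'   (level-by-scenario rates and shares), `pairwise`, `composite` and, when
#'   a baseline is given, `changes` (percent of baseline, full precision).
#' @examples
#' scenario_table(reference_scenarios(), baseline = "A")
#' @export
scenario_table <- function(scenarios, baseline = NULL, reference = NULL) {
  if (length(scenarios) == 0L)
    return(structure(list(inputs = data.frame(), pairwise = data.frame(),
                          composite = data.frame(), changes = NULL),
                     class = "scenario_table"))
  ev <- evaluate_scenarios(scenarios, reference)
  labs <- ev$label
  n <- length(scenarios[[1]]$shares)
  inputs <- data.frame(level = paste0("EL", seq_len(n)))
  for (k in seq_along(scenarios)) {
    s <- scenarios[[k]]
    inputs[[paste0("rate_", s$label)]] <- s$rates
    inputs[[paste0("share_", s$label)]] <- s$shares
  }
  pw_cols <- grep("^(diff|ratio)_", names(ev), value = TRUE)
  pairwise <- data.frame(measure = pw_cols)
  composite <- data.frame(
    index = c("SII", "RII", "PAF"),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(ev))) {
    pairwise[[labs[k]]] <- as.numeric(ev[k, pw_cols])
    composite[[labs[k]]] <- c(round(ev$sii[k]), round(ev$rii[k], 2),
                              round(ev$paf[k], 2))
  }
  changes <- NULL
  if (!is.null(baseline)) {
    if (!baseline %in% labs) stop("baseline scenario '", baseline,
                                  "' not in the set", call. = FALSE)
    b <- which(labs == baseline)
    changes <- data.frame(index = c("sii", "rii", "paf"))
    full <- rbind(sii = ev$sii, rii = ev$rii, paf = ev$paf)
    for (k in seq_len(nrow(ev))) {
      changes[[labs[k]]] <- 100 * (full[, k] - full[, b]) / full[, b]
    }
  }
  structure(list(inputs = inputs, pairwise = pairwise, composite = composite,
                 changes = changes, baseline = baseline),
            class = "scenario_table")
}

#' @export
print.scenario_table <- function(x, ...) {
  if (nrow(x$composite) == 0L) {
    cat("Empty scenario table\n"); return(invisible(x))
  }
  cat("Scenario inputs (rates per 100,000 py; shares as fractions):\n")
  print(x$inputs, row.names = FALSE)
  cat("\nPairwise differentials (vs reference level):\n")
  print(cbind(x$pairwise[1], round(x$pairwise[-1], 2)), row.names = FALSE)
  cat("\nComposite indices (display-rounded):\n")
  print(x$composite, row.names = FALSE)
  if (!is.null(x$changes)) {
    cat("\nPercent change vs baseline", x$baseline,
        "(full precision, rounded for display):\n")
    print(cbind(x$changes[1], round(x$changes[-1])), row.names = FALSE)
  }
  invisible(x)
}

#' Read scenario definitions from a YAML config
#'
#' The file maps scenario labels to `shares` and `rates` lists:
#' ```yaml
#' scenarios:
#'   A: {shares: [0.40, 0.25, 0.25, 0.10], rates: [750, 550, 450, 300]}
#'   B: {shares: [0.20, 0.25, 0.25, 0.30], rates: [750, 550, 450, 300]}
#' baseline: A
#' ```
#'
#' @param path Path to the YAML file.
#' @return List with `scenarios` (named list of [scenario()]) and `baseline`
#'   (label or `NULL`).
#' @export
read_scenarios_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    stop("config must define at least one scenario", call. = FALSE)
  scen <- lapply(names(cfg$scenarios), function(lab) {
    s <- cfg$scenarios[[lab]]
    if (is.null(s$shares) || is.null(s$rates))
      stop("scenario '", lab, "' needs both 'shares' and 'rates'", call. = FALSE)
    scenario(lab, as.numeric(s$shares), as.numeric(s$rates))
  })
  names(scen) <- names(cfg$scenarios)
  list(scenarios = scen, baseline = cfg$baseline)
}
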