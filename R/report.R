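#' Evaluate the base case over the structural-convention grid
#'
#' The authors' spreadsheet conventions are not fully published, so three
#' binary modelling conventions are genuinely open: the treatment-switch
#' timing (`per_cycle` vs `first_cycle_only`), the discount timing
#' (`mid_cycle` vs `end_of_cycle`), and whether AP/BP patients keep accruing
#' their current drug's cost (`continue` vs `none`). This helper re-runs the
#' model at all eight combinations and reports per-strategy totals together
#' with the total relative deviation from a set of reference totals (by
#' default the published base-case table), which is how the shipped default
#' convention set was selected and documented.
#'
#' @param spec A `tki_spec` (default: the packaged base case).
#' @param reference_totals Data frame with columns `strategy`, `total_cost`,
#'   `total_qalys` used for the deviation column; `NULL` skips it.
#' @return Data frame: one row per convention combination with per-strategy
#'   costs/QALYs and `total_rel_dev`, sorted by deviation when available.
#' @export
run_convention_grid <- function(spec = builtin_basecase(),
                                reference_totals = published_basecase_totals()) {
  grid <- expand.grid(
    switch_mode = c("per_cycle", "first_cycle_only"),
    discount_timing = c("mid_cycle", "end_of_cycle"),
    apbp_drug_cost = c("continue", "none"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- spec
    s$conventions$switch_mode <- grid$switch_mode[i]
    s$conventions$discount_timing <- grid$discount_timing[i]
    s$conventions$apbp_drug_cost <- grid$apbp_drug_cost[i]
    run <- run_model(s)$summary
    out <- grid[i, , drop = FALSE]
    for (j in seq_len(nrow(run))) {
      out[[paste0("cost_", run$strategy[j])]] <- run$total_cost[j]
      out[[paste0("qalys_", run$strategy[j])]] <- run$total_qalys[j]
    }
    if (!is.null(reference_totals)) {
      m <- merge(run, reference_totals, by = "strategy",
                 suffixes = c("", "_ref"))
      out$total_rel_dev <-
        sum(abs(m$total_cost - m$total_cost_ref) / m$total_cost_ref) +
        sum(abs(m$total_qalys - m$total_qalys_ref) / m$total_qalys_ref)
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference_totals)) out <- out[order(out$total_rel_dev), ]
  rownames(out) <- NULL
  out
}

#' Published base-case totals
#'
#' The per-strategy discounted totals of the published base-case analysis,
#' used as the reference for convention-grid selection and for acceptance
#' checks.
#'
#' @return Data frame: `strategy`, `total_cost` (US$), `total_qalys`.
#' @export
published_basecase_totals <- function() {
  data.frame(strategy = c("imatinib", "nilotinib", "dasatinib"),
             total_cost = c(120719.55, 169861.41, 180774.97),
             total_qalys = c(5.93, 7.78, 7.60))
}

write_manifest <- function(out_dir, spec, outputs, seed = NULL) {
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(spec, cfg_path)
  manifest <- list(
    config = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = seed,
    conventions = spec$conventions,
    package_version = as.character(packageVersion("tkicea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = basename(outputs)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the base-case analysis and write its report files
#'
#' Writes `basecase_table.csv` (the incremental cost-effectiveness table),
#' one trace CSV per strategy (`trace_<strategy>.csv`: cycle, state,
#' occupancy), the resolved configuration, and a JSON manifest recording the
#' configuration hash and convention flags.
#'
#' @param spec A `tki_spec`.
#' @param out_dir Output directory (created if missing).
#' @param reference Reference strategy for the incremental table.
#' @return Invisibly, the character vector of files written.
#' @export
run_basecase_report <- function(spec, out_dir,
                                reference = names(spec$strategies)[1]) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_model(spec)
  tab <- build_incremental_table(run, reference = reference)
  files <- file.path(out_dir, "basecase_table.csv")
  write_icer_table(tab, files)
  for (st in names(run$results)) {
    f <- file.path(out_dir, paste0("trace_", st, ".csv"))
    write.csv(trace_as_df(run$results[[st]]$trace), f, row.names = FALSE)
    files <- c(files, f)
  }
  files <- c(files, write_manifest(out_dir, spec, files))
  invisible(files)
}

#' Run the one-way sensitivity analyses and write their report files
#'
#' One sorted tornado table per comparator (`dsa_<comparator>.csv`), the
#' switch-split and discount-rate sweeps, and a manifest.
#'
#' @param spec A `tki_spec`.
#' @param out_dir Output directory.
#' @param comparators Strategies compared against the reference.
#' @param reference Reference strategy.
#' @return Invisibly, the files written.
#' @export
run_dsa_report <- function(spec, out_dir,
                           comparators = setdiff(names(spec$strategies),
                                                 reference),
                           reference = "imatinib") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cmp in comparators) {
    f <- file.path(out_dir, paste0("dsa_", cmp, "_vs_", reference, ".csv"))
    write.csv(as.data.frame(tornado(spec, cmp, reference)), f,
              row.names = FALSE)
    files <- c(files, f)
  }
  if (reference %in% names(spec$strategies) &&
      all(c("nilotinib", "dasatinib") %in% names(spec$drugs))) {
    f <- file.path(out_dir, "switch_split_sweep.csv")
    write.csv(switch_split_sweep(spec, reference = reference), f,
              row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "discount_sweep.csv")
  write.csv(discount_sweep(spec, reference = reference), f, row.names = FALSE)
  files <- c(files, f)
  files <- c(files, write_manifest(out_dir, spec, files))
  invisible(files)
}

#' Run the probabilistic sensitivity analysis and write its report files
#'
#' Writes the parameter draws (`psa_draws.csv`), per-iteration strategy
#' outcomes (`psa_outcomes.csv`), pairwise cost-effectiveness-plane points
#' and ellipse parameters per comparator, the acceptability curves
#' (`ceac.csv`), and a manifest.
#'
#' @param spec A `tki_spec`.
#' @param out_dir Output directory.
#' @param n Iterations.
#' @param seed Integer seed.
#' @param wtp_grid Thresholds for the acceptability curves.
#' @param reference Reference strategy for pairwise outputs.
#' @return Invisibly, the files written.
#' @export
run_psa_report <- function(spec, out_dir, n = 1000, seed = 1,
                           wtp_grid = default_wtp_grid(spec),
                           reference = "imatinib") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(spec, n = n, seed = seed)
  files <- file.path(out_dir, "psa_draws.csv")
  write.csv(cbind(iteration = seq_len(n), psa$draws), files,
            row.names = FALSE)
  outcomes <- data.frame(
    iteration = rep(seq_len(n), times = length(psa$strategies)),
    strategy = rep(psa$strategies, each = n),
    total_cost = as.numeric(psa$cost),
    total_qalys = as.numeric(psa$qalys))
  f <- file.path(out_dir, "psa_outcomes.csv")
  write.csv(outcomes, f, row.names = FALSE)
  files <- c(files, f)
  for (cmp in setdiff(psa$strategies, reference)) {
    d <- psa_deltas(psa, reference, cmp)
    f <- file.path(out_dir, paste0("ce_plane_", cmp, "_vs_", reference,
                                   ".csv"))
    write.csv(d, f, row.names = FALSE)
    files <- c(files, f)
    el <- confidence_ellipse(psa, reference, cmp)
    f <- file.path(out_dir, paste0("ellipse_", cmp, "_vs_", reference,
                                   ".csv"))
    write.csv(data.frame(center_de = el$center[1], center_dc = el$center[2],
                         cov_ee = el$cov[1, 1], cov_ec = el$cov[1, 2],
                         cov_cc = el$cov[2, 2], radius2 = el$radius2,
                         axis_major = max(el$axes),
                         axis_minor = min(el$axes), angle = el$angle),
              f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "ceac.csv")
  write.csv(as.data.frame(ceac(psa, wtp_grid)), f, row.names = FALSE)
  files <- c(files, f)
  files <- c(files, write_manifest(out_dir, spec, files, seed = seed))
  invisible(files)
}
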