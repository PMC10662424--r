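## Benchmark orchestration: run every assay over a sample manifest and
## assemble the per-sample summary table (class, eta at 50 1/s, breakup
## time, extensional maxima, boundary friction, QCM-D coating index).

analyze_one_sample <- function(entry, reference_rate, reference_speed,
                               base_dir = ".") {
  rec <- list(name = entry$name, class = NA_character_,
              eta_at_50 = NA_real_, t_b = NA_real_,
              thinning_model = NA_character_,
              max_eta_extensional = NA_real_, max_trouton = NA_real_,
              boundary_mu = NA_real_, mu_at_reference = NA_real_,
              surface = NA_character_, removal_percent = NA_real_,
              t_saturation_min = NA_real_, p_value = NA_real_,
              note = "")
  note <- function(msg) {
    rec$note <<- if (nzchar(rec$note)) paste(rec$note, msg, sep = "; ")
                 else msg
  }
  grab <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      note(sprintf("%s: %s", label, conditionMessage(e)))
      NULL
    })
  }
  resolve <- function(p) if (is.null(p)) NULL else
    (if (file.exists(p)) p else file.path(base_dir, p))

  gen <- if (!is.null(entry$preset))
    grab(generate_preset_sample(entry$preset,
                                if (is.null(entry$seed)) 1L
                                else as.integer(entry$seed)),
         "generation")
  sigma <- entry$sigma %||% gen$sigma

  # -- shear rheology ------------------------------------------------------
  flow <- if (!is.null(entry$flow))
    grab(read_flow_curve_csv(resolve(entry$flow)), "flow") else gen$flow
  shear_fit <- NULL
  if (!is.null(flow)) {
    mean_curve <- if (length(flow) >= 2L)
      grab(aggregate_replicates(flow)$mean, "replicates") %||% flow[[1L]]
      else flow[[1L]]
    eta50 <- grab(viscosity_at(mean_curve, reference_rate), "viscosity_at")
    if (!is.null(eta50)) {
      rec$eta_at_50 <- eta50
      cls <- grab(classify_viscosity(eta50, reference_rate), "classify")
      if (!is.null(cls)) rec$class <- cls$label
    }
    shear_fit <- grab(fit_shear_model(mean_curve), "shear fit")
  }

  # -- extensional rheology ------------------------------------------------
  thin <- if (!is.null(entry$thinning))
    grab(read_thinning_csv(resolve(entry$thinning)), "thinning")
    else gen$thinning
  if (!is.null(thin) && !is.null(sigma)) {
    tb <- grab(detect_breakup(thin), "breakup")
    sel <- grab(select_thinning_model(thin, sigma), "thinning fit")
    if (!is.null(sel)) {
      rec$thinning_model <- sel$choice
      if (sel$choice == "power_law" && !is.null(sel$power_law))
        tb <- sel$power_law$t_b
    }
    if (!is.null(tb)) rec$t_b <- tb
    prof <- grab(extensional_profile(thin, sigma, shear_fit),
                 "extensional profile")
    if (!is.null(prof)) {
      rec$max_eta_extensional <- prof$max_eta_extensional
      rec$max_trouton <- prof$max_trouton
    }
  }

  # -- tribology -----------------------------------------------------------
  fric <- if (!is.null(entry$friction))
    grab(read_friction_csv(resolve(entry$friction)), "friction")
    else gen$friction
  if (!is.null(fric)) {
    rec$surface <- fric$surface
    seg <- grab(segment_regimes(fric), "segmentation")
    if (!is.null(seg)) rec$boundary_mu <- seg$boundary_mu
    mu_ref <- grab(friction_at(fric, reference_speed), "friction_at")
    if (!is.null(mu_ref)) rec$mu_at_reference <- mu_ref
  }

  # -- QCM-D ---------------------------------------------------------------
  qc <- if (!is.null(entry$qcmd))
    grab(read_qcmd_csv(resolve(entry$qcmd), entry$injection_time,
                       entry$rinse_time), "qcmd")
    else gen$qcmd
  if (!is.null(qc)) {
    qs <- grab(summarize_qcmd(qc), "qcmd summary")
    if (!is.null(qs)) {
      rec$removal_percent <- qs$removal_percent
      rec$t_saturation_min <- qs$t_saturation / 60
    }
  }

  list(record = rec,
       data = list(flow = flow, thinning = thin, friction = fric,
                   qcmd = qc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full benchmark over a sample manifest
#'
#' Executes viscosity classification, CaBER fitting, Stribeck analysis
#' and QCM-D analysis for every sample in a manifest and assembles the
#' benchmark table. Per-sample failures are recorded in the `note`
#' column, never fatal to the run. The `p_value` column is a hook for
#' externally computed significance tests and is left `NA`.
#'
#' The manifest is a YAML file path or an equivalent R list:
#' \preformatted{
#' reference_rate: 50        # 1/s, classification shear rate
#' reference_speed: 0.01     # m/s, friction benchmarking speed
#' samples:
#'   - name: gel-like
#'     preset: gel           # synthetic input ...
#'     seed: 11
#'   - name: product-A       # ... or measured CSV files
#'     flow: a_flow.csv
#'     thinning: a_caber.csv
#'     sigma: 0.06
#'     friction: a_stribeck.csv
#'     qcmd: a_qcmd.csv
#'     injection_time: 300
#'     rinse_time: 2000
#' }
#'
#' @param manifest YAML path or list, see above.
#' @return An object of class `benchmark_table`: a list with `records`
#'   (a data.frame, one row per sample), `data` (the per-sample input
#'   curves, for plotting), `reference_rate` and `reference_speed`.
#' @export
run_benchmark <- function(manifest) {
  base_dir <- "."
  if (is.character(manifest) && length(manifest) == 1L) {
    base_dir <- dirname(manifest)
    manifest <- tryCatch(yaml::read_yaml(manifest),
                         error = function(e)
                           stop_io("cannot read manifest: %s",
                                   conditionMessage(e)))
  }
  if (!is.list(manifest)) stop_param("manifest must be a list or YAML path")
  samples <- manifest$samples %||% list()
  reference_rate <- manifest$reference_rate %||% 50
  reference_speed <- manifest$reference_speed %||% 0.01
  out <- lapply(samples, function(entry) {
    if (is.null(entry$name)) stop_param("every manifest sample needs a name")
    analyze_one_sample(entry, reference_rate, reference_speed, base_dir)
  })
  records <- if (length(out)) do.call(rbind, c(
    lapply(out, function(o) as.data.frame(o$record,
                                          stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  if (is.null(records))
    records <- data.frame(name = character(), class = character(),
                          eta_at_50 = numeric(), t_b = numeric(),
                          thinning_model = character(),
                          max_eta_extensional = numeric(),
                          max_trouton = numeric(), boundary_mu = numeric(),
                          mu_at_reference = numeric(), surface = character(),
                          removal_percent = numeric(),
                          t_saturation_min = numeric(), p_value = numeric(),
                          note = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(records$name))
    stop_param("sample names must be unique")
  structure(list(records = records,
                 data = setNames(lapply(out, `[[`, "data"), records$name),
                 reference_rate = reference_rate,
                 reference_speed = reference_speed),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table> %d sample(s); eta at %g 1/s, mu at %g m/s\n",
              nrow(x$records), x$reference_rate, x$reference_speed))
  print(x$records[, c("name", "class", "eta_at_50", "t_b", "boundary_mu",
                      "removal_percent")], row.names = FALSE)
  invisible(x)
}

#' Pairwise friction-reduction matrix
#'
#' Percent friction reduction of every sample against every sample of a
#' reference class, \eqn{100(1 - \mu_{row}/\mu_{col})}, using the
#' friction coefficient at the table's reference speed. Missing values
#' leave `NA` cells.
#'
#' @param table a [run_benchmark()] result.
#' @param reference_class class label selecting the reference samples
#'   (`"liquid"`, `"viscous_liquid"` or `"gel"`).
#' @return matrix of percent reductions (rows: all samples, columns:
#'   reference-class samples).
#' @export
reduction_matrix <- function(table, reference_class) {
  if (!inherits(table, "benchmark_table"))
    stop_param("table must be a benchmark_table")
  rec <- table$records
  refs <- rec[!is.na(rec$class) & rec$class == reference_class, ]
  m <- matrix(NA_real_, nrow(rec), nrow(refs),
              dimnames = list(rec$name, refs$name))
  for (j in seq_len(nrow(refs))) {
    mu_ref <- refs$mu_at_reference[j]
    if (is.na(mu_ref) || mu_ref <= 0) next
    ok <- !is.na(rec$mu_at_reference)
    m[ok, j] <- percent_reduction(rec$mu_at_reference[ok], mu_ref)
  }
  m
}

#' Render a benchmark table to files
#'
#' Writes `benchmark_table.csv` (one row per sample, absent fields as
#' empty cells), `run_log.yaml` (references, package version, sample
#' notes) and, when the raw curves are attached, a `plots.pdf` with the
#' flow curves, thinning traces, Stribeck curves and QCM-D traces of all
#' samples overlaid. Output is byte-stable for a given table.
#'
#' @param table a [run_benchmark()] result.
#' @param out_dir output directory (created if needed).
#' @param plots logical, draw the comparison plots (default TRUE).
#' @return character vector of the files written, invisibly.
#' @export
render_benchmark <- function(table, out_dir, plots = TRUE) {
  if (!inherits(table, "benchmark_table"))
    stop_param("table must be a benchmark_table")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_io("cannot create output directory %s", out_dir)
  csv <- file.path(out_dir, "benchmark_table.csv")
  rec <- table$records
  num <- vapply(rec, is.numeric, logical(1L))
  rec[num] <- lapply(rec[num], function(x) ifelse(is.na(x), NA, signif(x, 8)))
  write.csv(rec, csv, row.names = FALSE, na = "")
  log_path <- file.path(out_dir, "run_log.yaml")
  yaml::write_yaml(list(
    package = "salivabench",
    version = as.character(utils::packageVersion("salivabench")),
    reference_rate_per_s = table$reference_rate,
    reference_speed_m_per_s = table$reference_speed,
    samples = setNames(as.list(table$records$note),
                       table$records$name)), log_path)
  written <- c(csv, log_path)
  if (plots && length(table$data)) {
    pdf_path <- file.path(out_dir, "plots.pdf")
    grDevices::pdf(pdf_path, width = 7, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_benchmark_panels(table)
    written <- c(written, pdf_path)
  }
  invisible(written)
}

plot_benchmark_panels <- function(table) {
  nm <- names(table$data)
  cols <- seq_along(nm)
  panel <- function(getx, gety, logaxes, xlab, ylab, main) {
    xs <- lapply(table$data, getx); ys <- lapply(table$data, gety)
    ok <- !vapply(xs, is.null, logical(1L)) &
      !vapply(ys, is.null, logical(1L))
    if (!any(ok)) return(invisible())
    plot(NA, xlim = range(unlist(xs[ok])), ylim = range(unlist(ys[ok])),
         log = logaxes, xlab = xlab, ylab = ylab, main = main)
    for (i in which(ok)) lines(xs[[i]], ys[[i]], col = cols[i], lwd = 1.5)
    legend("topright", legend = nm[ok], col = cols[ok], lwd = 1.5,
           bty = "n", cex = 0.8)
  }
  panel(function(d) if (is.null(d$flow)) NULL
        else d$flow[[1L]]$shear_rate,
        function(d) if (is.null(d$flow)) NULL else d$flow[[1L]]$viscosity,
        "xy", "shear rate (1/s)", "viscosity (Pa s)", "Flow curves")
  panel(function(d) if (is.null(d$thinning)) NULL else d$thinning$time,
        function(d) if (is.null(d$thinning)) NULL else d$thinning$diameter,
        "y", "time (s)", "diameter (m)", "Filament thinning")
  panel(function(d) if (is.null(d$friction)) NULL else d$friction$speed,
        function(d) if (is.null(d$friction)) NULL else d$friction$mu,
        "xy", "entrainment speed (m/s)", "friction coefficient",
        "Stribeck curves")
  panel(function(d) if (is.null(d$qcmd)) NULL else d$qcmd$time,
        function(d) if (is.null(d$qcmd)) NULL else d$qcmd$delta_f,
        "", "time (s)", "delta f (Hz)", "QCM-D traces")
  invisible()
}
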