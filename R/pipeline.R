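# End-to-end orchestration: progress curves -> lambda(S) -> rate
# constants and cage delta G; denaturation curves -> linkage
# extrapolation and bulk delta G; their difference is the cage-vs-bulk
# destabilization.  Melt and anisotropy sections run when inputs are
# present.

.pipeline_defaults <- function() {
  list(
    temperature = 296.15,        # K (23 C assay temperature)
    depletion_fraction = 0.10,   # progress-curve fit window cutoff
    delta_eps = 6220,            # M^-1 cm^-1 (NADPH at 340 nm)
    path_cm = 0.5,               # optical pathlength
    km_nadph = 13e-6,            # M, NADPH Michaelis constant
    smooth_window = 11L,         # melt derivative filter
    grid_n = 101L,               # chi2 surface nodes per axis
    grid_span = 3,               # chi2 surface half-width in SEs
    count_threshold = 100,       # anisotropy denominator cutoff
    seed = 1L)
}

#' Build a validated pipeline configuration
#'
#' @param manifest Either the path of a JSON manifest file or a list of
#'   entries; each entry is a list with `path`, `role` (one of
#'   `"progress"`, `"lambda"`, `"denaturation"`, `"melt"`,
#'   `"anisotropy"`) and per-role metadata (`dhf_M`, `nadph_M`,
#'   `enzyme_M`, `G`, `label`).
#' @param out_dir Output directory (created if missing).
#' @param ... Overrides of the documented defaults: `temperature` (K),
#'   `depletion_fraction`, `delta_eps`, `path_cm`, `km_nadph`,
#'   `smooth_window`, `grid_n`, `grid_span`, `count_threshold`, `seed`.
#'   Unknown keys are rejected.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir, ...) {
  cfg <- .pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (!is.list(manifest)) stop("'manifest' must be a list or a JSON path")
  roles <- c("progress", "lambda", "denaturation", "melt", "anisotropy")
  for (e in manifest) {
    if (is.null(e$path) || is.null(e$role) || !(e$role %in% roles))
      stop("each manifest entry needs 'path' and a valid 'role' (",
           paste(roles, collapse = ", "), ")")
  }
  cfg$manifest <- manifest
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr, partial, out_dir) {
  tryCatch(expr, error = function(e) {
    # preserve whatever completed before the failure
    try(jsonlite::write_json(partial,
                             file.path(out_dir, "report_partial.json"),
                             auto_unbox = TRUE, digits = NA,
                             force = TRUE), silent = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which the manifest provides inputs and
#' writes `report.json`, a human-readable `report.txt` and a
#' `results.csv` parameter table to the output directory.  Any stage
#' failure halts with the stage named; results of completed stages are
#' preserved in `report_partial.json`.  Re-running on the same inputs
#' and seed reproduces the report exactly.  The report states the free
#' energy sign convention and the constants used.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  set.seed(config$seed)
  consts <- physical_constants(config$temperature)
  optics <- optics_config(config$delta_eps, config$path_cm)
  by_role <- split(config$manifest,
                   vapply(config$manifest, `[[`, "", "role"))
  if (!length(config$manifest))
    stop("empty manifest: no inputs for any section ",
         "(progress/lambda, denaturation, melt, anisotropy)")
  report <- list(
    constants = list(R_kcal_per_mol_K = consts$R, T_K = consts$T,
                     sign_convention = paste("delta G is the folding",
                                             "free energy; positive =",
                                             "unfolded state favored")),
    seed = config$seed)

  meta_num <- function(e, key, default = NA_real_) {
    v <- e[[key]]
    if (is.null(v)) default else as.numeric(v)
  }

  ## --- progress curves -> per-concentration lambda and V ------------
  lam_tab <- NULL
  if (!is.null(by_role$progress)) {
    report$progress <- .stage("progress", {
      rows <- lapply(by_role$progress, function(e) {
        curve <- read_progress_curve(
          e$path, substrate_conc = meta_num(e, "dhf_M"),
          cofactor_conc = meta_num(e, "nadph_M"),
          enzyme_conc = meta_num(e, "enzyme_M"),
          label = if (is.null(e$label)) e$path else e$label)
        win <- select_fit_window(curve, config$depletion_fraction, optics)
        fit <- fit_progress_curve(curve, win)
        data.frame(file = e$path, dhf_M = meta_num(e, "dhf_M"),
                   V = fit$V, V_se = fit$se[["V"]], A = fit$A,
                   lambda = fit$lam, lambda_se = fit$se[["lam"]],
                   lag_detected = fit$lag_detected,
                   window_last = win[2L], converged = fit$converged)
      })
      do.call(rbind, rows)
    }, report, config$out_dir)
    lam_tab <- report$progress[report$progress$converged &
                                 report$progress$lag_detected &
                                 is.finite(report$progress$dhf_M), ]
  }

  ## --- lambda series (from files and/or progress fits) --------------
  series <- NULL
  if (!is.null(by_role$lambda)) {
    series <- .stage("lambda-input", {
      parts <- lapply(by_role$lambda, function(e)
        read_lambda_series(e$path, consts$T))
      S <- unlist(lapply(parts, `[[`, "S"))
      lam <- unlist(lapply(parts, `[[`, "lam"))
      err <- lapply(parts, `[[`, "lam_err")
      err <- if (any(vapply(err, is.null, TRUE))) NULL else unlist(err)
      lambda_series(S, lam, err, consts$T)
    }, report, config$out_dir)
  } else if (!is.null(lam_tab) && length(unique(lam_tab$dhf_M)) >= 4L) {
    series <- lambda_series(lam_tab$dhf_M, lam_tab$lambda,
                            if (all(is.finite(lam_tab$lambda_se)))
                              lam_tab$lambda_se else NULL,
                            consts$T)
  }

  cage <- NULL
  if (!is.null(series)) {
    report$rates <- .stage("rate-inference", {
      fit <- fit_lambda_curve(series)
      surf <- chi2_surface(series, fit,
                           grid_spec = list(n = config$grid_n,
                                            span = config$grid_span))
      ci <- confint_lambda(fit)
      mech <- classify_mechanism(series)
      cage_dg <- delta_g_from_rates(fit$rates, consts,
                                    k1_se = fit$se[["k1"]],
                                    k_minus1_se = fit$se[["k_minus1"]])
      surf_df <- data.frame(
        k1 = rep(surf$k1, times = length(surf$k_minus1)),
        k_minus1 = rep(surf$k_minus1, each = length(surf$k1)),
        reduced_chi2 = as.vector(surf$reduced_chi2))
      write_table(surf_df, file.path(config$out_dir, "chi2_surface.csv"))
      list(k1 = fit$rates$k1, k1_se = fit$se[["k1"]],
           k_minus1 = fit$rates$k_minus1,
           k_minus1_se = fit$se[["k_minus1"]],
           Ka = fit$rates$Ka, Ka_se = fit$se[["Ka"]],
           reduced_chi2 = fit$reduced_chi2,
           ci_k1 = unname(ci["k1", ]),
           ci_k_minus1 = unname(ci["k_minus1", ]),
           mechanism = mech$mechanism,
           mechanism_p_value = mech$p_value,
           delta_g_cage = cage_dg$delta_g,
           delta_g_cage_se = cage_dg$uncertainty)
    }, report, config$out_dir)
    cage <- stability_result(report$rates$delta_g_cage, consts$T,
                             source = "rates",
                             uncertainty = report$rates$delta_g_cage_se)
  }

  ## --- Michaelis-Menten on steady-state velocities -------------------
  if (!is.null(report$progress)) {
    vt <- report$progress[report$progress$converged &
                            is.finite(report$progress$dhf_M), ]
    if (length(unique(vt$dhf_M)) >= 4L) {
      report$michaelis_menten <- .stage("michaelis-menten", {
        mm <- suppressWarnings(
          fit_michaelis_menten(vt$dhf_M, vt$V,
                               if (all(is.finite(vt$V_se))) vt$V_se
                               else NULL))
        list(Vmax = mm$Vmax, Vmax_se = mm$se[["Vmax"]], Km = mm$Km,
             Km_se = mm$se[["Km"]], identifiable = mm$identifiable)
      }, report, config$out_dir)
    }
  }

  ## --- denaturation -> bulk delta G ---------------------------------
  bulk <- NULL
  if (!is.null(by_role$denaturation)) {
    report$denaturation <- .stage("denaturation", {
      fits <- lapply(by_role$denaturation, function(e) {
        curve <- read_denaturation_curve(e$path,
                                         meta_num(e, "nadph_M", 0),
                                         consts$T)
        suppressWarnings(fit_denaturation(curve, consts))
      })
      bulk_dg <- extrapolate_ligand_series(fits, config$km_nadph, consts)
      list(per_curve = data.frame(
             nadph_M = vapply(fits, `[[`, 0, "ligand_conc"),
             delta_g = vapply(fits, `[[`, 0, "delta_g0"),
             delta_g_se = vapply(fits, function(f)
               f$se[["delta_g0"]], 0),
             m = vapply(fits, `[[`, 0, "m"),
             baseline_resolved = vapply(fits, `[[`, TRUE,
                                        "baseline_resolved")),
           delta_g_bulk = bulk_dg$delta_g,
           delta_g_bulk_se = bulk_dg$uncertainty,
           km_nadph = config$km_nadph)
    }, report, config$out_dir)
    bulk <- stability_result(report$denaturation$delta_g_bulk, consts$T,
                             source = "extrapolation",
                             uncertainty =
                               report$denaturation$delta_g_bulk_se)
  }

  ## --- destabilization ----------------------------------------------
  if (!is.null(cage) && !is.null(bulk)) {
    report$destabilization <- .stage("destabilization", {
      dd <- destabilization(cage, bulk)
      list(ddg = dd$ddg, ddg_se = dd$uncertainty)
    }, report, config$out_dir)
  }

  ## --- thermal melts --------------------------------------------------
  if (!is.null(by_role$melt)) {
    report$melts <- .stage("melt", {
      rows <- lapply(by_role$melt, function(e) {
        curve <- read_melt_curve(e$path,
                                 if (is.null(e$label)) e$path else
                                   e$label)
        tm <- melting_temperature(curve, config$smooth_window)
        data.frame(file = e$path, label = curve$label, tm_C = tm$tm,
                   peak = tm$derivative_peak_height,
                   ambiguous = tm$ambiguous)
      })
      do.call(rbind, rows)
    }, report, config$out_dir)
  }

  ## --- anisotropy ------------------------------------------------------
  if (!is.null(by_role$anisotropy)) {
    report$anisotropy <- .stage("anisotropy", {
      rows <- lapply(by_role$anisotropy, function(e) {
        dec <- read_anisotropy_decay(e$path, G = meta_num(e, "G", 1))
        rt <- compute_anisotropy(dec, config$count_threshold)
        fit <- fit_rotational_time(rt)
        data.frame(file = e$path,
                   label = if (is.null(e$label)) e$path else e$label,
                   r0 = fit$r0, theta_ns = fit$theta,
                   theta_se = fit$se[["theta"]],
                   reduced_chi2 = fit$reduced_chi2)
      })
      do.call(rbind, rows)
    }, report, config$out_dir)
  }

  sections <- intersect(c("rates", "michaelis_menten", "denaturation",
                          "destabilization", "melts", "anisotropy"),
                        names(report))
  if (!length(sections))
    stop("no analyzable sections; manifest provided no usable inputs")

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  .write_text_report(report, file.path(config$out_dir, "report.txt"))
  .write_results_csv(report, file.path(config$out_dir, "results.csv"))
  invisible(report)
}

.write_text_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Chaperonin-cage folding analysis report")
  w("Constants: R = %g kcal/mol/K, T = %.2f K",
    report$constants$R_kcal_per_mol_K, report$constants$T_K)
  w("Sign convention: %s", report$constants$sign_convention)
  w("Seed: %d", report$seed)
  if (!is.null(report$rates)) {
    r <- report$rates
    w("\n[Rate inference]")
    w("  k1 = %.4g +/- %.2g s^-1; k_minus1 = %.4g +/- %.2g s^-1; Ka = %.4g M^-1",
      r$k1, r$k1_se, r$k_minus1, r$k_minus1_se, r$Ka)
    w("  mechanism: %s (p = %.3g)", r$mechanism, r$mechanism_p_value)
    w("  cage delta G = %.3f +/- %.3f kcal/mol", r$delta_g_cage,
      r$delta_g_cage_se)
  }
  if (!is.null(report$michaelis_menten))
    w("\n[Michaelis-Menten]\n  Vmax = %.4g, Km = %.4g M",
      report$michaelis_menten$Vmax, report$michaelis_menten$Km)
  if (!is.null(report$denaturation))
    w("\n[Equilibrium stability]\n  bulk delta G (zero NADPH) = %.3f +/- %.3f kcal/mol",
      report$denaturation$delta_g_bulk,
      report$denaturation$delta_g_bulk_se)
  if (!is.null(report$destabilization))
    w("\n[Destabilization]\n  cage - bulk = %.2f +/- %.2f kcal/mol",
      report$destabilization$ddg, report$destabilization$ddg_se)
  if (!is.null(report$melts)) {
    w("\n[Thermal melts]")
    for (i in seq_len(nrow(report$melts)))
      w("  %s: Tm = %.2f C", report$melts$label[i], report$melts$tm_C[i])
  }
  if (!is.null(report$anisotropy)) {
    w("\n[Anisotropy]")
    for (i in seq_len(nrow(report$anisotropy)))
      w("  %s: theta = %.2f +/- %.2f ns", report$anisotropy$label[i],
        report$anisotropy$theta_ns[i], report$anisotropy$theta_se[i])
  }
  invisible(path)
}

.write_results_csv <- function(report, path) {
  rows <- list()
  add <- function(section, quantity, value, se = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(section = section,
                                             quantity = quantity,
                                             value = value, se = se)
  if (!is.null(report$rates)) {
    r <- report$rates
    add("rates", "k1_per_s", r$k1, r$k1_se)
    add("rates", "k_minus1_per_s", r$k_minus1, r$k_minus1_se)
    add("rates", "Ka_per_M", r$Ka, r$Ka_se)
    add("rates", "delta_g_cage_kcal_mol", r$delta_g_cage,
        r$delta_g_cage_se)
  }
  if (!is.null(report$michaelis_menten)) {
    add("mm", "Km_M", report$michaelis_menten$Km,
        report$michaelis_menten$Km_se)
    add("mm", "Vmax", report$michaelis_menten$Vmax,
        report$michaelis_menten$Vmax_se)
  }
  if (!is.null(report$denaturation))
    add("denaturation", "delta_g_bulk_kcal_mol",
        report$denaturation$delta_g_bulk,
        report$denaturation$delta_g_bulk_se)
  if (!is.null(report$destabilization))
    add("destabilization", "ddg_kcal_mol", report$destabilization$ddg,
        report$destabilization$ddg_se)
  if (!is.null(report$melts))
    for (i in seq_len(nrow(report$melts)))
      add("melt", paste0("tm_C:", report$melts$label[i]),
          report$melts$tm_C[i])
  if (!is.null(report$anisotropy))
    for (i in seq_len(nrow(report$anisotropy)))
      add("anisotropy", paste0("theta_ns:", report$anisotropy$label[i]),
          report$anisotropy$theta_ns[i], report$anisotropy$theta_se[i])
  tab <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("section,quantity,value,se", con)
  if (!is.null(tab) && nrow(tab))
    writeLines(sprintf("%s,%s,%.17g,%.17g", tab$section, tab$quantity,
                       tab$value, tab$se), con)
  invisible(path)
}
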