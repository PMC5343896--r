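## Batch orchestration over variants, and rendering of the three standard
## report tables: thermal/two-state thermodynamics, three-state
## thermodynamics, and trajectory metrics.

#' Run the full analysis pipeline over a batch of variants
#'
#' For each variant in the configuration, runs whichever stages its inputs
#' support: melting-temperature extraction from a thermal melt, a two-state
#' fit of a CD-monitored unfolding curve, a three-state (or two-state,
#' auto-selected) fit of a fluorescence-monitored curve, the 222/208
#' ellipticity ratio of a far-UV CD spectrum, and trajectory metric
#' summaries. Per-variant failures are isolated: the batch continues and the
#' failure is recorded in the report and the structured log.
#'
#' @param config a list (or path to a JSON file) with an element `variants`:
#'   a named list, one entry per variant, each a list with any of the fields
#'   `melt`, `curve_cd`, `curve_fluor` (file paths to the delimited formats
#'   of [write_thermal_melt()] / [write_unfolding_curve()], or the in-memory
#'   objects), `cd_spectrum` (a [cd_spectrum()]), `trajectory` (a PDB path or
#'   [trajectory()]). Optional top-level fields: `helix_ranges` (default
#'   [pparg_helix_ranges()]), `salt_bridges` (list of [salt_bridge_spec()]),
#'   `out_dir` (write rendered tables and JSON there), `seed`.
#' @return an object of class `variant_report_batch`: a named list of
#'   per-variant reports, with a structured log in `attr(, "log")` (data
#'   frame: variant, stage, status, message). If `out_dir` is set, the
#'   rendered tables and a JSON dump are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  variants <- config$variants
  if (is.null(variants) || length(variants) == 0L) {
    stop("configuration lists no variants", call. = FALSE)
  }
  if (is.null(names(variants)) || any(names(variants) == "")) {
    stop("every variant entry must be named", call. = FALSE)
  }
  helices <- config$helix_ranges
  if (is.null(helices)) helices <- pparg_helix_ranges()

  log <- list()
  note <- function(variant, stage, status, message = "") {
    log[[length(log) + 1L]] <<- data.frame(
      variant = variant, stage = stage, status = status, message = message,
      stringsAsFactors = FALSE)
  }
  run_stage <- function(variant, stage, expr) {
    tryCatch({
      val <- withCallingHandlers(expr, warning = function(w) {
        note(variant, stage, "warning", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      note(variant, stage, "ok")
      val
    }, error = function(e) {
      note(variant, stage, "error", conditionMessage(e))
      NULL
    })
  }

  reports <- lapply(names(variants), function(vn) {
    v <- variants[[vn]]
    rep <- list(name = vn)

    if (!is.null(v$melt)) {
      melt <- if (is.character(v$melt)) read_thermal_melt(v$melt) else v$melt
      rep$melt <- run_stage(vn, "melting_temperature", {
        if (!is.null(melt$blank)) melt <- blank_correct(melt)
        melting_temperature(melt)
      })
    }
    if (!is.null(v$curve_cd)) {
      cur <- if (is.character(v$curve_cd)) read_unfolding_curve(v$curve_cd)
             else v$curve_cd
      rep$two_state <- run_stage(vn, "fit_two_state", fit_two_state(cur))
    }
    if (!is.null(v$curve_fluor)) {
      cur <- if (is.character(v$curve_fluor)) read_unfolding_curve(v$curve_fluor)
             else v$curve_fluor
      sel <- run_stage(vn, "model_select", model_select(cur))
      if (!is.null(sel)) {
        rep$fluor_model <- sel$preferred
        rep$three_state <- sel$three_state
        if (is.null(rep$two_state)) rep$two_state_fluor <- sel$two_state
      }
    }
    if (!is.null(v$cd_spectrum)) {
      rep$ratio_222_208 <- run_stage(vn, "ellipticity_ratio",
                                     ellipticity_ratio(v$cd_spectrum))
    }
    if (!is.null(v$trajectory)) {
      traj <- if (is.character(v$trajectory)) read_trajectory_pdb(v$trajectory)
              else v$trajectory
      rep$traj <- run_stage(vn, "trajectory_metrics", {
        out <- list(
          rmsd = rmsd_trace(traj),
          rg = rg_trace(traj),
          helix_ranges = helices
        )
        dist_ok <- function(h) all(traj$atoms$resno >= 0) &&
          any(traj$atoms$resno >= h$from & traj$atoms$resno <= h$to &
                traj$atoms$atom == "CA")
        if (dist_ok(helices$H3) && dist_ok(helices$H12)) {
          out$h3_h12 <- helix_distance(traj, helices$H3, helices$H12)
        }
        if (!is.null(helices$sub280_287) && dist_ok(helices$sub280_287) &&
            dist_ok(helices$H12)) {
          out$h12_sub <- helix_distance(traj, helices$H12, helices$sub280_287)
        }
        if (!is.null(config$salt_bridges)) {
          out$salt_bridges <- lapply(config$salt_bridges, function(sb) {
            salt_bridge_trace(traj, sb)
          })
        }
        out
      })
    }
    structure(rep, class = "variant_report")
  })
  names(reports) <- names(variants)
  out <- structure(reports, class = "variant_report_batch")
  attr(out, "log") <- do.call(rbind, log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- render_tables(out)
    for (nm in names(tabs$tables)) {
      utils::write.table(tabs$tables[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
    }
    jsonlite::write_json(tabs$records,
                         file.path(config$out_dir, "reports.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.variant_report_batch <- function(x, ...) {
  cat(sprintf("<variant_report_batch> %d variants: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Render report tables from a batch of variant reports
#'
#' Produces the three standard tables: thermal stability plus two-state
#' thermodynamics (Tm, dG_H2O +/- SE, m +/- SE, urea midpoint), three-state
#' thermodynamics (m and D50 +/- SE and derived dG for each transition), and
#' trajectory metrics (mean with sd in parentheses). Derived quantities are
#' recomputed from the stored fit parameters at render time — the urea
#' midpoint as `dG_H2O / m` and the three-state free energies as `m * D50` —
#' never cached independently.
#'
#' @param reports a `variant_report_batch` from [run_pipeline()].
#' @return a list with `tables` (formatted data frames `table_two_state`,
#'   `table_three_state`, `table_trajectory`; absent quantities are rendered
#'   as `"-"`) and `records` (a nested list of the full-precision numbers
#'   behind every cell, suitable for lossless JSON round-tripping).
#' @export
render_tables <- function(reports) {
  stopifnot(inherits(reports, "variant_report_batch"))
  fmt_pm <- function(v, se, digits = 2) {
    if (is.null(v) || !is.finite(v)) return("-")
    sprintf("%.*f ± %.*f", digits, v, digits, se)
  }
  fmt_sd <- function(m, s, digits = 2) {
    if (is.null(m) || !is.finite(m)) return("-")
    sprintf("%.*f (%.*f)", digits, m, digits, s)
  }
  fmt1 <- function(v, digits = 2) {
    if (is.null(v) || length(v) == 0L || !is.finite(v)) return("-")
    sprintf("%.*f", digits, v)
  }

  t1 <- lapply(reports, function(r) {
    fit <- r$two_state
    data.frame(
      variant = r$name,
      Tm_C = if (!is.null(r$melt)) fmt1(r$melt$tm, 1) else "-",
      dG_H2O = if (!is.null(fit)) fmt_pm(fit$dG_H2O, fit$se[["dG_H2O"]]) else "-",
      m = if (!is.null(fit)) fmt_pm(fit$m, fit$se[["m"]]) else "-",
      urea50 = if (!is.null(fit)) fmt1(fit$dG_H2O / fit$m) else "-",
      stringsAsFactors = FALSE)
  })
  t2 <- lapply(reports, function(r) {
    fit <- r$three_state
    if (is.null(fit)) {
      data.frame(variant = r$name, m_IN = "-", D50_IN = "-", dG_IN = "-",
                 m_UI = "-", D50_UI = "-", dG_UI = "-", stringsAsFactors = FALSE)
    } else {
      data.frame(
        variant = r$name,
        m_IN = fmt_pm(fit$m_IN, fit$se[["m_IN"]]),
        D50_IN = fmt_pm(fit$D50_IN, fit$se[["D50_IN"]]),
        dG_IN = fmt1(fit$m_IN * fit$D50_IN),
        m_UI = fmt_pm(fit$m_UI, fit$se[["m_UI"]]),
        D50_UI = fmt_pm(fit$D50_UI, fit$se[["D50_UI"]]),
        dG_UI = fmt1(fit$m_UI * fit$D50_UI),
        stringsAsFactors = FALSE)
    }
  })
  t3 <- lapply(reports, function(r) {
    tr <- r$traj
    data.frame(
      variant = r$name,
      rmsd_nm = if (!is.null(tr)) fmt_sd(tr$rmsd$mean, tr$rmsd$sd) else "-",
      rg_nm = if (!is.null(tr)) fmt_sd(tr$rg$mean, tr$rg$sd) else "-",
      h3_h12_nm = if (!is.null(tr$h3_h12))
        fmt_sd(tr$h3_h12$mean, tr$h3_h12$sd) else "-",
      h12_sub_nm = if (!is.null(tr$h12_sub))
        fmt_sd(tr$h12_sub$mean, tr$h12_sub$sd) else "-",
      stringsAsFactors = FALSE)
  })

  records <- lapply(reports, function(r) {
    rec <- list(name = r$name)
    if (!is.null(r$melt)) {
      rec$tm <- r$melt$tm
      rec$aggregation_onset <- r$melt$aggregation_onset
    }
    if (!is.null(r$two_state)) {
      f <- r$two_state
      rec$two_state <- list(dG_H2O = f$dG_H2O, m = f$m,
                            urea50 = f$dG_H2O / f$m, se = as.list(f$se))
    }
    if (!is.null(r$three_state)) {
      f <- r$three_state
      rec$three_state <- list(m_IN = f$m_IN, D50_IN = f$D50_IN,
                              dG_IN = f$m_IN * f$D50_IN,
                              m_UI = f$m_UI, D50_UI = f$D50_UI,
                              dG_UI = f$m_UI * f$D50_UI, se = as.list(f$se))
    }
    if (!is.null(r$ratio_222_208)) rec$ratio_222_208 <- r$ratio_222_208
    if (!is.null(r$traj)) {
      rec$traj <- list(
        rmsd = list(mean = r$traj$rmsd$mean, sd = r$traj$rmsd$sd),
        rg = list(mean = r$traj$rg$mean, sd = r$traj$rg$sd))
      if (!is.null(r$traj$h3_h12)) {
        rec$traj$h3_h12 <- list(mean = r$traj$h3_h12$mean,
                                sd = r$traj$h3_h12$sd)
      }
      if (!is.null(r$traj$h12_sub)) {
        rec$traj$h12_sub <- list(mean = r$traj$h12_sub$mean,
                                 sd = r$traj$h12_sub$sd)
      }
      rec$traj$helix_ranges <- lapply(r$traj$helix_ranges, function(h) {
        list(label = h$label, from = h$from, to = h$to)
      })
    }
    rec
  })

  list(tables = list(table_two_state = do.call(rbind, t1),
                     table_three_state = do.call(rbind, t2),
                     table_trajectory = do.call(rbind, t3)),
       records = records)
}
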