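#' Assemble a run configuration
#'
#' A plain-list configuration driving the end-to-end pipelines.  It can
#' also be read from a YAML file with [read_run_config()]; values given
#' directly override the file.
#'
#' @param cohorts named list: cohort CSV paths or [cohort()] objects
#' @param input bioassay CSV path or [bioassay_table()] (bioassay runs)
#' @param stage_order stage codes used when reading cohort CSVs
#' @param B bootstrap iterations
#' @param seed integer RNG seed
#' @param alpha significance level for comparisons
#' @param out_dir output directory (created if absent)
#' @param plots write figure panels per cohort
#' @param control_strain strain name supplying control mortality for
#'   Abbott correction (bioassay runs; `NULL` for none)
#' @param lc50_strain strain for the dose-response fit (`NULL` picks the
#'   only strain present, if unique)
#' @param lc50_day endpoint day of the dose-response fit
#' @return list of class `run_config`
#' @export
run_config <- function(cohorts = NULL, input = NULL,
                       stage_order = DEFAULT_STAGES, B = 1000L,
                       seed = 1L, alpha = 0.05, out_dir = "twosexlt-out",
                       plots = FALSE, control_strain = NULL,
                       lc50_strain = NULL, lc50_day = 14L) {
  stopifnot(B >= 1L, alpha > 0, alpha < 1)
  structure(list(cohorts = cohorts, input = input,
                 stage_order = stage_order, B = as.integer(B),
                 seed = as.integer(seed), alpha = alpha,
                 out_dir = out_dir, plots = plots,
                 control_strain = control_strain,
                 lc50_strain = lc50_strain,
                 lc50_day = as.integer(lc50_day)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML configuration file
#' @param ... overrides applied on top of the file's values
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

# Short provenance hash of the analysis configuration.  Output location
# and plot toggle are excluded: they do not affect the numbers, and two
# runs of the same analysis must produce byte-identical tables.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$plots <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}

write_report_csv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full demographic pipeline
#'
#' Cohort CSVs in, report bundle out: for every cohort the age-stage
#' survival matrix, the `l_x`/`f_x`/`m_x` schedule, the `e_xj` and `v_xj`
#' matrices (tidy long CSVs), bootstrap standard errors for the
#' population parameters, and — with two or more cohorts — an all-pairs
#' paired-bootstrap comparison with Holm letters (`params.csv`).  Every
#' output starts with a comment line carrying the configuration hash and
#' seed, so identical configurations reproduce byte-identical files.
#'
#' @param config a [run_config()] (or a YAML path accepted by
#'   [read_run_config()]) with a non-empty named `cohorts` list
#' @return invisibly, a list with `lifetables`, `bootstraps`,
#'   `comparison` and `files`
#' @export
run_lifetable_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$cohorts) || length(config$cohorts) == 0L ||
      is.null(names(config$cohorts))) {
    stop("config$cohorts must be a non-empty named list", call. = FALSE)
  }
  # validate every input before writing anything
  cohorts <- lapply(names(config$cohorts), function(nm) {
    x <- config$cohorts[[nm]]
    if (inherits(x, "cohort")) return(x)
    read_cohort(x, stage_order = config$stage_order, label = nm)
  })
  names(cohorts) <- names(config$cohorts)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# twosexlt run: config=%s seed=%d B=%d",
                 config_hash(config), config$seed, config$B)
  files <- character(0)

  lts <- lapply(cohorts, life_table)
  boots <- lapply(cohorts, bootstrap_parameters, B = config$B,
                  seed = config$seed)

  long <- function(m, value = "value") {
    df <- expand.grid(age = as.integer(rownames(m)),
                      stage = colnames(m), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df[[value]] <- as.vector(m)
    df[!is.na(df[[value]]), , drop = FALSE]
  }
  for (nm in names(lts)) {
    lt <- lts[[nm]]
    sched <- data.frame(age = as.integer(names(lt$lx)), lx = lt$lx,
                        fx = lt$f[, "adult_female"], mx = lt$mx)
    out <- list(schedule = sched, sxj = long(unclass(lt$s)),
                exj = long(lt$exj))
    if (!is.null(lt$vxj)) out$vxj <- long(lt$vxj)
    for (what in names(out)) {
      p <- file.path(config$out_dir, sprintf("%s_%s.csv", nm, what))
      write_report_csv(out[[what]], p, hdr)
      files <- c(files, p)
    }
    if (isTRUE(config$plots)) {
      p <- file.path(config$out_dir, sprintf("%s_panels.png", nm))
      grDevices::png(p, width = 1400, height = 1000, res = 130)
      plot(lt)
      grDevices::dev.off()
      files <- c(files, p)
    }
  }

  comparison <- NULL
  if (length(boots) >= 2L) {
    comparison <- bootstrap_letters(boots, alpha = config$alpha)
  } else {
    b <- boots[[1L]]
    comparison <- data.frame(parameter = names(b$estimates),
                             group = names(boots)[1L],
                             estimate = unname(b$estimates),
                             se = unname(b$se), letter = "a")
  }
  p <- file.path(config$out_dir, "params.csv")
  write_report_csv(comparison, p, hdr)
  files <- c(files, p)

  invisible(list(lifetables = lts, bootstraps = boots,
                 comparison = comparison, files = files))
}

#' Run the bioassay pipeline
#'
#' Produces a strain-level virulence report from a cumulative-mortality
#' table: per strain x concentration the Abbott-corrected mortality time
#' course (`mortality.csv`), the three-parameter logistic time-mortality
#' fit with LT50 or the reason it is undefined (`time_mortality.csv`,
#' where an asymptote at or below 50% yields an empty LT50 field with
#' reason `"asymptote <= 50%"`), and a probit dose-response fit with
#' LC50 and Fieller limits at the endpoint day when more than two
#' concentrations of the target strain are present (`lc50.csv`).
#'
#' @param config a [run_config()] with `input` set
#' @return invisibly, a list with `mortality`, `time_mortality`, `lc50`
#'   and `files`
#' @export
run_bioassay_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input)) stop("config$input is required", call. = FALSE)
  tab <- if (inherits(config$input, "bioassay_table")) config$input else
    read_bioassay(config$input)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# twosexlt run: config=%s seed=%d", config_hash(config),
                 config$seed)
  files <- character(0)

  # mean mortality proportion by strain x concentration x day
  agg <- stats::aggregate(cbind(p = n_dead_cum / n_total) ~
                            strain + concentration + day,
                          data = tab, FUN = mean)
  ctrl <- NULL
  if (!is.null(config$control_strain)) {
    ctrl <- agg[agg$strain == config$control_strain, ]
    agg <- agg[agg$strain != config$control_strain, ]
    if (nrow(ctrl) == 0L) {
      stop("control strain '", config$control_strain,
           "' absent from the table", call. = FALSE)
    }
  }
  agg$corrected <- if (is.null(ctrl)) 100 * agg$p else {
    pc <- ctrl$p[match(agg$day, ctrl$day)]
    mapply(abbott_correction, agg$p, pc)
  }
  mortality <- agg[order(agg$strain, agg$concentration, agg$day),
                   c("strain", "concentration", "day", "corrected")]
  p <- file.path(config$out_dir, "mortality.csv")
  write_report_csv(mortality, p, hdr)
  files <- c(files, p)

  series <- split(mortality,
                  interaction(mortality$strain, mortality$concentration,
                              drop = TRUE))
  tm_rows <- lapply(series, function(sr) {
    row <- data.frame(strain = sr$strain[1L],
                      concentration = sr$concentration[1L],
                      final_mortality = sr$corrected[which.max(sr$day)],
                      K = NA_real_, a = NA_real_, b = NA_real_,
                      r2 = NA_real_, lt50 = NA_real_,
                      reason = NA_character_)
    fit <- tryCatch(fit_time_mortality(sr$day, pmax(0, sr$corrected)),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      row$reason <- fit
    } else {
      lt <- lt50(fit)
      row[c("K", "a", "b", "r2")] <- fit[c("K", "a", "b", "r2")]
      row$lt50 <- lt$lt50
      row$reason <- lt$reason
    }
    row
  })
  time_mortality <- do.call(rbind, c(tm_rows, make.row.names = FALSE))
  p <- file.path(config$out_dir, "time_mortality.csv")
  write_report_csv(time_mortality, p, hdr)
  files <- c(files, p)

  lc50_out <- NULL
  target <- config$lc50_strain
  if (is.null(target) && length(unique(agg$strain)) == 1L) {
    target <- unique(agg$strain)
  }
  if (!is.null(target)) {
    endpoint <- tab[tab$strain == target & tab$day == config$lc50_day, ]
    if (nrow(endpoint) > 0L) {
      bydose <- stats::aggregate(cbind(n_total, n_dead_cum) ~ concentration,
                                 data = endpoint, FUN = sum)
      if (nrow(bydose) >= 3L) {
        dr <- tryCatch(
          fit_dose_response(bydose$concentration, bydose$n_total,
                            bydose$n_dead_cum),
          error = function(e) NULL)
        if (!is.null(dr)) {
          lc50_out <- data.frame(strain = target, day = config$lc50_day,
                                 intercept = dr$intercept,
                                 slope = dr$slope, lc50 = dr$lc50,
                                 lc50_lo = dr$lc50_ci[1L],
                                 lc50_hi = dr$lc50_ci[2L],
                                 chi2_gof = dr$chi2_gof, df = dr$df)
          p <- file.path(config$out_dir, "lc50.csv")
          write_report_csv(lc50_out, p, hdr)
          files <- c(files, p)
        }
      }
    }
  }
  invisible(list(mortality = mortality, time_mortality = time_mortality,
                 lc50 = lc50_out, files = files))
}

#' Four-panel life-table plot
#'
#' Base-graphics panels of the age-stage survival curves `s_xj`, the
#' `l_x`/`f_x`/`m_x` schedules, the life expectancy `e_xj` and the
#' reproductive value `v_xj` by stage.
#'
#' @param x a [life_table()]
#' @param ... ignored
#' @return `x`, invisibly
#' @export
plot.lifetable <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ages <- as.integer(rownames(x$s))
  cols <- grDevices::hcl.colors(ncol(x$s), "Dark 3")
  matcurves <- function(m, ylab, main) {
    graphics::matplot(ages, m, type = "l", lty = 1, col = cols,
                      xlab = "age (days)", ylab = ylab, main = main)
    graphics::legend("topright", colnames(m), col = cols, lty = 1,
                     cex = 0.6, bty = "n")
  }
  matcurves(unclass(x$s), "s_xj", "Age-stage survival")
  graphics::plot(ages, x$lx, type = "l", ylim = c(0, 1),
                 xlab = "age (days)", ylab = "l_x",
                 main = "Survival and fecundity")
  graphics::par(new = TRUE)
  graphics::plot(ages, x$mx, type = "l", col = "firebrick", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "firebrick")
  graphics::mtext("m_x", side = 4, line = -1.2, col = "firebrick",
                  cex = 0.7)
  matcurves(x$exj, "e_xj (days)", "Life expectancy")
  if (!is.null(x$vxj)) {
    matcurves(x$vxj, "v_xj", "Reproductive value")
  }
  invisible(x)
}
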