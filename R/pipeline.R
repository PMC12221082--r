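# Data ingest, cleaning, trait scoring, and orchestration of the full
# analysis: clean -> fit -> dynamics -> trait associations -> report.

#' Read a long-format EMA CSV
#'
#' Expected columns: `person_id`, `timestamp` (ISO 8601), `felt`,
#' `expressed` (0-100, empty for missing).
#'
#' @param path CSV file path.
#' @return Data frame of raw records.
#' @export
read_ema_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "timestamp", "felt", "expressed")
  if (!all(need %in% names(df)))
    ld_stop(paste("EMA CSV must have columns:", paste(need, collapse = ", ")),
            "lovedyn_data_error")
  df
}

#' Read a trait CSV
#'
#' One row per person; either scored columns (`sex`, `happiness`,
#' `flourishing`, `wellbeing`) or item columns (see [score_traits()]).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_trait_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"person_id" %in% names(df))
    ld_stop("trait CSV must have a person_id column", "lovedyn_data_error")
  df
}

parse_times_hours <- function(timestamp) {
  tt <- as.POSIXct(timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (any(is.na(tt)))
    ld_stop("unparseable timestamps in EMA records", "lovedyn_data_error")
  as.numeric(tt) / 3600
}

#' Clean raw EMA records into per-person observation series
#'
#' Applies the study's cleaning rules per person, in order: (1) sort by
#' time; (2) drop the first completed survey (the expressed-love item
#' refers to the interval since the previous survey, which does not exist
#' at the initial prompt); (3) forward-scan and drop any record less than
#' one minute after the previously retained record; (4) re-express times
#' in hours since the first retained record. Persons with fewer than
#' `min_occasions` retained records are excluded with a warning.
#'
#' @param raw Data frame of raw records (see [read_ema_csv()]).
#' @param drop_initial Apply rule (2); set `FALSE` when re-cleaning data
#'   that is already clean.
#' @param min_occasions Minimum retained records per person (default 3).
#' @return Named list of [observation_series()]; the removal log (one row
#'   per person: counts of raw, initial-dropped, min-gap-dropped, retained
#'   records) is attached as attribute `"removal_log"`.
#' @export
clean_series <- function(raw, drop_initial = TRUE, min_occasions = 3) {
  stopifnot(is.data.frame(raw))
  raw$._hours <- parse_times_hours(raw$timestamp)
  out <- list()
  log <- list()
  for (id in unique(raw$person_id)) {
    d <- raw[raw$person_id == id, , drop = FALSE]
    d <- d[order(d$._hours), , drop = FALSE]
    n_raw <- nrow(d)
    n_init <- 0L
    if (drop_initial && nrow(d) > 0) {
      d <- d[-1, , drop = FALSE]
      n_init <- 1L
    }
    keep <- logical(nrow(d))
    last <- -Inf
    for (i in seq_len(nrow(d))) {
      if (d$._hours[i] - last >= 1 / 60) {
        keep[i] <- TRUE
        last <- d$._hours[i]
      }
    }
    d <- d[keep, , drop = FALSE]
    log[[id]] <- data.frame(person_id = id, n_raw = n_raw,
                            n_initial_removed = n_init,
                            n_min_gap_removed = sum(!keep),
                            n_retained = nrow(d))
    if (nrow(d) < min_occasions) {
      warning(sprintf("person %s excluded: only %d retained records (< %d)",
                      id, nrow(d), min_occasions))
      next
    }
    out[[as.character(id)]] <-
      observation_series(id, d$._hours - d$._hours[1], d$felt, d$expressed)
  }
  structure(out, removal_log = do.call(rbind, c(log, make.row.names = FALSE)))
}

#' Score trait scales
#'
#' Scores the trait battery from item-level responses where present:
#' general happiness is the mean of 4 items on 1-7; flourishing is the sum
#' of 8 items on 1-7 (range 8-56); emotional well-being is the mean of 4
#' items on 1-6 after reverse-keying flagged items (`x -> 7 - x`). Columns
#' already scored (`happiness`, `flourishing`, `wellbeing`) pass through
#' unchanged; `sex` is expected coded Male = 0, Female = 1.
#'
#' @param traits Data frame with `person_id`, `sex`, and either scored
#'   columns or item columns `happiness_1..4`, `flourishing_1..8`,
#'   `wellbeing_1..4`.
#' @param wellbeing_reverse Logical length-4 flags marking reverse-keyed
#'   well-being items.
#' @return Data frame with columns `person_id`, `sex`, `happiness`,
#'   `flourishing`, `wellbeing`.
#' @export
score_traits <- function(traits, wellbeing_reverse = rep(FALSE, 4)) {
  stopifnot(is.data.frame(traits), "person_id" %in% names(traits))
  out <- data.frame(person_id = traits$person_id)
  out$sex <- if ("sex" %in% names(traits)) traits$sex else NA_real_

  item_block <- function(prefix, k, lo, hi) {
    cols <- paste0(prefix, "_", seq_len(k))
    if (!all(cols %in% names(traits))) return(NULL)
    m <- as.matrix(traits[cols])
    bad <- which(!is.na(m) & (m < lo | m > hi), arr.ind = TRUE)
    if (nrow(bad) > 0)
      ld_stop(sprintf("%s item out of range [%d, %d] at row %d",
                      prefix, lo, hi, bad[1, 1]), "lovedyn_data_error")
    m
  }

  h <- item_block("happiness", 4, 1, 7)
  out$happiness <- if (!is.null(h)) rowMeans(h)
  else if ("happiness" %in% names(traits)) traits$happiness else NA_real_

  f <- item_block("flourishing", 8, 1, 7)
  out$flourishing <- if (!is.null(f)) rowSums(f)
  else if ("flourishing" %in% names(traits)) traits$flourishing else NA_real_

  w <- item_block("wellbeing", 4, 1, 6)
  out$wellbeing <- if (!is.null(w)) {
    stopifnot(length(wellbeing_reverse) == 4)
    w[, wellbeing_reverse] <- 7 - w[, wellbeing_reverse]
    rowMeans(w)
  } else if ("wellbeing" %in% names(traits)) traits$wellbeing else NA_real_
  out
}

#' Render report tables
#'
#' Formats the group-level dynamics summary (feature, mean, 95% CI) and
#' the trait-evidence grid (cells `r[bf10]`, an asterisk marking BF10 >
#' 10) as markdown tables with numbers rounded to 3 decimals.
#'
#' @param summary A `group_summary` from [summarize_group()].
#' @param evidence An `evidence_grid` from [associate()].
#' @return List with character vectors `dynamics` and `associations`
#'   (markdown lines).
#' @export
render_tables <- function(summary, evidence) {
  stopifnot(inherits(summary, "group_summary"))
  t2 <- c("| Time dynamics features | Mean | 95% CI |",
          "|---|---|---|",
          sprintf("| %s | %.3f | [%.3f, %.3f] |",
                  summary$feature, summary$mean, summary$lower, summary$upper))
  if (nrow(evidence) == 0) {
    t3 <- c("| Time dynamics features |", "|---|")
  } else {
    traits <- unique(evidence$trait)
    feats <- unique(evidence$feature)
    hdr <- paste0("| Time dynamics features | ",
                  paste(traits, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(traits) + 1), collapse = "|"), "|")
    rows <- vapply(feats, function(f) {
      cells <- vapply(traits, function(tr) {
        e <- evidence[evidence$feature == f & evidence$trait == tr, ]
        sprintf("%.3f%s[%.3f]", e$r[1], if (isTRUE(e$bf10[1] > 10)) "*" else "",
                e$bf10[1])
      }, character(1))
      paste0("| ", f, " | ", paste(cells, collapse = " | "), " |")
    }, character(1))
    t3 <- c(hdr, sep, rows)
  }
  list(dynamics = t2, associations = t3)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a long-format EMA table and a
#' trait table: cleaning, hierarchical model fitting, group summary,
#' lag curves and peak cross-lags at the group-mean drift, person-level
#' point estimates, trait scoring and Bayes-factor associations. All
#' outputs plus a run manifest (seed, configuration, convergence
#' diagnostics) are written to `out_dir`; any stage error aborts with a
#' stage-named message and removes partial outputs.
#'
#' @param ema EMA data frame or CSV path (see [read_ema_csv()]).
#' @param traits Trait data frame or CSV path.
#' @param out_dir Output directory.
#' @param config An [mcmc_config()].
#' @param prior A [group_prior()].
#' @param lag_grid Lag grid (hours) for the lag-curve table.
#' @return Invisible list with components `series`, `posterior`, `summary`,
#'   `curves`, `peaks`, `estimates`, `evidence`, `tables`, `manifest`.
#' @export
run_pipeline <- function(ema, traits, out_dir, config = mcmc_config(),
                         prior = group_prior(),
                         lag_grid = seq(0.1, 10, by = 0.1)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "ingest"
  res <- tryCatch({
    if (is.character(ema)) ema <- read_ema_csv(ema)
    if (is.character(traits)) traits <- read_trait_csv(traits)

    stage <- "clean"
    series <- clean_series(ema)

    stage <- "fit"
    post <- fit_hierarchical(series, prior = prior, config = config)

    stage <- "summarize"
    summ <- summarize_group(post)

    stage <- "dynamics"
    amean <- matrix(c(summ$mean[1], summ$mean[4], summ$mean[3], summ$mean[2]),
                    2, 2)
    curves <- lag_curves(amean, lag_grid)
    peaks <- do.call(rbind, lapply(
      c("expressed_to_felt", "felt_to_expressed"), function(w) {
        pk <- peak_cross_lag(amean, w)
        data.frame(cross_influence = w,
                   peak_lag_hours = if (is.null(pk)) NA_real_ else pk$lag,
                   peak_value = if (is.null(pk)) NA_real_ else pk$value)
      }))

    stage <- "associate"
    est <- person_point_estimates(post)
    scored <- score_traits(traits)
    scored <- scored[scored$person_id %in% est$person_id, , drop = FALSE]
    ev <- associate(est, scored)

    stage <- "report"
    tables <- render_tables(summ, ev)
    w <- function(path, fun) { fun(path); written <<- c(written, path); path }
    w(file.path(out_dir, "group_summary.csv"),
      function(p) write.csv(format_num_df(summ), p, row.names = FALSE))
    w(file.path(out_dir, "lag_curves.csv"),
      function(p) write_lag_curve(curves, p))
    w(file.path(out_dir, "peak_lags.csv"),
      function(p) write.csv(format_num_df(peaks), p, row.names = FALSE))
    w(file.path(out_dir, "person_estimates.csv"),
      function(p) write.csv(format_num_df(est), p, row.names = FALSE))
    w(file.path(out_dir, "associations.csv"),
      function(p) write.csv(format_num_df(ev), p, row.names = FALSE))
    w(file.path(out_dir, "table_dynamics.md"),
      function(p) writeLines(tables$dynamics, p))
    w(file.path(out_dir, "table_associations.md"),
      function(p) writeLines(tables$associations, p))

    manifest <- list(
      seed = config$seed, chains = config$chains,
      iterations = config$iterations, warmup_frac = config$warmup_frac,
      n_persons = length(series),
      removal_log = attr(series, "removal_log"),
      converged = post$converged,
      max_rhat = max(post$diagnostics$rhat, na.rm = TRUE),
      min_ess = min(post$diagnostics$ess, na.rm = TRUE),
      nonstationary_frac = post$nonstationary_frac)
    w(file.path(out_dir, "manifest.json"),
      function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                       digits = 10, dataframe = "rows"))

    list(series = series, posterior = post, summary = summ, curves = curves,
         peaks = peaks, estimates = est, evidence = ev, tables = tables,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    ld_stop(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)), "lovedyn_pipeline_error")
  })
  invisible(res)
}

# round numeric columns for stable, readable CSV output
format_num_df <- function(df, digits = 6) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  df
}
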